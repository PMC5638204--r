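test_that("maximal contribution solves the ceiling calibration", {
    cfg <- PriorConfig()
    mc <- maxContribution(cfg)
    # combining prior odds with contribution odds lands exactly on the ceiling
    post <- 1 / (1 + exp(-(log(cfg@tau / (1 - cfg@tau)) +
                           log(mc / (1 - mc)))))
    expect_equal(post, cfg@ceiling, tolerance = 1e-12)
    # hand-solved odds: (0.02/0.98) * (0.9975/0.0025) = 399/49, Mc = 399/448
    expect_equal(mc, 399 / 448, tolerance = 1e-12)
    # degenerate equality: no headroom, no contribution
    expect_equal(maxContribution(tau = 0.02, ceiling = 0.02), 0.5)
})

test_that("minimal significant neighbour counts match the binomial tail", {
    expect_identical(minActiveNeighbours(10), 3L)
    expect_identical(minActiveNeighbours(100), 6L)
    # d = 3: tail(>=2) = 3 tau^2 (1-tau) + tau^3 > 0.05/12000 >= tau^3
    expect_identical(minActiveNeighbours(3), 3L)
    # low degrees where no a <= d is significant return d + 1
    expect_identical(minActiveNeighbours(1), 2L)
    expect_error(minActiveNeighbours(0), "degree")
})

test_that("significance is consistent at the returned count", {
    cfg <- PriorConfig()
    thr <- cfg@significanceBase / cfg@nGenesTotal
    for (d in c(3, 5, 10, 25, 100, 400)) {
        a <- minActiveNeighbours(d, cfg)
        if (a <= d) {
            expect_lte(pbinom(a - 1, d, cfg@tau, lower.tail = FALSE), thr)
            expect_gt(pbinom(a - 2, d, cfg@tau, lower.tail = FALSE), thr)
        }
    }
})

test_that("delta solves the per-neighbour calibration and respects the cap", {
    cfg <- PriorConfig()
    # d = 10: (delta/(1-delta))^3 = 399/49, hand-solved delta ~ 0.668
    expect_equal(deltaForDegree(10), 0.66798, tolerance = 1e-4)
    # exactly a_min active neighbours reproduce the maximal contribution
    for (d in c(3, 10, 100)) {
        a <- minActiveNeighbours(d, cfg)
        del <- deltaForDegree(d, cfg)
        expect_equal(a * log(del / (1 - del)),
                     log(399 / 49), tolerance = 1e-9)
    }
    # monotonicity: a_min non-decreasing, delta non-increasing in d
    ds <- 1:200
    expect_true(all(diff(minActiveNeighbours(ds)) >= 0))
    expect_true(all(diff(deltaForDegree(ds)) <= 1e-12))
    # cap over a wide tau/degree sweep
    for (tau in c(0.001, 0.0025, 0.01))
        expect_lte(max(deltaForDegree(1:500, PriorConfig(tau = tau))), 0.9)
})

test_that("distance-2 closure behaves on paths, triangles and stars", {
    path <- GeneNetwork(cbind(c("A", "B"), c("B", "C")))
    cl <- buildAugmentedAdjacency(path, 2)
    expect_equal(nrow(networkEdges(cl)), 3L)
    expect_identical(buildAugmentedAdjacency(path, 1), path)

    tri <- GeneNetwork(cbind(c("A", "B", "C"), c("B", "C", "A")))
    expect_equal(nrow(networkEdges(buildAugmentedAdjacency(tri, 2))), 3L)

    star <- GeneNetwork(cbind("c", paste0("l", 1:5)))
    cl2 <- buildAugmentedAdjacency(star, 2)
    expect_equal(nrow(networkEdges(cl2)), choose(6, 2))  # complete on 6
})

test_that("pair priors are directed, degree-parametrized and symmetric only when degrees match", {
    cfg <- PriorConfig()
    single <- GeneNetwork(cbind("A", "B"))
    pp <- buildPairPriors(single, cfg)
    expect_equal(nrow(pp), 2L)
    expect_equal(pp$delta[1], pp$delta[2])

    star <- GeneNetwork(cbind("c", paste0("l", 1:5)))
    pp2 <- buildPairPriors(star, PriorConfig(nGenesTotal = 12000))
    # closure makes the star complete: every gene has augmented degree 5
    expect_true(all(pp2$delta == deltaForDegree(5, cfg)))
    expect_equal(nrow(pp2), 2 * choose(6, 2))

    expect_equal(nrow(buildPairPriors(GeneNetwork())), 0L)
})

test_that("contribution capping clips positive evidence at the maximal contribution", {
    cfg <- PriorConfig()
    lcap <- log(399 / 49)
    del <- deltaForDegree(10, cfg)
    unit <- log(del / (1 - del))
    expect_equal(capContribution(rep(unit, 10), cfg), lcap)
    expect_equal(capContribution(numeric(0), cfg), 0)
    expect_equal(capContribution(0.5 * unit, cfg), 0.5 * unit)
    # negative contributions pass through
    expect_equal(capContribution(c(rep(unit, 10), -0.3), cfg), lcap - 0.3)
})

test_that("prior config validity rejects inconsistent thresholds", {
    expect_error(PriorConfig(tau = 0.05), "tau < ceiling")
    expect_error(PriorConfig(deltaCap = 1.2), "deltaCap")
})
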