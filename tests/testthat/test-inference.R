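test_that("damped update is a convex combination with fixed points", {
    old <- c(1, 0); nw <- c(0, 1)
    expect_equal(dampedUpdate(old, nw, 0), nw)
    expect_equal(dampedUpdate(old, nw, 0.5), c(0.5, 0.5))
    m <- c(0.3, 0.7)
    expect_equal(dampedUpdate(m, m, 0.5), m)
    expect_error(dampedUpdate(c(0.5, 0.5), c(1, 0, 0), 0.5), "support")
})

test_that("an isolated gene stays at its prior", {
    co <- makeEmptyCohort(2, c(0, 0))
    # gene enters through a degenerate 'network' of one isolated prior pair
    # partner: use a single-edge network, clamp nothing, gamma = 1
    m <- matrix(0, 1, 2, dimnames = list("v1", c("s1", "s2")))
    m[1, 1] <- 0
    co <- VariantCohort(m + 0, c(v1 = "A"),
                        phenotype = c(s1 = 0, s2 = 0))
    g <- buildFactorGraph(co, NULL, ModelConfig(gamma = 1), PriorConfig())
    fit <- runInference(g, tightConfig())
    expect_equal(unname(geneMarginals(fit)["A"]), 0.0025, tolerance = 1e-9)
})

test_that("loopy BP equals exhaustive enumeration on tree fixtures", {
    g <- buildFactorGraph(makeTreeCohort())
    ex <- exactMarginals(g)
    bp <- runInference(g, tightConfig())
    expectMarginalsEqual(bp, ex, 1e-6)
    expect_true(convergenceInfo(bp)$converged)

    # second tree: one gene, several individuals, mixed dosages
    m <- matrix(0, 3, 4)
    m[1, 1] <- 2; m[2, 2] <- 1; m[3, 4] <- 1
    co <- makeCohort(m, c("A", "A", "A"), c(1, 0, 1, 0))
    g2 <- buildFactorGraph(co, NULL, ModelConfig(gamma = 0.7), PriorConfig())
    expectMarginalsEqual(runInference(g2, tightConfig()),
                         exactMarginals(g2), 1e-6)
})

test_that("loopy BP error stays within its documented bounds", {
    # shared-carrier loop (the typical loop type in rare-variant cohorts):
    # gene marginals within 0.02 of enumeration, variant marginals within
    # 0.07 (intrinsic loopy double-counting through the shared gene; the
    # fixed point is unique across damping weights and schedules)
    g <- buildFactorGraph(makeLoopyCohort())
    expectMarginalsEqual(runInference(g, tightConfig()),
                         exactMarginals(g), 0.02, tolVariant = 0.07)

    # adversarial fixture: every individual shares variants with every
    # other; measured worst-case loopy error, documented in the vignette
    m <- matrix(c(1, 1, 0,
                  0, 1, 1,
                  1, 0, 1), 3, 3, byrow = TRUE)
    co <- makeCohort(m, c("A", "A", "B"), c(1, 1, 0))
    g2 <- buildFactorGraph(co)
    expectMarginalsEqual(runInference(g2, tightConfig()),
                         exactMarginals(g2), 0.05, tolVariant = 0.07)
})

test_that("directed prior factors honour their contracts", {
    pc <- PriorConfig()
    net <- GeneNetwork(cbind("A", "B"))
    pri <- buildPairPriors(net, pc)
    m <- matrix(0, 1, 2, dimnames = list("v1", c("s1", "s2")))
    m[1, 1] <- 1
    co <- VariantCohort(m, c(v1 = "B"), phenotype = c(s1 = 1, s2 = 0))
    g <- buildFactorGraph(co, pri, ModelConfig(gamma = 1), pc)
    # neighbour clamped off: focal gene sits exactly at its prior
    offFit <- runInference(g, tightConfig(), clamp = c(B = 0))
    expect_equal(unname(geneMarginals(offFit)["A"]), pc@tau,
                 tolerance = 1e-9)
    # neighbour clamped on: evidence is positive but capped below ceiling
    onFit <- runInference(g, tightConfig(), clamp = c(B = 1))
    expect_gt(geneMarginals(onFit)["A"], pc@tau)
    expect_lte(geneMarginals(onFit)["A"], pc@ceiling + 1e-12)
})

test_that("network context alone never exceeds the marginal ceiling", {
    pc <- PriorConfig()
    # exhaustive neighbour-state enumeration on graphs of <= 10 genes
    graphs <- list(
        star9 = GeneNetwork(cbind("focal", paste0("n", 1:9))),
        k5 = GeneNetwork(t(combn(c("focal", paste0("n", 1:4)), 2))),
        path = GeneNetwork(cbind(c("focal", "n1", "n2"),
                                 c("n1", "n2", "n3"))))
    for (gname in names(graphs)) {
        net <- graphs[[gname]]
        pri <- buildPairPriors(net, pc)
        nbs <- setdiff(networkGenes(net), "focal")
        co <- makeEmptyCohort(2, c(1, 0))
        g <- buildFactorGraph(co, pri, ModelConfig(), pc)
        worst <- 0
        for (mask in 0:(2^length(nbs) - 1)) {
            states <- as.numeric(bitwAnd(mask, 2^(seq_along(nbs) - 1)) > 0)
            fit <- runInference(g, clamp = setNames(states, nbs))
            worst <- max(worst, geneMarginals(fit)["focal"])
        }
        expect_lte(worst, pc@ceiling + 1e-9)
        expect_lt(worst, pc@detectionThreshold)
    }
})

test_that("inference is deterministic and convergence is recorded", {
    g <- buildFactorGraph(makeLoopyCohort())
    f1 <- runInference(g)
    f2 <- runInference(g)
    expect_identical(geneMarginals(f1), geneMarginals(f2))
    expect_identical(variantMarginals(f1), variantMarginals(f2))
    ci <- convergenceInfo(f1)
    expect_true(ci$converged)
    expect_equal(nrow(ci$trace), ci$iterations)
    # converged: the final recorded sweep change is below tolerance
    expect_lt(ci$trace$maxDelta[ci$iterations], 1e-4)
})

test_that("emitted distributions are normalized and marginals valid", {
    g <- buildFactorGraph(makeLoopyCohort())
    fit <- runInference(g)
    sg <- fit@sampleGeneMarginals
    expect_true(all(abs(rowSums(sg[, c("g0", "g1", "g2")]) - 1) < 1e-12))
    expect_true(all(geneMarginals(fit) >= 0 & geneMarginals(fit) <= 1))
    expect_true(all(variantMarginals(fit) >= 0 & variantMarginals(fit) <= 1))
})

test_that("patient aberration ranking orders carried variants by posterior", {
    m <- matrix(0, 3, 2)
    m[1, 1] <- 1; m[2, 1] <- 1; m[3, 2] <- 1
    co <- makeCohort(m, c("A", "B", "B"), c(1, 0))
    g <- buildFactorGraph(co)
    fit <- runInference(g, tightConfig())
    rk <- rankPatientAberrations(fit, co, "s1")
    expect_equal(nrow(rk), 2L)
    expect_true(all(diff(rk$posterior) <= 0))
    expect_identical(sort(rk$variant), c("v1", "v2"))
    # individual with no carried variants -> empty ranking
    m2 <- rbind(m, 0)
    co2 <- makeCohort(m2, c("A", "B", "B", "A"), c(1, 0))
    g2 <- buildFactorGraph(co2)
    fit2 <- runInference(g2)
    expect_equal(nrow(rankPatientAberrations(fit2, co2, "s2")), 1L)
    expect_error(rankPatientAberrations(fit, co, "nobody"), "unknown")
})

test_that("inner loop respects its caps", {
    # oscillation-prone fixture with zero inner tolerance: the trace exists
    # and the fit still returns; the cap bounds work per outer sweep
    g <- buildFactorGraph(makeLoopyCohort())
    cfgFast <- InferenceConfig(innerLoopMax = 1, outerMaxIterations = 500,
                               convergenceTol = 1e-8)
    cfgDeep <- InferenceConfig(innerLoopMax = 10, outerMaxIterations = 500,
                               convergenceTol = 1e-8)
    f1 <- runInference(g, cfgFast)
    f2 <- runInference(g, cfgDeep)
    # both schedules converge to the same fixed point
    expectMarginalsEqual(f1, f2, 1e-6)
    # deeper inner loops need no more outer sweeps
    expect_lte(convergenceInfo(f2)$iterations,
               convergenceInfo(f1)$iterations)
})
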