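popConfigSmall <- function() {
    PopulationConfig(nGenes = 50, nIndividuals = 2000, variantsPerGene = 8)
}

test_that("population simulation is reproducible and rare-skewed", {
    cfg <- PopulationConfig(nGenes = 100, nIndividuals = 20000,
                            variantsPerGene = 10)
    p1 <- simulatePopulation(cfg, seed = 5)
    p2 <- simulatePopulation(cfg, seed = 5)
    expect_identical(as.matrix(genotypeCounts(p1$cohort)),
                     as.matrix(genotypeCounts(p2$cohort)))
    expect_identical(p1$truthHarmful, p2$truthHarmful)
    # >= 90% of variants have sample allele frequency < 1%
    af <- Matrix::rowSums(genotypeCounts(p1$cohort)) /
        (2 * ncol(p1$cohort))
    expect_gte(mean(af < 0.01), 0.9)
    expect_true(all(genotypeCounts(p1$cohort)@x %in% c(1, 2)))
})

test_that("zero deleterious fraction yields zero causal burden", {
    cfg <- PopulationConfig(nGenes = 20, nIndividuals = 500,
                            variantsPerGene = 5, deleteriousFraction = 0)
    p <- simulatePopulation(cfg, seed = 2)
    expect_false(any(p$truthHarmful))
    expect_error(assignDiseaseStatus(p$cohort, p$truthHarmful,
                                     unique(variantGenes(p$cohort))[1:3],
                                     topK = 10),
                 "no signal")
})

test_that("neighbourhood causal sets stay within distance 2 of a seed", {
    net <- generateSyntheticNetwork(300, seed = 3, cliqueSize = 12,
                                    starLeaves = 20, pathLength = 12)
    cs <- selectCausalNeighbourhood(net, P = 8, seed = 4)
    expect_length(cs, 8L)
    expect_identical(cs, selectCausalNeighbourhood(net, P = 8, seed = 4))
    # all pairs within distance 4 of each other (shared seed, distance 2)
    dd <- igraph::distances(net@graph, cs, cs)
    expect_lte(max(dd), 4)
    # P larger than every neighbourhood errors
    expect_error(selectCausalNeighbourhood(net, P = 301), "neighbourhood")
})

test_that("star selection returns the periphery and excludes the center", {
    net <- GeneNetwork(cbind("hub", paste0("l", 1:12)))
    cs <- selectStar(net, "hub")
    expect_length(cs, 12L)
    expect_false("hub" %in% cs)
    expect_error(selectStar(GeneNetwork(nodes = c("x", "y")), "x"),
                 "isolated")
})

test_that("clique selection samples fractions of the largest clique", {
    net <- generateSyntheticNetwork(300, seed = 9, cliqueSize = 36,
                                    starLeaves = 20, pathLength = 12)
    third <- selectClique(net, fraction = 1 / 3, seed = 1)
    half <- selectClique(net, fraction = 1 / 2, seed = 1)
    expect_length(third, 12L)
    expect_length(half, 18L)
    # selected genes are mutually adjacent
    sub <- igraph::induced_subgraph(net@graph, half)
    expect_equal(igraph::ecount(sub), choose(18, 2))
})

test_that("chain selection obeys all four chain rules", {
    path <- GeneNetwork(cbind(c("A", "B", "C"), c("B", "C", "D")))
    ch <- selectChain(path, 4, seed = 1)
    expect_true(identical(ch, c("A", "B", "C", "D")) ||
                identical(ch, c("D", "C", "B", "A")))

    tri <- GeneNetwork(cbind(c("A", "B", "C"), c("B", "C", "A")))
    expect_error(selectChain(tri, 3, maxRestarts = 5), "could not build")

    net <- generateSyntheticNetwork(400, seed = 13, cliqueSize = 12,
                                    starLeaves = 20, pathLength = 25)
    for (len in c(10, 20)) {
        ch <- selectChain(net, len, seed = 2)
        expect_length(ch, len)
        g <- net@graph
        for (k in seq_len(len - 1))
            expect_true(igraph::are_adjacent(g, ch[k], ch[k + 1]))
        for (k in 3:len) {
            earlier <- ch[seq_len(k - 2)]
            nb <- igraph::neighbors(g, ch[k])$name
            expect_false(any(earlier %in% nb))
        }
        degs <- geneDegrees(net)[ch[2:(len - 1)]]
        expect_true(all(degs >= 2))
    }
})

test_that("disease status ranks by causal harmful burden with id tie-breaks", {
    m <- matrix(0, 2, 4)
    m[1, 2] <- 2; m[1, 3] <- 1
    co <- makeCohort(m, c("A", "B"), c(0, 0, 0, 0))
    lab <- assignDiseaseStatus(co, c(v1 = TRUE, v2 = TRUE), "A", topK = 1)
    expect_equal(unname(lab[c("s2", "s1", "s3")]), c(1L, 0L, 0L))
    # ties at the boundary resolved by individual id
    m2 <- matrix(0, 1, 3); m2[1, ] <- 1
    co2 <- makeCohort(m2, "A", c(0, 0, 0))
    lab2 <- assignDiseaseStatus(co2, c(v1 = TRUE), "A", topK = 2)
    expect_equal(unname(lab2[c("s1", "s2", "s3")]), c(1L, 1L, 0L))
})

test_that("case/control sampling balances strata and drops monomorphic variants", {
    cfg <- popConfigSmall()
    p <- simulatePopulation(cfg, seed = 6)
    causal <- unique(variantGenes(p$cohort))[1:5]
    lab <- assignDiseaseStatus(p$cohort, p$truthHarmful, causal, topK = 150)
    cc <- sampleCaseControl(p$cohort, lab, n = 100, seed = 6)
    ph <- phenotypeLabels(cc)
    expect_equal(sum(ph == 1), 50L)
    expect_equal(sum(ph == 0), 50L)
    expect_true(all(Matrix::rowSums(genotypeCounts(cc)) > 0))
    cc2 <- sampleCaseControl(p$cohort, lab, n = 100, seed = 6)
    expect_identical(colnames(cc), colnames(cc2))
    expect_error(sampleCaseControl(p$cohort, lab, n = 1000, seed = 1),
                 "stratum")
})

test_that("synthetic networks have hubs, planted motifs and heavy tails", {
    net <- generateSyntheticNetwork(1000, seed = 1)
    degs <- geneDegrees(net)
    expect_gte(max(degs), 50)
    expect_lte(median(degs), 5)
    expect_length(networkGenes(net), 1000L)
    # planted 36-clique is retrievable as the largest clique
    expect_length(selectClique(net, fraction = 1), 36L)
    net2 <- generateSyntheticNetwork(1000, seed = 1)
    expect_identical(networkEdges(net), networkEdges(net2))
})

test_that("simulated cohorts separate cases from controls by causal burden", {
    cfg <- PopulationConfig(nGenes = 120, nIndividuals = 4000,
                            variantsPerGene = 12)
    net <- generateSyntheticNetwork(120, seed = 21, cliqueSize = 10,
                                    starLeaves = 12, pathLength = 10)
    for (seed in c(31, 32)) {
        sc <- simulateScenario(net, cfg, P = 6, n = 120, topK = 300,
                               seed = seed)
        harm <- sc@truthHarmful[rownames(sc@cohort)]
        vg <- variantGenes(sc@cohort)
        sel <- which(vg %in% sc@causalGenes & harm)
        burden <- Matrix::colSums(genotypeCounts(sc@cohort)[sel, , drop = FALSE])
        ph <- phenotypeLabels(sc@cohort)
        expect_gt(mean(burden[ph == 1]), mean(burden[ph == 0]))
        # non-causal burden indistinguishable between strata
        other <- which(!(vg %in% sc@causalGenes) & harm)
        ob <- Matrix::colSums(genotypeCounts(sc@cohort)[other, , drop = FALSE])
        expect_gt(wilcox.test(ob[ph == 1], ob[ph == 0])$p.value, 0.001)
    }
})
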