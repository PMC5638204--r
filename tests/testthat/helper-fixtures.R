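# Programmatic fixtures shared across the suite.

# cohort with an explicit dense genotype matrix
makeCohort <- function(counts, genes, pheno) {
    vnames <- paste0("v", seq_len(nrow(counts)))
    snames <- paste0("s", seq_len(ncol(counts)))
    dimnames(counts) <- list(vnames, snames)
    VariantCohort(counts, setNames(genes, vnames),
                  phenotype = setNames(pheno, snames))
}

# tree-structured fixture: every variant carried by exactly one individual
# and the gene/individual incidence acyclic, so BP is exact
makeTreeCohort <- function() {
    m <- matrix(0, 4, 3)
    m[1, 1] <- 1   # gene A, s1
    m[2, 2] <- 2   # gene A, s2
    m[3, 2] <- 1   # gene A, s2 (same pair, extra variant)
    m[4, 3] <- 1   # gene B, s3
    makeCohort(m, c("A", "A", "A", "B"), c(1, 1, 0))
}

# loopy (network-free) fixture: shared carriers create cycles through the
# phenotype factors
makeLoopyCohort <- function() {
    m <- matrix(0, 3, 3)
    m[1, c(1, 3)] <- 1   # gene A carried by s1 and s3
    m[2, 2] <- 2         # gene A
    m[3, c(2, 3)] <- 1   # gene B carried by s2 and s3
    makeCohort(m, c("A", "A", "B"), c(1, 1, 0))
}

# cohort with no variants at all (pure-network inference)
makeEmptyCohort <- function(nIndiv = 2, pheno = rep(0, nIndiv)) {
    m <- matrix(0, 0, nIndiv,
                dimnames = list(character(0), paste0("s", seq_len(nIndiv))))
    VariantCohort(m, character(0),
                  phenotype = setNames(pheno, colnames(m)))
}

# variant tolerance defaults to the gene tolerance; loopy fixtures document
# a looser bound for the variant tier (see the methods vignette)
expectMarginalsEqual <- function(a, b, tol, tolVariant = tol) {
    expect_lt(max(abs(geneMarginals(a) - geneMarginals(b))), tol)
    if (length(variantMarginals(a)))
        expect_lt(max(abs(variantMarginals(a) - variantMarginals(b))),
                  tolVariant)
}

tightConfig <- function() {
    InferenceConfig(convergenceTol = 1e-10, innerTol = 1e-10,
                    outerMaxIterations = 2000)
}
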