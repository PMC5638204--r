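## Factor-graph assembly.  Variables follow the hierarchical model:
##   X_i  binary   harmfulness of variant i (shared across individuals)
##   Y_ij ternary  X_i * D_ij, present only where the genotype D_ij > 0
##   Q_gj ternary  dysfunction level of gene g in individual j
##   H_g  binary   gene-disease indicator (the main output)
##   G_gj ternary  H_g * Q_gj, gene relevance in individual j
##   pheno_j       observed case/control label
## Factors: P(X)=0.5, the deterministic Y link, phi2(Q|Y), the indicator
## phi3(G,H,Q) = 1[G = H*Q], the noisy-OR phi4(pheno | #active G), the gene
## prior tau, the geometric cardinality penalty rho and the directed
## pairwise network priors.

#' Model-level configuration
#'
#' @slot epsQ probability mass leaked off the deterministic value of the
#'   gene-dysfunction CPT (default 0.01); keeps all messages strictly
#'   positive.
#' @slot penetrance per-active-gene probability of disease in the noisy-OR
#'   phenotype factor (default 0.7).
#' @slot backgroundRate probability of disease with zero active genes
#'   (phenocopy rate, default 0.01).
#' @slot gamma multiplicative sparsity penalty per active gene in the
#'   cardinality prior \eqn{\rho(k) = \gamma^k} (default 0.9; 1 disables
#'   regularization).
#' @slot xPrior prior on variant harmfulness (default 0.5, uninformative).
#' @export
setClass("ModelConfig", representation(
    epsQ = "numeric", penetrance = "numeric", backgroundRate = "numeric",
    gamma = "numeric", xPrior = "numeric"))

setValidity("ModelConfig", function(object) {
    p <- c(object@epsQ, object@penetrance, object@backgroundRate,
           object@xPrior)
    if (any(p <= 0) || any(p >= 1))
        return("epsQ, penetrance, backgroundRate and xPrior must be in (0,1)")
    if (object@gamma <= 0 || object@gamma > 1)
        return("gamma must be in (0, 1]")
    TRUE
})

#' @rdname ModelConfig-class
#' @param epsQ,penetrance,backgroundRate,gamma,xPrior see the class slots.
#' @return a \code{ModelConfig}.
#' @export
ModelConfig <- function(epsQ = 0.01, penetrance = 0.7,
                        backgroundRate = 0.01, gamma = 0.9, xPrior = 0.5) {
    new("ModelConfig", epsQ = epsQ, penetrance = penetrance,
        backgroundRate = backgroundRate, gamma = gamma, xPrior = xPrior)
}

#' Gene-dysfunction CPT
#'
#' Distribution of the gene dysfunction level Q given the functional-variant
#' states Y of one gene in one individual: the mode sits at
#' \eqn{S = \min(2, \sum Y)} with mass \code{1 - epsQ}, the leak \code{epsQ}
#' split uniformly over the two remaining states.
#'
#' @param yValues integer vector (possibly empty) of Y values in \{0,1,2\}.
#' @param config a [ModelConfig-class].
#' @return numeric length-3 distribution over Q = 0, 1, 2.
#' @examples
#' phi2Distribution(c(1, 1))  # mode at Q = 2
#' @export
phi2Distribution <- function(yValues, config = ModelConfig()) {
    stopifnot(all(yValues %in% 0:2))
    s <- min(2L, sum(yValues))
    p <- rep(config@epsQ / 2, 3)
    p[s + 1L] <- 1 - config@epsQ
    p
}

## CPT matrix P(Q = q | S = s), rows s = 0..2, cols q = 0..2 (symmetric).
phi2Matrix <- function(epsQ) {
    m <- matrix(epsQ / 2, 3, 3)
    diag(m) <- 1 - epsQ
    m
}

#' Gene-relevance indicator factor
#'
#' \eqn{\phi_3(G, H, Q) = 1[G = H \cdot Q]}: a gene can only be relevant in
#' an individual if it is disease associated overall (H = 1) and dysfunctional
#' in that individual (Q > 0).
#'
#' @param g,h,q states (vectors recycle): g, q in \{0,1,2\}, h in \{0,1\}.
#' @return 0/1 indicator values.
#' @export
phi3Indicator <- function(g, h, q) {
    stopifnot(all(g %in% 0:2), all(h %in% 0:1), all(q %in% 0:2))
    as.numeric(g == h * q)
}

#' Phenotype factor (noisy-OR)
#'
#' \eqn{P(\mathrm{case} \mid c) = 1 - (1 - \epsilon_{bg})(1 -
#' p_{pen})^{c}} where c is the number of relevant genes (G >= 1) in the
#' individual: a patient is expected to have some affected genes, a healthy
#' individual few or none.
#'
#' @param pheno 0 (control) or 1 (case).
#' @param activeCount non-negative count(s) of active G variables.
#' @param config a [ModelConfig-class].
#' @return potential value(s) \eqn{P(pheno \mid c)}.
#' @examples
#' phi4Potential(1, 0)  # background rate
#' phi4Potential(1, 1)  # 1 - 0.99 * 0.3
#' @export
phi4Potential <- function(pheno, activeCount, config = ModelConfig()) {
    stopifnot(all(pheno %in% 0:1), all(activeCount >= 0))
    pCase <- 1 - (1 - config@backgroundRate) *
        (1 - config@penetrance)^activeCount
    ifelse(pheno == 1, pCase, 1 - pCase)
}

#' Sparsity (cardinality) potential
#'
#' Geometric penalty \eqn{\rho(k) = \gamma^k} on the number of active gene
#' indicators; log-linear, so it composes exactly with counting-factor
#' message passing (and factorizes into per-gene unaries).
#'
#' @param kActive count(s) of genes with H = 1.
#' @param config a [ModelConfig-class].
#' @return potential value(s).
#' @export
sparsityPotential <- function(kActive, config = ModelConfig()) {
    stopifnot(all(kActive >= 0))
    config@gamma^kActive
}

#' Assemble the factor graph
#'
#' Builds the full model from a cohort, the directed pairwise network priors
#' and the configuration.  Variable support is pruned to the data: Y, Q and
#' G nodes exist only for (gene, individual) pairs with at least one carried
#' variant; every gene with a variant or a prior edge gets an H node; each
#' individual gets one phenotype factor; the cardinality prior is global.
#'
#' @param cohort a [VariantCohort-class] with phenotype labels.
#' @param pairPriors data.frame from [buildPairPriors()] (may be empty).
#' @param modelConfig a [ModelConfig-class].
#' @param priorConfig a [PriorConfig-class].
#' @return a \code{FactorGraph} object (opaque; pass to [runInference()] or
#'   [exactMarginals()]).
#' @export
buildFactorGraph <- function(cohort, pairPriors = NULL,
                             modelConfig = ModelConfig(),
                             priorConfig = PriorConfig()) {
    stopifnot(is(cohort, "VariantCohort"))
    validObject(modelConfig); validObject(priorConfig)
    if (is.null(pairPriors))
        pairPriors <- data.frame(source = character(0), target = character(0),
                                 delta = numeric(0))
    counts <- genotypeCounts(cohort)
    vg <- variantGenes(cohort)
    pheno <- phenotypeLabels(cohort)
    if (anyNA(pheno))
        stop("phenotype labels are required to build the factor graph")

    genes <- sort(unique(c(vg, pairPriors$source, pairPriors$target)))
    orphan <- setdiff(unique(c(pairPriors$source, pairPriors$target)), genes)
    if (length(orphan))
        warning("dropping prior genes absent from data and network: ",
                paste(orphan, collapse = ", "))

    ## sparse triplets of carried genotypes (force general storage: a
    ## symmetric-looking matrix must not collapse to one triangle)
    tm <- as(as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
             "CsparseMatrix")
    trip <- as.data.frame(Matrix::summary(tm))  # i = variant, j = indiv, x = dose
    trip <- trip[order(trip$j, trip$i), , drop = FALSE]
    variants <- rownames(cohort)
    indivs <- colnames(cohort)

    geneOfVar <- match(vg, genes)        # per variant index -> gene index
    pairKey <- paste(geneOfVar[trip$i], trip$j)
    pairId <- match(pairKey, unique(pairKey))
    nPairs <- length(unique(pairKey))
    firstOf <- !duplicated(pairId)
    pairGene <- geneOfVar[trip$i][firstOf]
    pairIndiv <- trip$j[firstOf]
    ## incidences sorted by pair, with within-pair positions, so the
    ## engine's ragged convolutions can run position-by-position
    ord <- order(pairId, trip$i)
    incVariant <- trip$i[ord]
    incPair <- pairId[ord]
    incDose <- as.integer(trip$x)[ord]
    incPos <- if (length(incPair)) {
        stats::ave(seq_along(incPair), incPair, FUN = seq_along)
    } else integer(0)

    thetaSrc <- match(pairPriors$source, genes)
    thetaTgt <- match(pairPriors$target, genes)
    ## index of the reverse directed edge (always present by construction)
    revIdx <- match(paste(thetaTgt, thetaSrc), paste(thetaSrc, thetaTgt))

    structure(class = "FactorGraph", list(
        genes = genes, variants = variants, individuals = indivs,
        pheno = as.integer(pheno),
        incid = data.frame(variant = incVariant, pair = incPair,
                           dose = incDose, pos = as.integer(incPos)),
        pairGene = pairGene, pairIndiv = pairIndiv, nPairs = nPairs,
        theta = data.frame(src = thetaSrc, tgt = thetaTgt,
                           delta = pairPriors$delta, rev = revIdx),
        modelConfig = modelConfig, priorConfig = priorConfig))
}

#' @export
print.FactorGraph <- function(x, ...) {
    cat("FactorGraph:", length(x$genes), "H nodes,", length(x$variants),
        "X nodes,", x$nPairs, "Q/G pairs,", nrow(x$incid), "Y links,",
        nrow(x$theta), "directed pair priors,", length(x$individuals),
        "phenotype factors\n")
    invisible(x)
}

#' Joint density of a complete assignment
#'
#' Unnormalized model density evaluated at a full configuration; used by the
#' exhaustive-enumeration oracle and for term-by-term checks.  G is the
#' deterministic product H*Q and Y the product X*D, so only X, H and Q are
#' free.
#'
#' @param graph a \code{FactorGraph}.
#' @param x binary vector over variants; \code{h} binary over genes;
#'   \code{q} vector in \{0,1,2\} over the graph's (gene, individual) pairs.
#' @param h,q see \code{x}.
#' @return the unnormalized joint density (numeric scalar).
#' @export
jointDensity <- function(graph, x, h, q) {
    mc <- graph$modelConfig; pc <- graph$priorConfig
    stopifnot(length(x) == length(graph$variants),
              length(h) == length(graph$genes),
              length(q) == graph$nPairs)
    ## phi2 per pair: S = min(2, sum of x * dose)
    s <- rep(0L, graph$nPairs)
    on <- x[graph$incid$variant] == 1
    if (any(on)) {
        sums <- rowsum(graph$incid$dose * on, graph$incid$pair)
        s[as.integer(rownames(sums))] <- pmin(2L, as.integer(sums))
    }
    cpt <- phi2Matrix(mc@epsQ)
    phi2 <- prod(cpt[cbind(s + 1L, q + 1L)])
    ## phenotype: count of active G = H*Q per individual
    g <- h[graph$pairGene] * q
    cActive <- rep(0L, length(graph$individuals))
    if (graph$nPairs) {
        cs <- rowsum(as.integer(g >= 1), graph$pairIndiv)
        cActive[as.integer(rownames(cs))] <- as.integer(cs)
    }
    phi4 <- prod(phi4Potential(graph$pheno, cActive, mc))
    ## priors on X and H
    px <- prod(ifelse(x == 1, mc@xPrior, 1 - mc@xPrior))
    ph <- prod(ifelse(h == 1, pc@tau, 1 - pc@tau)) *
        sparsityPotential(sum(h), mc)
    theta <- 1
    if (nrow(graph$theta)) {
        srcOn <- h[graph$theta$src] == 1
        tgtOn <- h[graph$theta$tgt] == 1
        pr <- ifelse(srcOn, ifelse(tgtOn, graph$theta$delta,
                                   1 - graph$theta$delta), 0.5)
        theta <- prod(pr)
    }
    px * ph * theta * phi2 * phi4
}
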