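## Synthetic rare-variant case/control scenarios with network-embedded
## causal gene sets.  Genotypes come from a parametric rare-skewed site
## frequency spectrum (bounded Pareto allele frequencies, Hardy-Weinberg
## sampling); disease status is assigned by ranking individuals on their
## harmful-allele burden inside the causal mechanism and taking the top k
## as the patient subpopulation, from which cases are drawn.

#' Population simulation settings
#'
#' Defaults are the desk-scale study conditions: 1000 genes, a population of
#' 20000 individuals, a Poisson(30) number of variants per gene, allele
#' frequencies from a bounded Pareto spectrum on \[1/(2N), 0.01\] with shape
#' 0.25, and 20\% of variants labeled harmful (standing in for a selection
#' coefficient above the deleteriousness cutoff).
#'
#' @slot nGenes,nIndividuals population dimensions.
#' @slot variantsPerGene Poisson mean of variants per gene.
#' @slot mafShape bounded-Pareto shape of the allele-frequency spectrum
#'   (smaller = heavier rare tail).
#' @slot mafMin,mafMax frequency bounds; \code{mafMin = NA} means
#'   \code{1/(2 nIndividuals)}.
#' @slot deleteriousFraction per-variant probability of the harmful label.
#' @export
setClass("PopulationConfig", representation(
    nGenes = "numeric", nIndividuals = "numeric",
    variantsPerGene = "numeric", mafShape = "numeric",
    mafMin = "numeric", mafMax = "numeric",
    deleteriousFraction = "numeric"))

setValidity("PopulationConfig", function(object) {
    if (object@nGenes < 1 || object@nIndividuals < 1 ||
        object@variantsPerGene <= 0)
        return("population counts must be positive")
    mx <- object@mafMax
    if (mx <= 0 || mx > 0.5)
        return("mafMax must be in (0, 0.5]")
    if (object@deleteriousFraction < 0 || object@deleteriousFraction > 1)
        return("deleteriousFraction must be in [0, 1]")
    TRUE
})

#' @rdname PopulationConfig-class
#' @param nGenes,nIndividuals,variantsPerGene,mafShape,mafMin,mafMax,deleteriousFraction
#'   see the class slots.
#' @return a \code{PopulationConfig}.
#' @export
PopulationConfig <- function(nGenes = 1000, nIndividuals = 20000,
                             variantsPerGene = 30, mafShape = 0.25,
                             mafMin = NA_real_, mafMax = 0.01,
                             deleteriousFraction = 0.2) {
    new("PopulationConfig", nGenes = nGenes, nIndividuals = nIndividuals,
        variantsPerGene = variantsPerGene, mafShape = mafShape,
        mafMin = mafMin, mafMax = mafMax,
        deleteriousFraction = deleteriousFraction)
}

## bounded Pareto quantile sampling (shape a on [lo, hi]); a -> 0 tends to
## the log-uniform spectrum
rBoundedPareto <- function(n, a, lo, hi) {
    u <- runif(n)
    if (abs(a) < 1e-12) return(lo * (hi / lo)^u)
    (lo^-a - u * (lo^-a - hi^-a))^(-1 / a)
}

#' Simulate a rare-variant population
#'
#' Per-variant allele frequencies are drawn from the bounded-Pareto
#' spectrum, genotypes independently per individual as Binomial(2, f)
#' (Hardy-Weinberg), and harmful labels as Bernoulli(deleteriousFraction).
#' Genotypes are returned sparse.
#'
#' @param config a [PopulationConfig-class].
#' @param geneIds optional gene identifiers (length \code{nGenes}); defaults
#'   to \code{g0001...}.
#' @param seed integer seed; the simulation is fully reproducible from it.
#' @return list with \code{cohort} (a [VariantCohort-class] without
#'   phenotypes), \code{truthHarmful} (named logical) and \code{maf} (the
#'   drawn frequencies).
#' @export
simulatePopulation <- function(config = PopulationConfig(), geneIds = NULL,
                               seed = 1) {
    validObject(config)
    set.seed(seed)
    nG <- as.integer(config@nGenes); nI <- as.integer(config@nIndividuals)
    if (is.null(geneIds))
        geneIds <- sprintf("g%04d", seq_len(nG))
    stopifnot(length(geneIds) == nG)
    nVarPerGene <- pmax(1L, rpois(nG, config@variantsPerGene))
    nV <- sum(nVarPerGene)
    gene <- rep(geneIds, nVarPerGene)
    variants <- sprintf("v%06d", seq_len(nV))
    lo <- if (is.na(config@mafMin)) 1 / (2 * nI) else config@mafMin
    maf <- rBoundedPareto(nV, config@mafShape, lo, config@mafMax)
    harmful <- runif(nV) < config@deleteriousFraction

    ## genotype sampling: per variant draw het/hom carrier counts, then
    ## carrier indices (sparse triplets)
    nHet <- rbinom(nV, nI, 2 * maf * (1 - maf))
    nHom <- rbinom(nV, nI, maf^2)
    tot <- nHet + nHom
    keep <- which(tot > 0)
    ii <- integer(0); jj <- integer(0); xx <- integer(0)
    if (length(keep)) {
        carr <- lapply(keep, function(v) sample.int(nI, min(tot[v], nI)))
        ii <- rep.int(keep, lengths(carr))
        jj <- unlist(carr, use.names = FALSE)
        xx <- unlist(lapply(seq_along(keep), function(k) {
            v <- keep[k]
            nh <- min(tot[v], nI)
            c(rep.int(2L, min(nHom[v], nh)),
              rep.int(1L, max(nh - nHom[v], 0L)))
        }), use.names = FALSE)
    }
    counts <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                   dims = c(nV, nI),
                                   dimnames = list(variants,
                                                   sprintf("i%06d", seq_len(nI))))
    cohort <- VariantCohort(counts, variantGene = setNames(gene, variants))
    list(cohort = cohort,
         truthHarmful = setNames(harmful, variants),
         maf = setNames(maf, variants))
}

#' Sample a causal gene set from a network neighbourhood
#'
#' Randomly picks a seed gene whose joint first- and second-degree
#' neighbourhood (including itself) exceeds \code{P}, then draws \code{P}
#' causal genes from that neighbourhood.
#'
#' @param network a [GeneNetwork-class].
#' @param P number of causal genes.
#' @param seed integer seed.
#' @return character vector of P gene ids, all within distance 2 of the
#'   chosen seed gene.
#' @export
selectCausalNeighbourhood <- function(network, P, seed = 1) {
    set.seed(seed)
    g <- network@graph
    sizes <- igraph::ego_size(g, order = 2)
    eligible <- which(sizes > P)
    if (!length(eligible))
        stop("no seed gene has a distance-2 neighbourhood larger than P = ", P)
    seedGene <- sample(eligible, 1L)
    nb <- igraph::ego(g, order = 2, nodes = seedGene)[[1L]]$name
    sort(sample(nb, P))
}

#' Star-topology causal set
#'
#' The neighbours of \code{center} are causal; the center itself is not.
#'
#' @param network a [GeneNetwork-class].
#' @param center gene id of the star center.
#' @return character vector of causal genes (the center's neighbours).
#' @export
selectStar <- function(network, center) {
    g <- network@graph
    if (!center %in% networkGenes(network)) stop("unknown center: ", center)
    nb <- igraph::neighbors(g, center)$name
    if (!length(nb)) stop("star center '", center, "' is isolated")
    sort(nb)
}

#' Clique-topology causal set
#'
#' Finds the largest clique in the network and samples
#' \code{ceiling(fraction * size)} of its members as causal.
#'
#' @param network a [GeneNetwork-class].
#' @param fraction fraction of the clique to mark causal (e.g. 1/3, 1/2).
#' @param seed integer seed.
#' @return character vector of causal genes (subset of the largest clique).
#' @export
selectClique <- function(network, fraction = 0.5, seed = 1) {
    set.seed(seed)
    cl <- igraph::largest_cliques(network@graph)
    if (!length(cl) || length(cl[[1L]]) < 4L)
        stop("no clique of size >= 4 in the network")
    members <- sort(cl[[1L]]$name)
    sort(sample(members, ceiling(fraction * length(members))))
}

#' Chain-topology causal set
#'
#' Grows an induced chain: each new gene is adjacent to the last selected
#' gene, has no edges to any earlier selection except the last, candidates
#' are taken in ascending degree (ties by id), and every internal pick needs
#' degree at least 2.  Dead ends trigger a restart from a new seed gene, up
#' to \code{maxRestarts}.
#'
#' @param network a [GeneNetwork-class].
#' @param length chain length requested.
#' @param seed integer seed.
#' @param maxRestarts restart budget.
#' @return ordered character vector of chain genes (consecutive entries
#'   adjacent).
#' @export
selectChain <- function(network, length, seed = 1, maxRestarts = 50) {
    set.seed(seed)
    g <- network@graph
    degs <- geneDegrees(network)
    ids <- networkGenes(network)
    if (!base::length(ids)) stop("empty network")
    best <- character(0)
    for (attempt in seq_len(maxRestarts)) {
        chain <- sample(ids, 1L)
        while (base::length(chain) < length) {
            last <- chain[base::length(chain)]
            cand <- igraph::neighbors(g, last)$name
            cand <- setdiff(cand, chain)
            ## no edges back to anything but the last pick
            if (base::length(cand) && base::length(chain) > 1L) {
                earlier <- chain[-base::length(chain)]
                ok <- vapply(cand, function(cn) {
                    !any(earlier %in% igraph::neighbors(g, cn)$name)
                }, logical(1))
                cand <- cand[ok]
            }
            ## internal genes must be able to continue: degree >= 2
            if (base::length(chain) + 1L < length)
                cand <- cand[degs[cand] >= 2]
            if (!base::length(cand)) break
            cand <- cand[order(degs[cand], cand)]
            chain <- c(chain, cand[1L])
        }
        if (base::length(chain) >= length) return(chain[seq_len(length)])
        if (base::length(chain) > base::length(best)) best <- chain
    }
    stop("could not build a chain of length ", length, " after ",
         maxRestarts, " restarts (longest achieved: ", base::length(best), ")")
}

#' Assign population disease status by causal burden
#'
#' Each individual's burden is the summed allele count over harmful variants
#' in causal genes; the \code{topK} largest burdens are labeled diseased
#' (ties at the boundary broken by individual id), everyone else healthy.
#'
#' @param cohort population [VariantCohort-class].
#' @param truthHarmful named logical over variants.
#' @param causalGenes character vector of causal gene ids.
#' @param topK number of patients.
#' @return named integer vector of population labels (1 = diseased).
#' @export
assignDiseaseStatus <- function(cohort, truthHarmful, causalGenes, topK) {
    stopifnot(topK < ncol(cohort))
    vg <- variantGenes(cohort)
    sel <- which(vg %in% causalGenes & truthHarmful[names(vg)])
    burden <- if (length(sel))
        Matrix::colSums(genotypeCounts(cohort)[sel, , drop = FALSE])
    else rep(0, ncol(cohort))
    if (all(burden == 0))
        stop("no signal: all causal-gene harmful burdens are zero")
    ord <- order(-burden, colnames(cohort))
    labels <- setNames(integer(ncol(cohort)), colnames(cohort))
    labels[ord[seq_len(topK)]] <- 1L
    labels
}

#' Sample a case/control cohort
#'
#' Draws n/2 cases uniformly from the diseased subpopulation and n/2
#' controls from the healthy one, restricts the genotype matrix to the
#' sample and drops monomorphic variants.
#'
#' @param cohort population [VariantCohort-class].
#' @param populationLabels labels from [assignDiseaseStatus()].
#' @param n total (even) sample size.
#' @param seed integer seed.
#' @return a [VariantCohort-class] with phenotype labels.
#' @export
sampleCaseControl <- function(cohort, populationLabels, n, seed = 1) {
    stopifnot(n %% 2 == 0)
    set.seed(seed)
    cases <- names(populationLabels)[populationLabels == 1L]
    ctrls <- names(populationLabels)[populationLabels == 0L]
    if (length(cases) < n / 2 || length(ctrls) < n / 2)
        stop("stratum too small for n = ", n)
    pick <- c(sample(cases, n / 2), sample(ctrls, n / 2))
    sub <- cohort[, pick]
    poly <- Matrix::rowSums(genotypeCounts(sub)) > 0
    sub <- sub[poly, ]
    SummarizedExperiment::colData(sub)$phenotype <-
        as.integer(pick %in% cases)
    new("VariantCohort", sub)
}

#' Generate a synthetic scale-free-like gene network
#'
#' Preferential-attachment core plus planted motifs so every topology
#' sampler is exercisable: one large clique (size \code{cliqueSize}), one
#' hub star (\code{starLeaves} leaves) and one long low-degree path
#' (\code{pathLength} genes), each tied into the core.
#'
#' @param nGenes total gene count (>= 100).
#' @param seed integer seed.
#' @param cliqueSize,starLeaves,pathLength planted motif sizes.
#' @return a [GeneNetwork-class] on gene ids \code{g0001...}.
#' @export
generateSyntheticNetwork <- function(nGenes = 1000, seed = 1,
                                     cliqueSize = 36, starLeaves = 50,
                                     pathLength = 30) {
    stopifnot(nGenes >= cliqueSize + starLeaves + pathLength + 20)
    set.seed(seed)
    ids <- sprintf("g%04d", seq_len(nGenes))
    nCore <- nGenes - cliqueSize - pathLength - 1L
    core <- igraph::sample_pa(nCore, m = 2, directed = FALSE)
    coreEdges <- igraph::as_edgelist(core)
    edges <- cbind(ids[coreEdges[, 1]], ids[coreEdges[, 2]])
    ## planted clique on reserved ids, tied to the core
    cliqueIds <- ids[nCore + seq_len(cliqueSize)]
    cp <- t(utils::combn(cliqueIds, 2L))
    edges <- rbind(edges, cp, c(cliqueIds[1L], ids[1L]))
    ## hub star: reserved center, leaves sampled in the core
    center <- ids[nCore + cliqueSize + 1L]
    leaves <- ids[sample.int(nCore, starLeaves)]
    edges <- rbind(edges, cbind(center, leaves))
    ## low-degree path, one end tied to the core
    pathIds <- ids[nCore + cliqueSize + 1L + seq_len(pathLength)]
    edges <- rbind(edges,
                   cbind(pathIds[-pathLength], pathIds[-1L]),
                   c(pathIds[1L], ids[2L]))
    GeneNetwork(edges, nodes = ids)
}

#' Simulate a complete disease scenario
#'
#' End-to-end generator: population genotypes, causal gene set of the
#' requested topology, burden-ranked disease status and a sampled
#' case/control cohort.
#'
#' @param network a [GeneNetwork-class] whose genes name the simulated
#'   genes (its size must equal \code{config@nGenes}).
#' @param config a [PopulationConfig-class].
#' @param P causal gene count (neighbourhood/clique-fraction/chain-length
#'   meaning depends on topology).
#' @param n cohort size (cases + controls).
#' @param topK diseased subpopulation size (default 1000 at the default
#'   population scale).
#' @param topology one of \code{"neighbourhood"}, \code{"star"},
#'   \code{"clique"}, \code{"chain"}, \code{"explicit"}.
#' @param causalGenes explicit causal set (topology \code{"explicit"});
#'   star center for \code{"star"}.
#' @param seed integer seed driving every random draw.
#' @return a [DiseaseScenario-class].
#' @export
simulateScenario <- function(network, config = PopulationConfig(),
                             P = 10, n = 800, topK = 1000,
                             topology = c("neighbourhood", "star", "clique",
                                          "chain", "explicit"),
                             causalGenes = NULL, seed = 1) {
    topology <- match.arg(topology)
    ids <- networkGenes(network)
    stopifnot(length(ids) == config@nGenes)
    pop <- simulatePopulation(config, geneIds = ids, seed = seed)
    causal <- switch(topology,
        neighbourhood = selectCausalNeighbourhood(network, P, seed = seed + 1L),
        star = selectStar(network, causalGenes),
        clique = selectClique(network, fraction = P / 36, seed = seed + 1L),
        chain = selectChain(network, P, seed = seed + 1L),
        explicit = causalGenes)
    labels <- assignDiseaseStatus(pop$cohort, pop$truthHarmful, causal, topK)
    cc <- sampleCaseControl(pop$cohort, labels, n, seed = seed + 2L)
    new("DiseaseScenario", cohort = cc, causalGenes = sort(causal),
        truthHarmful = pop$truthHarmful, network = network,
        topology = topology)
}
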