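#' @import methods
#' @importFrom stats pbinom rbinom rpois runif setNames fisher.test p.adjust
#' @importFrom utils read.table write.table head
NULL

#' Gene interaction network
#'
#' Thin S4 wrapper around an undirected simple \pkg{igraph} graph over opaque
#' gene identifiers.  The network supplies degrees and neighbourhoods for the
#' calibrated pairwise priors; no edge weights or directions are used.
#'
#' @slot graph an undirected simple \code{igraph} object with named vertices.
#'
#' @seealso [GeneNetwork()] for construction, [readNetwork()] for parsing
#'   edge-list files.
#' @export
setClass("GeneNetwork", representation(graph = "ANY"))

setValidity("GeneNetwork", function(object) {
    g <- object@graph
    if (!igraph::is_igraph(g))
        return("'graph' must be an igraph object")
    if (igraph::is_directed(g))
        return("network must be undirected")
    if (igraph::any_loop(g) || igraph::any_multiple(g))
        return("network must be a simple graph (no self-loops, no duplicate edges)")
    if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name))
        return("vertices must be named by gene identifier")
    TRUE
})

#' Construct a GeneNetwork
#'
#' @param edges a two-column character matrix or data.frame of gene-id pairs,
#'   or an \code{igraph} object.  Self-loops and duplicate (unordered) edges
#'   are dropped.
#' @param nodes optional character vector of additional isolated gene ids.
#'
#' @return a [GeneNetwork-class] object.
#' @examples
#' net <- GeneNetwork(cbind(c("A", "B"), c("B", "C")))
#' geneDegrees(net)
#' @export
GeneNetwork <- function(edges = NULL, nodes = NULL) {
    if (igraph::is_igraph(edges)) {
        g <- igraph::as_undirected(edges, mode = "collapse")
        g <- igraph::simplify(g)
    } else {
        if (is.null(edges) || NROW(edges) == 0) {
            em <- matrix(character(0), ncol = 2)
        } else {
            em <- as.matrix(edges)[, 1:2, drop = FALSE]
            storage.mode(em) <- "character"
        }
        keep <- em[, 1] != em[, 2]
        em <- em[keep, , drop = FALSE]
        # canonical unordered order, then dedupe
        swap <- em[, 1] > em[, 2]
        em[swap, ] <- em[swap, 2:1]
        em <- unique(em)
        verts <- sort(unique(c(as.vector(em), as.character(nodes))))
        g <- igraph::graph_from_edgelist(em, directed = FALSE)
        g <- igraph::add_vertices(g, length(setdiff(verts, igraph::V(g)$name)),
                                  name = setdiff(verts, igraph::V(g)$name))
        g <- igraph::permute(g, match(igraph::V(g)$name, sort(igraph::V(g)$name)))
    }
    new("GeneNetwork", graph = g)
}

#' @describeIn GeneNetwork-class number of genes
#' @param x,object a \code{GeneNetwork}
#' @export
setMethod("length", "GeneNetwork", function(x) igraph::vcount(x@graph))

#' @export
setMethod("show", "GeneNetwork", function(object) {
    cat("GeneNetwork with", igraph::vcount(object@graph), "genes and",
        igraph::ecount(object@graph), "interactions\n")
})

#' Gene identifiers of a network
#' @param x a [GeneNetwork-class]
#' @return character vector of gene ids.
#' @export
networkGenes <- function(x) {
    stopifnot(is(x, "GeneNetwork"))
    if (igraph::vcount(x@graph) == 0) character(0) else igraph::V(x@graph)$name
}

#' Edge list of a network
#' @param x a [GeneNetwork-class]
#' @return two-column character matrix of unordered edges.
#' @export
networkEdges <- function(x) {
    stopifnot(is(x, "GeneNetwork"))
    em <- igraph::as_edgelist(x@graph)
    storage.mode(em) <- "character"
    colnames(em) <- c("gene1", "gene2")
    em
}

#' Degrees of a network
#' @param x a [GeneNetwork-class]
#' @return named integer vector of degrees.
#' @export
geneDegrees <- function(x) {
    stopifnot(is(x, "GeneNetwork"))
    igraph::degree(x@graph)
}

#' Case/control variant cohort
#'
#' A \linkS4class{SummarizedExperiment} holding a variants-by-individuals
#' allele-count matrix (values 0/1/2) in the \code{"counts"} assay, the
#' variant-to-gene assignment in \code{rowData(x)$gene}, and optional binary
#' phenotype labels (case = 1, control = 0) in \code{colData(x)$phenotype}.
#'
#' @seealso [VariantCohort()], [readGenotypes()]
#' @export
setClass("VariantCohort", contains = "SummarizedExperiment")

setValidity("VariantCohort", function(object) {
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    m <- SummarizedExperiment::assay(object, "counts")
    vals <- if (inherits(m, "sparseMatrix")) m@x else as.vector(m)
    if (length(vals) && (anyNA(vals) || !all(vals %in% c(0, 1, 2))))
        return("genotype counts must all be 0, 1 or 2")
    rd <- SummarizedExperiment::rowData(object)
    if (!"gene" %in% colnames(rd))
        return("rowData column 'gene' (variant-to-gene map) is required")
    if (anyNA(rd$gene))
        return("every variant must map to exactly one gene")
    if ((nrow(object) > 0 && is.null(rownames(object))) ||
        (ncol(object) > 0 && is.null(colnames(object))))
        return("variant and individual identifiers are required as dimnames")
    cd <- SummarizedExperiment::colData(object)
    if ("phenotype" %in% colnames(cd)) {
        ph <- cd$phenotype
        if (!all(is.na(ph) | ph %in% c(0, 1)))
            return("phenotype labels must be 0 (control) or 1 (case)")
    }
    TRUE
})

#' Construct a VariantCohort
#'
#' @param counts variants x individuals matrix (dense or \pkg{Matrix} sparse)
#'   of allele counts in \{0,1,2\}, with dimnames.
#' @param variantGene character vector mapping each variant (row) to a gene
#'   id; recycled against \code{rownames(counts)} by name when named.
#' @param phenotype optional 0/1 vector of case/control labels, named by or
#'   ordered as \code{colnames(counts)}.
#'
#' @return a [VariantCohort-class].
#' @examples
#' m <- matrix(c(0, 1, 2, 0), 2, 2,
#'             dimnames = list(c("v1", "v2"), c("s1", "s2")))
#' vc <- VariantCohort(m, variantGene = c(v1 = "A", v2 = "B"),
#'                     phenotype = c(s1 = 1, s2 = 0))
#' variantGenes(vc)
#' @export
VariantCohort <- function(counts, variantGene, phenotype = NULL) {
    if (!is.null(names(variantGene)))
        variantGene <- variantGene[rownames(counts)]
    if (anyNA(variantGene))
        stop("variants without a gene mapping: ",
             paste(rownames(counts)[is.na(variantGene)], collapse = ", "))
    cd <- S4Vectors::DataFrame(row.names = colnames(counts))
    if (!is.null(phenotype)) {
        if (!is.null(names(phenotype))) phenotype <- phenotype[colnames(counts)]
        cd$phenotype <- as.integer(phenotype)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(gene = as.character(variantGene)),
        colData = cd)
    new("VariantCohort", se)
}

#' @export
setMethod("show", "VariantCohort", function(object) {
    ph <- phenotypeLabels(object)
    cat("VariantCohort:", nrow(object), "variants x", ncol(object),
        "individuals in", length(unique(variantGenes(object))), "genes")
    if (!all(is.na(ph)))
        cat(";", sum(ph == 1, na.rm = TRUE), "cases /",
            sum(ph == 0, na.rm = TRUE), "controls")
    cat("\n")
})

#' Variant-to-gene assignment
#' @param x a [VariantCohort-class]
#' @return character vector named by variant id.
#' @export
variantGenes <- function(x) {
    setNames(as.character(SummarizedExperiment::rowData(x)$gene), rownames(x))
}

#' Case/control labels
#' @param x a [VariantCohort-class]
#' @return integer vector (1 = case, 0 = control, NA when absent) named by
#'   individual id.
#' @export
phenotypeLabels <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    if ("phenotype" %in% colnames(cd))
        setNames(as.integer(cd$phenotype), colnames(x))
    else
        setNames(rep(NA_integer_, ncol(x)), colnames(x))
}

#' Genotype count matrix
#' @param x a [VariantCohort-class]
#' @return the variants x individuals count matrix.
#' @export
genotypeCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' Posterior marginals from the fitted model
#'
#' Holds the output of [runInference()]: per-gene posteriors
#' \eqn{P(H_g = 1)}, per gene-individual distributions over the relevance
#' state G, per-variant harmfulness posteriors \eqn{P(X_i = 1)}, and the
#' convergence record.
#'
#' @slot geneMarginals named numeric, \eqn{P(H_g = 1)} per gene.
#' @slot variantMarginals named numeric, \eqn{P(X_i = 1)} per variant.
#' @slot sampleGeneMarginals data.frame with columns \code{gene},
#'   \code{individual}, \code{g0}, \code{g1}, \code{g2} (distribution of G).
#' @slot converged logical; \code{iterations} integer; \code{trace}
#'   data.frame of per-sweep maximal marginal change.
#' @export
setClass("MarginalTable", representation(
    geneMarginals = "numeric",
    variantMarginals = "numeric",
    sampleGeneMarginals = "data.frame",
    converged = "logical",
    iterations = "integer",
    trace = "data.frame"))

setValidity("MarginalTable", function(object) {
    p <- c(object@geneMarginals, object@variantMarginals)
    if (length(p) && (anyNA(p) || any(p < -1e-9) || any(p > 1 + 1e-9)))
        return("marginals must lie in [0, 1]")
    TRUE
})

#' @export
setMethod("show", "MarginalTable", function(object) {
    cat("MarginalTable over", length(object@geneMarginals), "genes,",
        length(object@variantMarginals), "variants;",
        if (object@converged) "converged" else "NOT converged",
        "after", object@iterations, "sweeps\n")
    gm <- sort(object@geneMarginals, decreasing = TRUE)
    top <- head(gm, 5L)
    cat("top genes:", paste(sprintf("%s=%.3f", names(top), top),
                            collapse = ", "), "\n")
})

#' Per-gene posterior marginals
#' @param x a [MarginalTable-class]
#' @return named numeric vector of \eqn{P(H_g=1)}.
#' @export
geneMarginals <- function(x) x@geneMarginals

#' Per-variant posterior marginals
#' @param x a [MarginalTable-class]
#' @return named numeric vector of \eqn{P(X_i=1)}.
#' @export
variantMarginals <- function(x) x@variantMarginals

#' Convergence record of a fit
#' @param x a [MarginalTable-class]
#' @return list with \code{converged}, \code{iterations} and the sweep trace.
#' @export
convergenceInfo <- function(x)
    list(converged = x@converged, iterations = x@iterations, trace = x@trace)

#' Simulated disease scenario
#'
#' A self-contained synthetic benchmark instance: the sampled case/control
#' cohort, per-variant ground-truth harmfulness, the causal gene set and the
#' network it was drawn from.
#'
#' @slot cohort a [VariantCohort-class] (sampled cases + controls).
#' @slot causalGenes character vector of ground-truth disease genes.
#' @slot truthHarmful named logical, per-variant harmfulness truth.
#' @slot network the [GeneNetwork-class] used.
#' @slot topology how the causal set was selected
#'   (neighbourhood/star/clique/chain/explicit).
#' @export
setClass("DiseaseScenario", representation(
    cohort = "VariantCohort",
    causalGenes = "character",
    truthHarmful = "logical",
    network = "GeneNetwork",
    topology = "character"))

#' @export
setMethod("show", "DiseaseScenario", function(object) {
    cat("DiseaseScenario (", object@topology, "): ",
        length(object@causalGenes), " causal genes; cohort ",
        ncol(object@cohort), " individuals x ", nrow(object@cohort),
        " variants\n", sep = "")
})
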