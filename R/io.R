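## Tabular readers/writers for the formats the tool touches: 2-column TSV
## edge lists (SIF tolerated), variants-by-individuals genotype TSVs with a
## separate variant-to-gene map, per-individual phenotype labels and the
## ranked gene-marginal output.  All identifiers are opaque strings.

#' Read a gene network from an edge list
#'
#' Whitespace/tab-delimited file with two gene identifiers per line.  A
#' three-column file is treated as SIF and the middle column ignored; extra
#' columns beyond that are ignored.  Duplicate edges and self-loops are
#' dropped (with a message counting them when \code{verbose}).
#'
#' @param path file path.
#' @param verbose message the dropped-edge count.
#' @return a [GeneNetwork-class].
#' @export
readNetwork <- function(path, verbose = FALSE) {
    if (!file.exists(path)) stop("network file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    toks <- strsplit(trimws(lines), "[ \t]+")
    bad <- which(lengths(toks) < 2L)
    if (length(bad))
        stop("network parse error: line ", bad[1L], " has fewer than 2 fields")
    em <- t(vapply(toks, function(tk) {
        if (length(tk) == 3L) tk[c(1L, 3L)] else tk[1:2]
    }, character(2)))
    net <- GeneNetwork(em)
    if (verbose) {
        dropped <- nrow(em) - igraph::ecount(net@graph)
        if (dropped > 0)
            message(dropped, " duplicate/self-loop edge(s) dropped")
    }
    net
}

#' Write a network as a 2-column TSV edge list
#' @param network a [GeneNetwork-class].
#' @param path output file path.
#' @export
writeNetwork <- function(network, path) {
    write.table(networkEdges(network), path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read genotypes and the variant-to-gene map
#'
#' The matrix TSV has a header of individual ids and one row per variant
#' (first column: variant id); entries must be 0, 1 or 2.  The map TSV has
#' two columns, variant id and gene id (header optional); every matrix
#' variant must be mapped.
#'
#' @param matrixPath,mapPath file paths.
#' @param phenotypePath optional TSV with columns individual id and 0/1
#'   label.
#' @return a [VariantCohort-class].
#' @export
readGenotypes <- function(matrixPath, mapPath, phenotypePath = NULL) {
    for (p in c(matrixPath, mapPath, phenotypePath))
        if (!file.exists(p)) stop("file not found: ", p)
    tab <- read.table(matrixPath, header = TRUE, sep = "\t",
                      check.names = FALSE, colClasses = "character")
    variants <- tab[[1L]]
    m <- as.matrix(tab[, -1L, drop = FALSE])
    suppressWarnings(num <- matrix(as.numeric(m), nrow(m), ncol(m)))
    bad <- which(is.na(num) | !(num %in% c(0, 1, 2)))
    if (length(bad)) {
        rc <- arrayInd(bad[1L], dim(num))
        stop("invalid genotype entry '", m[bad[1L]], "' at variant ",
             variants[rc[1L]], ", individual ", colnames(m)[rc[2L]],
             " (must be 0, 1 or 2)")
    }
    dimnames(num) <- list(variants, colnames(m))

    map <- read.table(mapPath, header = FALSE, sep = "\t",
                      colClasses = "character")
    if (identical(tolower(map[1L, 1L]), "variant")) map <- map[-1L, , drop = FALSE]
    vg <- setNames(map[[2L]], map[[1L]])
    missing <- setdiff(variants, names(vg))
    if (length(missing))
        stop("variants without gene mapping: ", paste(missing, collapse = ", "))

    pheno <- NULL
    if (!is.null(phenotypePath)) pheno <- readPhenotypes(phenotypePath)
    VariantCohort(num, variantGene = vg[variants], phenotype = pheno)
}

#' Read case/control labels
#' @param path TSV with columns individual id and binary label (header
#'   optional).
#' @return named integer vector (1 = case, 0 = control).
#' @export
readPhenotypes <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- read.table(path, header = FALSE, sep = "\t",
                      colClasses = "character")
    if (identical(tolower(tab[1L, 1L]), "individual"))
        tab <- tab[-1L, , drop = FALSE]
    lab <- suppressWarnings(as.integer(tab[[2L]]))
    if (anyNA(lab) || !all(lab %in% 0:1))
        stop("phenotype labels must be 0 or 1")
    setNames(lab, tab[[1L]])
}

#' Write a cohort to genotype + map (+ phenotype) TSVs
#'
#' Inverse of [readGenotypes()]; round-trips bit-exactly.
#'
#' @param cohort a [VariantCohort-class].
#' @param matrixPath,mapPath,phenotypePath output paths
#'   (\code{phenotypePath} optional).
#' @export
writeGenotypes <- function(cohort, matrixPath, mapPath,
                           phenotypePath = NULL) {
    m <- as.matrix(genotypeCounts(cohort))
    out <- data.frame(variant = rownames(m), m, check.names = FALSE)
    write.table(out, matrixPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    write.table(data.frame(variant = rownames(m),
                           gene = unname(variantGenes(cohort))),
                mapPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    ph <- phenotypeLabels(cohort)
    if (!is.null(phenotypePath) && !all(is.na(ph)))
        write.table(data.frame(individual = names(ph), phenotype = ph),
                    phenotypePath, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    invisible(matrixPath)
}

#' Write ranked gene marginals
#'
#' TSV with columns \code{gene} and \code{posterior}, sorted by posterior
#' descending with ties broken lexicographically by gene id.
#'
#' @param table a [MarginalTable-class] or a named numeric vector of gene
#'   marginals.
#' @param path output file path.
#' @export
writeMarginals <- function(table, path) {
    gm <- if (is(table, "MarginalTable")) geneMarginals(table) else table
    ord <- order(-gm, names(gm))
    out <- data.frame(gene = names(gm)[ord], posterior = unname(gm[ord]))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
    invisible(path)
}

#' Read gene marginals written by [writeMarginals()]
#' @param path file path.
#' @return named numeric vector.
#' @export
readMarginals <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- read.table(path, header = TRUE, sep = "\t",
                      colClasses = c("character", "numeric"))
    setNames(tab$posterior, tab$gene)
}
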