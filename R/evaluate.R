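## Scoring recovered gene sets against ground truth: threshold detection
## (detected >= 0.2, suggestive >= 0.05), top-P ranking, confusion metrics
## with integer-percent truncation, a carrier-based exact-test baseline, and
## a small benchmarking harness.

#' Threshold detection of genes
#'
#' @param marginals named numeric vector of gene posteriors (or a
#'   [MarginalTable-class]).
#' @param detectedCut detection threshold (inclusive; default 0.2).
#' @param suggestiveCut suggestive-evidence threshold (inclusive; default
#'   0.05); must be below \code{detectedCut}.
#' @return list with character vectors \code{detected} and
#'   \code{suggestive} (the band \[suggestiveCut, detectedCut)).
#' @export
detectAtThreshold <- function(marginals, detectedCut = 0.2,
                              suggestiveCut = 0.05) {
    if (is(marginals, "MarginalTable")) marginals <- geneMarginals(marginals)
    stopifnot(detectedCut > suggestiveCut, suggestiveCut > 0, detectedCut < 1)
    list(detected = sort(names(marginals)[marginals >= detectedCut]),
         suggestive = sort(names(marginals)[marginals >= suggestiveCut &
                                            marginals < detectedCut]))
}

#' Top-P gene selection
#'
#' @param marginals named numeric gene posteriors (or a
#'   [MarginalTable-class]).
#' @param P number of genes to select (the assumed causal-set size).
#' @return character vector of the P highest-posterior genes, ties broken
#'   lexicographically.
#' @export
topPSelection <- function(marginals, P) {
    if (is(marginals, "MarginalTable")) marginals <- geneMarginals(marginals)
    if (P > length(marginals))
        stop("P exceeds the number of scored genes")
    ord <- order(-marginals, names(marginals))
    names(marginals)[ord][seq_len(P)]
}

#' Confusion metrics against a truth set
#'
#' Sensitivity (power) is the fraction of true causal genes recovered,
#' precision the fraction of selected genes that are truly causal, and the
#' F-measure their harmonic mean.  Reported percentages are truncated to
#' whole percent (floor); exact fractions are always retained.
#'
#' @param selected character vector of selected genes.
#' @param truth nonempty character vector of true causal genes.
#' @return list with counts (\code{tp}, \code{fp}, \code{fn}), exact
#'   fractions (\code{sensitivity}, \code{precision}, \code{fMeasure}),
#'   truncated integer percents (\code{sensitivityPct},
#'   \code{precisionPct}) and \code{emptySelection} flag (precision is
#'   defined as 1 and flagged when nothing was selected).
#' @export
confusionMetrics <- function(selected, truth) {
    stopifnot(length(truth) > 0)
    tp <- length(intersect(selected, truth))
    fp <- length(setdiff(selected, truth))
    fn <- length(setdiff(truth, selected))
    sens <- tp / (tp + fn)
    empty <- (tp + fp) == 0
    prec <- if (empty) 1 else tp / (tp + fp)
    f <- if (sens + prec == 0) 0 else 2 * sens * prec / (sens + prec)
    if (tp == 0) f <- 0
    list(tp = tp, fp = fp, fn = fn,
         sensitivity = sens, precision = prec, fMeasure = f,
         sensitivityPct = as.integer(floor(100 * sens)),
         precisionPct = as.integer(floor(100 * prec)),
         emptySelection = empty)
}

#' Carrier-based burden baseline
#'
#' Per gene, a two-sided exact test (Fisher) on the 2x2 table of carrier
#' status (any variant in the gene) against case/control, ranked ascending
#' by p-value.  Internal plumbing baseline for the benchmark harness, not a
#' replacement for dedicated rare-variant association tests.
#'
#' @param cohort a [VariantCohort-class] with phenotype labels.
#' @return data.frame with columns \code{gene}, \code{p},
#'   \code{carriersCase}, \code{carriersControl}, \code{degenerate} (no
#'   carriers at all, p fixed at 1), sorted by p then gene id.
#' @export
burdenBaseline <- function(cohort) {
    ph <- phenotypeLabels(cohort)
    if (anyNA(ph)) stop("phenotype labels required")
    m <- as(as(Matrix::Matrix(genotypeCounts(cohort), sparse = TRUE),
               "generalMatrix"), "CsparseMatrix")
    vg <- variantGenes(cohort)
    genes <- sort(unique(vg))
    trip <- as.data.frame(Matrix::summary(m))
    gi <- match(vg[trip$i], genes)
    carrier <- unique(data.frame(g = gi, j = trip$j))
    isCase <- ph == 1
    nCase <- sum(isCase); nCtrl <- sum(!isCase)
    a <- tabulate(carrier$g[isCase[carrier$j]], length(genes))
    b <- tabulate(carrier$g[!isCase[carrier$j]], length(genes))
    p <- vapply(seq_along(genes), function(k) {
        if (a[k] + b[k] == 0) return(1)
        fisher.test(matrix(c(a[k], nCase - a[k], b[k], nCtrl - b[k]),
                           2))$p.value
    }, numeric(1))
    out <- data.frame(gene = genes, p = p, carriersCase = a,
                      carriersControl = b, degenerate = (a + b) == 0)
    out[order(out$p, out$gene), , drop = FALSE]
}

#' Fit the network-prior model to a cohort
#'
#' Convenience wrapper: builds the pairwise priors from the network, the
#' factor graph from the cohort and runs belief propagation.
#'
#' @param cohort a [VariantCohort-class] with phenotype labels.
#' @param network a [GeneNetwork-class] (may be empty).
#' @param priorConfig,modelConfig,inferenceConfig configuration objects.
#' @return a [MarginalTable-class].
#' @examples
#' \donttest{
#' net <- generateSyntheticNetwork(200, seed = 7, cliqueSize = 10,
#'                                 starLeaves = 12, pathLength = 10)
#' sc <- simulateScenario(net, PopulationConfig(nGenes = 200,
#'                        nIndividuals = 4000, variantsPerGene = 10),
#'                        P = 5, n = 200, topK = 200, seed = 7)
#' fit <- fitNetworkModel(sc@cohort, net)
#' head(sort(geneMarginals(fit), decreasing = TRUE))
#' }
#' @export
fitNetworkModel <- function(cohort, network = GeneNetwork(),
                            priorConfig = PriorConfig(),
                            modelConfig = ModelConfig(),
                            inferenceConfig = InferenceConfig()) {
    priors <- buildPairPriors(network, priorConfig)
    graph <- buildFactorGraph(cohort, priors, modelConfig, priorConfig)
    runInference(graph, inferenceConfig)
}

#' Run a small recovery benchmark
#'
#' For each replicate: simulate a scenario, fit the network-prior model and
#' the carrier baseline, and score both in threshold and top-P modes.
#'
#' @param network a [GeneNetwork-class].
#' @param config a [PopulationConfig-class].
#' @param P,n,topK scenario parameters (see [simulateScenario()]).
#' @param replicates number of replicates.
#' @param seed base seed; replicate k uses \code{seed + 1000 * k}.
#' @param methods subset of \code{c("model", "baseline")}.
#' @return data.frame, one row per (replicate, method, mode), with the
#'   confusion metrics and the mean causal / non-causal gene scores.
#' @export
runBenchmark <- function(network, config = PopulationConfig(), P = 10,
                         n = 800, topK = 1000, replicates = 5, seed = 1,
                         methods = c("model", "baseline")) {
    rows <- list()
    for (k in seq_len(replicates)) {
        sk <- seed + 1000L * k
        sc <- simulateScenario(network, config, P = P, n = n, topK = topK,
                               topology = "neighbourhood", seed = sk)
        truth <- sc@causalGenes
        scores <- list()
        if ("model" %in% methods) {
            fit <- fitNetworkModel(sc@cohort, network)
            scores$model <- geneMarginals(fit)
        }
        if ("baseline" %in% methods) {
            bb <- burdenBaseline(sc@cohort)
            ## rank-based score: smaller p = larger score; fill in genes
            ## the cohort never saw at the bottom
            s <- setNames(-log10(pmax(bb$p, 1e-300)), bb$gene)
            all <- networkGenes(network)
            s <- setNames(ifelse(is.na(s[all]), 0, s[all]), all)
            scores$baseline <- s
        }
        for (meth in names(scores)) {
            sel <- topPSelection(scores[[meth]], P)
            cmTop <- confusionMetrics(sel, truth)
            causal <- intersect(names(scores[[meth]]), truth)
            noncausal <- setdiff(names(scores[[meth]]), truth)
            base <- data.frame(
                replicate = k, method = meth, seed = sk,
                meanCausalScore = mean(scores[[meth]][causal]),
                meanNoncausalScore = mean(scores[[meth]][noncausal]))
            rows[[length(rows) + 1L]] <- cbind(
                base, mode = "topP",
                as.data.frame(cmTop[c("tp", "fp", "fn", "sensitivity",
                                      "precision", "fMeasure")]))
            if (meth == "model") {
                det <- detectAtThreshold(scores[[meth]])$detected
                cmThr <- confusionMetrics(det, truth)
                rows[[length(rows) + 1L]] <- cbind(
                    base, mode = "threshold",
                    as.data.frame(cmThr[c("tp", "fp", "fn", "sensitivity",
                                          "precision", "fMeasure")]))
            }
        }
    }
    do.call(rbind, rows)
}
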