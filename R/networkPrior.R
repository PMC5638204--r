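## Calibrated degree-dependent network priors over the gene indicator
## variables H.  The calibration guarantees that network context alone can
## never raise an otherwise-uninformative gene past a fixed marginal ceiling
## (default 0.02), an order of magnitude below the detection threshold (0.2).

#' Configuration of the network prior
#'
#' @slot tau baseline prior probability that a random gene is disease
#'   associated (default 0.0025).
#' @slot ceiling largest marginal the network alone may produce (default
#'   0.02).
#' @slot detectionThreshold marginal needed to call a gene (default 0.2).
#' @slot significanceBase numerator of the neighbourhood-significance
#'   threshold (default 0.05); the threshold is
#'   \code{significanceBase / nGenesTotal}.
#' @slot nGenesTotal significance denominator; \code{NA} means "use the
#'   analysis gene-universe size at build time", the constructor default is
#'   12000.
#' @slot deltaCap hard upper bound on the pairwise parameter delta (default
#'   0.9).
#' @slot neighbourhoodOrder 1 = direct interactions only, 2 = also
#'   neighbours-of-neighbours (default 2).
#' @export
setClass("PriorConfig", representation(
    tau = "numeric", ceiling = "numeric", detectionThreshold = "numeric",
    significanceBase = "numeric", nGenesTotal = "numeric",
    deltaCap = "numeric", neighbourhoodOrder = "numeric"))

setValidity("PriorConfig", function(object) {
    with(attributes(object), {
        if (!(tau > 0 && tau < ceiling && ceiling < detectionThreshold &&
              detectionThreshold < 1))
            return("need 0 < tau < ceiling < detectionThreshold < 1")
        if (!(deltaCap > 0 && deltaCap < 1))
            return("deltaCap must be in (0, 1)")
        if (!neighbourhoodOrder %in% c(1, 2))
            return("neighbourhoodOrder must be 1 or 2")
        if (significanceBase <= 0 || significanceBase >= 1)
            return("significanceBase must be in (0, 1)")
        if (!is.na(nGenesTotal) && nGenesTotal < 1)
            return("nGenesTotal must be positive")
        TRUE
    })
})

#' @rdname PriorConfig-class
#' @param tau,ceiling,detectionThreshold,significanceBase,nGenesTotal,deltaCap,neighbourhoodOrder
#'   see the class slots.
#' @return a \code{PriorConfig}.
#' @examples
#' cfg <- PriorConfig()
#' maxContribution(cfg)
#' @export
PriorConfig <- function(tau = 0.0025, ceiling = 0.02,
                        detectionThreshold = 0.2, significanceBase = 0.05,
                        nGenesTotal = 12000, deltaCap = 0.9,
                        neighbourhoodOrder = 2) {
    new("PriorConfig", tau = tau, ceiling = ceiling,
        detectionThreshold = detectionThreshold,
        significanceBase = significanceBase, nGenesTotal = nGenesTotal,
        deltaCap = deltaCap, neighbourhoodOrder = neighbourhoodOrder)
}

logOdds <- function(p) log(p) - log1p(-p)
invLogOdds <- function(l) 1 / (1 + exp(-l))

#' Maximal network contribution
#'
#' The largest aggregate evidence (as a probability \eqn{M_c}) the network is
#' allowed to contribute to a gene: combining the prior odds
#' \eqn{\tau/(1-\tau)} with the contribution odds \eqn{M_c/(1-M_c)} yields a
#' posterior exactly equal to the ceiling,
#' \deqn{\frac{\tau}{1-\tau}\cdot\frac{M_c}{1-M_c}
#'       = \frac{c}{1-c},\qquad c = \mathrm{ceiling}.}
#'
#' @param config a [PriorConfig-class], or \code{NULL} when \code{tau} and
#'   \code{ceiling} are given directly.
#' @param tau,ceiling override the config values.
#' @return the probability \eqn{M_c}.
#' @examples
#' maxContribution(PriorConfig())          # ~0.8906
#' maxContribution(tau = 0.02, ceiling = 0.02)  # 0.5: no headroom
#' @export
maxContribution <- function(config = PriorConfig(), tau = config@tau,
                            ceiling = config@ceiling) {
    stopifnot(tau > 0, tau <= ceiling, ceiling < 1)
    invLogOdds(logOdds(ceiling) - logOdds(tau))
}

#' Minimum significantly-enriched neighbour count
#'
#' Smallest number of simultaneously active neighbours that makes a gene's
#' neighbourhood significantly enriched under a binomial null with success
#' probability \code{tau} and \code{d} trials, at threshold
#' \code{significanceBase / nGenesTotal}.  The upper tail is taken as 0 for
#' counts exceeding the degree, so \code{d + 1} is returned when no count up
#' to \code{d} is significant (low-degree genes under default settings).
#'
#' @param d integer degree(s), each >= 1.
#' @param config a [PriorConfig-class].
#' @param nGenesTotal significance denominator; defaults to the config value
#'   (12000 unless changed).
#' @return integer vector of minimal significant counts.
#' @examples
#' minActiveNeighbours(10)   # 3
#' minActiveNeighbours(100)  # 6
#' @export
minActiveNeighbours <- function(d, config = PriorConfig(),
                                nGenesTotal = config@nGenesTotal) {
    if (any(d < 1)) stop("degree must be >= 1 (isolated genes get no pair priors)")
    if (is.na(nGenesTotal)) nGenesTotal <- 12000
    thr <- config@significanceBase / nGenesTotal
    vapply(as.integer(d), function(di) {
        tail <- pbinom(0:(di - 1L), di, config@tau, lower.tail = FALSE)
        sig <- which(tail <= thr)        # tail for count a is tail[a]
        if (length(sig)) sig[1L] else di + 1L
    }, integer(1))
}

#' Degree-dependent pairwise prior strength
#'
#' Solves \eqn{(\delta/(1-\delta))^{a_{\min}} = M_c/(1-M_c)} so that a just
#' significantly enriched neighbourhood (exactly \eqn{a_{\min}} active
#' neighbours) contributes exactly the maximal contribution, then applies the
#' hard cap \code{deltaCap}.  Higher-degree genes need more active
#' neighbours for significance and therefore get a smaller delta.
#'
#' @inheritParams minActiveNeighbours
#' @return numeric vector of delta values in \code{[0.5, deltaCap]}.
#' @examples
#' deltaForDegree(10)   # ~0.668
#' deltaForDegree(100)  # ~0.587
#' @export
deltaForDegree <- function(d, config = PriorConfig(),
                           nGenesTotal = config@nGenesTotal) {
    aMin <- minActiveNeighbours(d, config, nGenesTotal)
    lambdaC <- logOdds(maxContribution(config))
    pmin(config@deltaCap, invLogOdds(lambdaC / aMin))
}

#' Distance-two closure of a network
#'
#' Order 1 returns the input unchanged; order 2 returns the simple graph
#' connecting every pair of genes at distance at most 2 in the input, which
#' is how second-order interactions (neighbours of neighbours) enter the
#' prior.
#'
#' @param network a [GeneNetwork-class].
#' @param order 1 or 2.
#' @return a [GeneNetwork-class].
#' @export
buildAugmentedAdjacency <- function(network, order = 2) {
    stopifnot(is(network, "GeneNetwork"), order %in% c(1, 2))
    if (order == 1) return(network)
    g <- network@graph
    if (igraph::ecount(g) == 0) return(network)
    g2 <- igraph::connect(g, order = 2)
    GeneNetwork(igraph::simplify(g2))
}

#' Build the directed pairwise priors
#'
#' For every ordered pair of genes adjacent in the distance-closed network,
#' one directed asymmetric prior factor: uninformative when the source gene
#' is off (\eqn{P(H_i=1 \mid H_j=0) = 0.5}) and encouraging when it is on
#' (\eqn{P(H_i=1 \mid H_j=1) = \delta}), with delta set by the
#' \emph{target's} degree in the closed network via [deltaForDegree()].
#' Each undirected edge yields two priors, one per direction, each with its
#' own target-degree delta.
#'
#' @param network a [GeneNetwork-class].
#' @param config a [PriorConfig-class]; \code{nGenesTotal = NA} uses the
#'   number of genes in \code{network}.
#' @return data.frame with columns \code{source}, \code{target},
#'   \code{delta}.
#' @export
buildPairPriors <- function(network, config = PriorConfig()) {
    stopifnot(is(network, "GeneNetwork"))
    nTot <- config@nGenesTotal
    if (is.na(nTot)) nTot <- max(length(network), 1)
    aug <- buildAugmentedAdjacency(network, config@neighbourhoodOrder)
    em <- networkEdges(aug)
    if (nrow(em) == 0)
        return(data.frame(source = character(0), target = character(0),
                          delta = numeric(0)))
    degs <- geneDegrees(aug)
    deltaByDeg <- setNames(
        deltaForDegree(sort(unique(degs)), config, nTot),
        sort(unique(degs)))
    src <- c(em[, 1], em[, 2])
    tgt <- c(em[, 2], em[, 1])
    data.frame(source = src, target = tgt,
               delta = unname(deltaByDeg[as.character(degs[tgt])]))
}

#' Cap aggregated network evidence
#'
#' Positive per-neighbour log-odds contributions are summed and clipped at
#' the log-odds of the maximal contribution; non-positive contributions pass
#' through unmodified (the asymmetric prior factors never produce negative
#' evidence, so that term is zero in practice).  Applied to the incoming
#' prior-message product of every gene at every sweep of the inference.
#'
#' @param contributions numeric vector of per-neighbour log-odds
#'   contributions (may be empty).
#' @param config a [PriorConfig-class].
#' @return a single aggregated log-odds value.
#' @export
capContribution <- function(contributions, config = PriorConfig()) {
    stopifnot(all(is.finite(contributions)))
    cap <- logOdds(maxContribution(config))
    min(sum(pmax(contributions, 0)), cap) + sum(pmin(contributions, 0))
}
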