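## Damped loopy belief propagation with the two-tier schedule: each outer
## sweep updates the variant-tier messages (X, Y, Q) once, then iterates the
## tightly-coupled gene/phenotype tier (G, H, pheno, pairwise priors,
## cardinality prior) up to a fixed number of times or until local
## convergence.  Messages between binary variables are tracked as log-odds;
## multi-state messages as normalized rows.  Two exact simplifications are
## used: the geometric cardinality prior factorizes into per-gene unaries,
## and the noisy-OR phenotype counting factor admits closed-form
## leave-one-out messages (both asserted against the generic counting-factor
## machinery in the test suite).

#' Inference configuration
#'
#' @slot alpha damping weight on the old message (default 0.5).
#' @slot innerLoopMax sweeps of the gene/phenotype tier per outer sweep
#'   (default 10).
#' @slot outerMaxIterations cap on outer sweeps (default 200).
#' @slot convergenceTol maximal absolute marginal change declaring outer
#'   convergence (default 1e-4); \code{innerTol} likewise for the inner tier.
#' @slot innerTol see above.
#' @slot seed integer recorded for reproducibility (the default schedule is
#'   deterministic).
#' @export
setClass("InferenceConfig", representation(
    alpha = "numeric", innerLoopMax = "numeric",
    outerMaxIterations = "numeric", convergenceTol = "numeric",
    innerTol = "numeric", seed = "numeric"))

setValidity("InferenceConfig", function(object) {
    if (object@alpha < 0 || object@alpha >= 1)
        return("alpha must be in [0, 1)")
    if (object@convergenceTol <= 0 || object@innerTol <= 0)
        return("tolerances must be positive")
    if (object@innerLoopMax < 1 || object@outerMaxIterations < 1)
        return("iteration caps must be >= 1")
    TRUE
})

#' @rdname InferenceConfig-class
#' @param alpha,innerLoopMax,outerMaxIterations,convergenceTol,innerTol,seed
#'   see the class slots.
#' @return an \code{InferenceConfig}.
#' @export
InferenceConfig <- function(alpha = 0.5, innerLoopMax = 10,
                            outerMaxIterations = 200,
                            convergenceTol = 1e-4, innerTol = 1e-4,
                            seed = 0) {
    new("InferenceConfig", alpha = alpha, innerLoopMax = innerLoopMax,
        outerMaxIterations = outerMaxIterations,
        convergenceTol = convergenceTol, innerTol = innerTol, seed = seed)
}

#' Damped message update
#'
#' Convex combination \code{alpha * old + (1 - alpha) * new} in probability
#' space, renormalized; alpha = 0 returns the new message, and a message is
#' a fixed point of its own update.
#'
#' @param old,new normalized numeric distributions (or matrices of row
#'   distributions) on the same support.
#' @param alpha damping weight in \[0, 1).
#' @return the damped distribution(s).
#' @export
dampedUpdate <- function(old, new, alpha) {
    if (!identical(dim(old), dim(new)) || length(old) != length(new))
        stop("message support mismatch in damped update")
    m <- alpha * old + (1 - alpha) * new
    if (is.matrix(m)) m / rowSums(m) else m / sum(m)
}

## grouped sum that always returns a full-length vector (zero for empty
## groups)
groupSum <- function(values, group, nGroups) {
    out <- numeric(nGroups)
    if (length(values)) {
        s <- rowsum(values, group)
        out[as.integer(rownames(s))] <- s
    }
    out
}

## one step of the capped three-state sum distribution (states 0, 1, >=2)
## when adding a variant with activation probability p and dosage d
sumStep <- function(s0, s1, s2, p, d) {
    one <- d == 1L
    n0 <- s0 * (1 - p)
    n1 <- ifelse(one, s1 * (1 - p) + s0 * p, s1 * (1 - p))
    n2 <- ifelse(one, s2 + s1 * p, s2 + (s0 + s1) * p)
    list(n0, n1, n2)
}

#' Run loopy belief propagation
#'
#' Damped loopy BP with the two-tier schedule over a graph built by
#' [buildFactorGraph()].  Aggregated network-prior evidence into every gene
#' is capped at the maximal contribution ([capContribution()]) on every
#' sweep, so network context alone cannot push any gene past the calibrated
#' ceiling.
#'
#' @param graph a \code{FactorGraph}.
#' @param config an [InferenceConfig-class].
#' @param clamp optional named vector of hard gene-state assignments
#'   (\code{c(geneA = 1, ...)}); clamped genes broadcast their state and
#'   ignore incoming evidence.
#' @return a [MarginalTable-class].
#' @export
runInference <- function(graph, config = InferenceConfig(), clamp = NULL) {
    stopifnot(inherits(graph, "FactorGraph"))
    validObject(config)
    mc <- graph$modelConfig; pc <- graph$priorConfig
    al <- config@alpha
    nG <- length(graph$genes); nV <- length(graph$variants)
    nP <- graph$nPairs; nE <- nrow(graph$theta)
    inc <- graph$incid
    nInc <- nrow(inc)

    clampState <- rep(NA_real_, nG)
    if (!is.null(clamp)) {
        idx <- match(names(clamp), graph$genes)
        if (anyNA(idx)) stop("unknown gene in clamp: ",
                             paste(names(clamp)[is.na(idx)], collapse = ", "))
        clampState[idx] <- as.numeric(clamp)
    }
    isClamped <- !is.na(clampState)

    uH <- rep(logOdds(pc@tau) + log(mc@gamma), nG)
    uX <- logOdds(mc@xPrior)
    lcap <- logOdds(maxContribution(pc))
    cpt <- phi2Matrix(mc@epsQ)
    r <- 1 - mc@penetrance
    A <- 1 - mc@backgroundRate
    phenoPair <- graph$pheno[graph$pairIndiv]   # label per pair

    ## message state (probability space, normalized rows)
    MQ2 <- matrix(1 / 3, nP, 3); MQ3 <- matrix(1 / 3, nP, 3)
    MG3 <- matrix(1 / 3, nP, 3); MG4 <- matrix(0.5, nP, 2)
    MH3 <- matrix(0.5, nP, 2)
    MX2 <- matrix(0.5, nInc, 2)
    MTheta <- matrix(0.5, nE, 2)

    lodd <- function(m) log(m[, 2]) - log(m[, 1])

    geneLogOdds <- function() {
        lam <- if (nE) lodd(MTheta) else numeric(0)
        net <- pmin(groupSum(pmax(lam, 0), graph$theta$tgt, nG), lcap) +
            groupSum(pmin(lam, 0), graph$theta$tgt, nG)
        ds <- groupSum(lodd(MH3), graph$pairGene, nG)
        lh <- uH + ds + net
        lh[isClamped] <- ifelse(clampState[isClamped] == 1, Inf, -Inf)
        lh
    }

    lastHM <- rep(NA_real_, nG); lastXM <- rep(NA_real_, nV)
    trace <- data.frame(iteration = integer(0), maxDelta = numeric(0))
    converged <- FALSE
    outer <- 0L

    posIdx <- if (nInc) split(seq_len(nInc), inc$pos) else list()
    lastOf <- if (nInc) c(inc$pair[-1L] != inc$pair[-nInc], TRUE) else logical(0)

    repeat {
        outer <- outer + 1L

        ## ---- variant tier: X / Y / Q messages ----
        if (nInc) {
            lxInc <- groupSum(lodd(MX2), inc$variant, nV)[inc$variant] -
                lodd(MX2) + uX
            p <- invLogOdds(lxInc)
            ## prefix distributions (sum over earlier incidences in the pair)
            P0 <- numeric(nInc); P1 <- numeric(nInc); P2 <- numeric(nInc)
            S0 <- numeric(nInc); S1 <- numeric(nInc); S2 <- numeric(nInc)
            P0[posIdx[[1L]]] <- 1
            if (length(posIdx) > 1L)
                for (k in 2:length(posIdx)) {
                    at <- posIdx[[k]]; prev <- at - 1L
                    st <- sumStep(P0[prev], P1[prev], P2[prev],
                                  p[prev], inc$dose[prev])
                    P0[at] <- st[[1L]]; P1[at] <- st[[2L]]; P2[at] <- st[[3L]]
                }
            S0[lastOf] <- 1
            notLast <- which(!lastOf)
            if (length(notLast))
                for (at in rev(split(notLast, inc$pos[notLast]))) {
                    nxt <- at + 1L
                    st <- sumStep(S0[nxt], S1[nxt], S2[nxt],
                                  p[nxt], inc$dose[nxt])
                    S0[at] <- st[[1L]]; S1[at] <- st[[2L]]; S2[at] <- st[[3L]]
                }
            ## full per-pair sum distribution, from its last incidence
            fl <- which(lastOf)
            st <- sumStep(P0[fl], P1[fl], P2[fl], p[fl], inc$dose[fl])
            sFull <- cbind(st[[1L]], st[[2L]], st[[3L]])   # rows sum to 1
            MQ2 <- dampedUpdate(MQ2, sFull[inc$pair[fl], , drop = FALSE] %*% cpt, al)

            ## message to each X: leave-one-out sum distribution
            W0 <- P0 * S0
            W1 <- P0 * S1 + P1 * S0
            W2 <- pmax(1 - W0 - W1, 0)
            gq <- (MQ3 %*% cpt)[inc$pair, , drop = FALSE]
            out0 <- W0 * gq[, 1] + W1 * gq[, 2] + W2 * gq[, 3]
            out1 <- ifelse(inc$dose == 1L,
                           W0 * gq[, 2] + (W1 + W2) * gq[, 3],
                           gq[, 3])
            newX <- cbind(out0, out1)
            MX2 <- dampedUpdate(MX2, newX / rowSums(newX), al)
        }

        ## ---- gene/phenotype tier ----
        innerLastH <- invLogOdds(geneLogOdds())
        for (innerIt in seq_len(config@innerLoopMax)) {
            lh <- geneLogOdds()
            if (nP) {
                lhPair <- lh[graph$pairGene] - lodd(MH3)
                lhPair[isClamped[graph$pairGene]] <-
                    ifelse(clampState[graph$pairGene[isClamped[graph$pairGene]]] == 1,
                           Inf, -Inf)
                hm1 <- invLogOdds(lhPair); hm0 <- 1 - hm1
                q0 <- MQ2[, 1]; q12 <- MQ2[, 2] + MQ2[, 3]
                g0 <- MG4[, 1]; g1 <- MG4[, 2]
                ## phi3 -> H
                nH <- cbind(g0, MQ2[, 1] * g0 + q12 * g1)
                MH3 <- dampedUpdate(MH3, nH / rowSums(nH), al)
                ## phi3 -> G and -> Q
                nG3 <- cbind(hm0 + hm1 * MQ2[, 1], hm1 * MQ2[, 2],
                             hm1 * MQ2[, 3])
                MG3 <- dampedUpdate(MG3, nG3 / rowSums(nG3), al)
                nQ3 <- cbind(g0, hm0 * g0 + hm1 * g1, hm0 * g0 + hm1 * g1)
                MQ3 <- dampedUpdate(MQ3, nQ3 / rowSums(nQ3), al)
                ## phi4 -> G (closed-form noisy-OR counting messages)
                m0 <- MG3[, 1] / (MG3[, 1] + MG3[, 2] + MG3[, 3])
                m1 <- 1 - m0
                tP <- m0 + m1 * r
                logT <- groupSum(log(tP), graph$pairIndiv,
                                 length(graph$individuals))
                T2 <- exp(logT[graph$pairIndiv] - log(tP))
                case <- phenoPair == 1L
                n0 <- ifelse(case, 1 - A * T2, 1)
                n1 <- ifelse(case, 1 - A * r * T2, r)
                nG4 <- cbind(n0, n1)
                MG4 <- dampedUpdate(MG4, nG4 / rowSums(nG4), al)
            }
            ## directed pairwise priors, with per-edge leave-one-out of the
            ## reverse edge before re-capping
            if (nE) {
                lh <- geneLogOdds()
                lam <- lodd(MTheta)
                spos <- groupSum(pmax(lam, 0), graph$theta$tgt, nG)
                sneg <- groupSum(pmin(lam, 0), graph$theta$tgt, nG)
                ds <- groupSum(lodd(MH3), graph$pairGene, nG)
                revLam <- lam[graph$theta$rev]
                src <- graph$theta$src
                netEx <- pmin(spos[src] - pmax(revLam, 0), lcap) +
                    (sneg[src] - pmin(revLam, 0))
                lSrc <- uH[src] + ds[src] + netEx
                lSrc[isClamped[src]] <-
                    ifelse(clampState[src[isClamped[src]]] == 1, Inf, -Inf)
                b <- invLogOdds(lSrc)
                d <- graph$theta$delta
                nT <- cbind(0.5 * (1 - b) + (1 - d) * b,
                            0.5 * (1 - b) + d * b)
                MTheta <- dampedUpdate(MTheta, nT / rowSums(nT), al)
            }
            hMar <- invLogOdds(geneLogOdds())
            if (length(hMar) == 0L ||
                max(abs(hMar - innerLastH)) < config@innerTol) break
            innerLastH <- hMar
        }

        ## ---- outer convergence on marginals ----
        hMar <- invLogOdds(geneLogOdds())
        xMar <- invLogOdds(groupSum(lodd(MX2), inc$variant, nV) + uX)
        delta <- if (anyNA(lastHM)) Inf else
            max(abs(c(hMar - lastHM, xMar - lastXM)), 0)
        trace <- rbind(trace,
                       data.frame(iteration = outer, maxDelta = delta))
        lastHM <- hMar; lastXM <- xMar
        if (is.finite(delta) && delta < config@convergenceTol) {
            converged <- TRUE
            break
        }
        if (outer >= config@outerMaxIterations) break
    }

    if (anyNA(c(lastHM, lastXM)) || any(!is.finite(c(lastHM, lastXM))))
        stop("non-finite marginal encountered during inference")

    gDist <- MG3 * cbind(MG4[, 1], MG4[, 2], MG4[, 2])
    gDist <- gDist / rowSums(gDist)
    sg <- data.frame(
        gene = graph$genes[graph$pairGene],
        individual = graph$individuals[graph$pairIndiv],
        g0 = gDist[, 1], g1 = gDist[, 2], g2 = gDist[, 3])

    new("MarginalTable",
        geneMarginals = setNames(lastHM, graph$genes),
        variantMarginals = setNames(lastXM, graph$variants),
        sampleGeneMarginals = sg,
        converged = converged, iterations = outer, trace = trace)
}

#' Exact marginals by exhaustive enumeration
#'
#' Sums the unnormalized joint ([jointDensity()]) over every configuration
#' of the free variables (X, H, Q; Y and G are their deterministic
#' products).  The global test oracle for the loopy engine; refuses state
#' spaces above 2e6 configurations.
#'
#' @param graph a \code{FactorGraph}.
#' @return a [MarginalTable-class] (gene, variant and per-pair G marginals;
#'   convergence fields describe the enumeration trivially).
#' @export
exactMarginals <- function(graph) {
    stopifnot(inherits(graph, "FactorGraph"))
    nV <- length(graph$variants); nG <- length(graph$genes)
    nP <- graph$nPairs
    size <- 2^nV * 2^nG * 3^nP
    if (size > 2e6) stop("state space too large for exhaustive enumeration")
    grid <- expand.grid(c(rep(list(0:1), nV), rep(list(0:1), nG),
                          rep(list(0:2), nP)), KEEP.OUT.ATTRS = FALSE)
    grid <- as.matrix(grid)
    w <- apply(grid, 1L, function(row) {
        jointDensity(graph,
                     x = row[seq_len(nV)],
                     h = row[nV + seq_len(nG)],
                     q = row[nV + nG + seq_len(nP)])
    })
    z <- sum(w)
    xm <- vapply(seq_len(nV), function(i) sum(w[grid[, i] == 1]) / z,
                 numeric(1))
    hm <- vapply(seq_len(nG), function(g) sum(w[grid[, nV + g] == 1]) / z,
                 numeric(1))
    sg <- NULL
    if (nP) {
        gstate <- vapply(seq_len(nP), function(p)
            grid[, nV + graph$pairGene[p]] * grid[, nV + nG + p],
            numeric(nrow(grid)))
        sg <- data.frame(
            gene = graph$genes[graph$pairGene],
            individual = graph$individuals[graph$pairIndiv],
            t(vapply(seq_len(nP), function(p) c(
                g0 = sum(w[gstate[, p] == 0]) / z,
                g1 = sum(w[gstate[, p] == 1]) / z,
                g2 = sum(w[gstate[, p] == 2]) / z), numeric(3))))
    } else {
        sg <- data.frame(gene = character(0), individual = character(0),
                         g0 = numeric(0), g1 = numeric(0), g2 = numeric(0))
    }
    new("MarginalTable",
        geneMarginals = setNames(hm, graph$genes),
        variantMarginals = setNames(xm, graph$variants),
        sampleGeneMarginals = sg,
        converged = TRUE, iterations = 1L,
        trace = data.frame(iteration = 1L, maxDelta = 0))
}

#' Rank an individual's variants by model relevance
#'
#' Carried variants of one individual ordered by the posterior probability
#' that the variant is functionally affecting (\eqn{P(Y \ge 1)}, i.e. the
#' harmfulness posterior of a carried variant), ties broken by variant id.
#'
#' @param table a [MarginalTable-class] from [runInference()].
#' @param cohort the [VariantCohort-class] the model was fitted to.
#' @param individual an individual id present in the cohort.
#' @return data.frame with columns \code{variant}, \code{gene},
#'   \code{dose}, \code{posterior}, ordered by decreasing posterior.
#' @export
rankPatientAberrations <- function(table, cohort, individual) {
    stopifnot(is(table, "MarginalTable"), is(cohort, "VariantCohort"))
    j <- match(individual, colnames(cohort))
    if (is.na(j)) stop("unknown individual: ", individual)
    dose <- as.numeric(genotypeCounts(cohort)[, j])
    carried <- which(dose > 0)
    v <- rownames(cohort)[carried]
    post <- table@variantMarginals[v]
    ord <- order(-post, v)
    data.frame(variant = v[ord],
               gene = variantGenes(cohort)[v][ord],
               dose = dose[carried][ord],
               posterior = unname(post[ord]),
               row.names = NULL)
}
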