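## Counting (cardinality) factor message passing.  A factor over n binary
## variables whose value depends only on their sum admits messages in
## O(n log^2 n) with a binary tree whose internal nodes carry distributions
## over intermediary sums; the quadratic direct convolution serves as the
## reference implementation.

## convolution of two distributions over sums 0..(length-1); FFT above a
## size cutoff keeps the sum tree O(n log^2 n) overall
convolveSum <- function(a, b) {
    la <- length(a); lb <- length(b)
    n <- la + lb - 1L
    if (as.double(la) * lb > 4096) {
        m <- stats::nextn(n, 2)
        fa <- stats::fft(c(a, numeric(m - la)))
        fb <- stats::fft(c(b, numeric(m - lb)))
        out <- Re(stats::fft(fa * fb, inverse = TRUE))[seq_len(n)] / m
        return(pmax(out, 0))
    }
    out <- numeric(n)
    for (k in seq_along(a))
        out[k:(k + lb - 1L)] <- out[k:(k + lb - 1L)] + a[k] * b
    out
}

## correlation: d over parent sums, u over sibling sums ->
## out[a+1] = sum_b d[a+b+1] * u[b+1]  (= convolution with reversed u)
correlateSum <- function(d, u, nOut) {
    w <- convolveSum(d, rev(u))
    w[seq.int(length(u), length.out = nOut)]
}

#' Counting-factor messages via a binary sum tree
#'
#' Computes, for a factor \eqn{f(\sum_k b_k)} over n binary variables with
#' incoming messages \code{incoming}, the outgoing message to every variable
#' and the factor's belief over the count.  Internal tree nodes hold
#' distributions over intermediary sums; an upward pass convolves children,
#' a downward pass distributes the context, giving
#' \eqn{O(n \log^2 n)} total work.
#'
#' @param incoming n x 2 matrix of incoming messages (columns: state 0,
#'   state 1); rows need not be normalized.
#' @param potential function mapping an integer count vector \code{0:n} to
#'   non-negative potential values.
#' @return list with \code{messages} (n x 2, rows normalized) and
#'   \code{countBelief} (normalized distribution over 0..n).
#' @seealso [countingFactorMessagesNaive()] for the quadratic reference.
#' @export
countingFactorMessages <- function(incoming, potential) {
    incoming <- matrix(as.numeric(incoming), ncol = 2)
    n <- nrow(incoming)
    f <- potential(0:n)
    stopifnot(length(f) == n + 1L, all(f >= 0))
    if (n == 0L)
        return(list(messages = incoming, countBelief = 1))

    ## upward pass: node distributions over partial sums
    up <- lapply(seq_len(n), function(k) incoming[k, ])
    levels <- list(up)
    while (length(up) > 1L) {
        nxt <- list()
        i <- 1L
        while (i + 1L <= length(up)) {
            nxt[[length(nxt) + 1L]] <- convolveSum(up[[i]], up[[i + 1L]])
            i <- i + 2L
        }
        if (i == length(up)) nxt[[length(nxt) + 1L]] <- up[[i]]
        levels[[length(levels) + 1L]] <- nxt
        up <- nxt
    }
    total <- up[[1L]]
    countBelief <- total * f
    countBelief <- countBelief / sum(countBelief)

    ## downward pass: context distributions (sum over all other leaves,
    ## weighted by the potential)
    down <- list(f)                       # context for the root
    for (lev in rev(seq_len(length(levels) - 1L))) {
        cur <- levels[[lev]]
        parentDown <- down
        down <- vector("list", length(cur))
        i <- 1L; p <- 1L
        while (i + 1L <= length(cur)) {
            d <- parentDown[[p]]
            down[[i]] <- correlateSum(d, cur[[i + 1L]], length(cur[[i]]))
            down[[i + 1L]] <- correlateSum(d, cur[[i]], length(cur[[i + 1L]]))
            i <- i + 2L; p <- p + 1L
        }
        if (i == length(cur)) down[[i]] <- parentDown[[p]]
        names(down) <- NULL
    }
    msgs <- do.call(rbind, down)
    msgs <- msgs / rowSums(msgs)
    list(messages = msgs, countBelief = countBelief)
}

#' Counting-factor messages by direct convolution
#'
#' Reference implementation with prefix/suffix dynamic-programming
#' convolutions, quadratic in n; semantics identical to
#' [countingFactorMessages()].  Guarded to n <= 20 as it exists for
#' testing.
#'
#' @inheritParams countingFactorMessages
#' @return same shape as [countingFactorMessages()].
#' @export
countingFactorMessagesNaive <- function(incoming, potential) {
    incoming <- matrix(as.numeric(incoming), ncol = 2)
    n <- nrow(incoming)
    if (n > 20L) stop("naive counting messages refused for n > 20")
    f <- potential(0:n)
    stopifnot(length(f) == n + 1L)
    if (n == 0L)
        return(list(messages = incoming, countBelief = 1))
    pre <- vector("list", n + 1L); pre[[1L]] <- 1
    for (k in seq_len(n))
        pre[[k + 1L]] <- convolveSum(pre[[k]], incoming[k, ])
    suf <- vector("list", n + 1L); suf[[n + 1L]] <- 1
    for (k in rev(seq_len(n)))
        suf[[k]] <- convolveSum(incoming[k, ], suf[[k + 1L]])
    msgs <- matrix(0, n, 2)
    for (k in seq_len(n)) {
        others <- convolveSum(pre[[k]], suf[[k + 1L]])  # sums 0..n-1
        for (b in 0:1)
            msgs[k, b + 1L] <- sum(others * f[(0:(n - 1L)) + b + 1L])
    }
    countBelief <- pre[[n + 1L]] * f
    list(messages = msgs / rowSums(msgs),
         countBelief = countBelief / sum(countBelief))
}
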