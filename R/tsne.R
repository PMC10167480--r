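#' Exact t-SNE embedding of progulon members
#'
#' Exact (non-approximated, theta = 0) t-distributed stochastic neighbour
#' embedding of a member-restricted dissimilarity matrix into two
#' dimensions. The conditional-distribution bandwidths are tuned per point
#' by binary search to match the requested perplexity; the layout is
#' optimised by gradient descent with early exaggeration and momentum.
#' Coordinates are deterministic given \code{rngSeed}. A perplexity too
#' large for the member count is shrunk to (n - 1) / 3 with a warning.
#'
#' @param d a [DissimilarityMatrix-class] or square matrix, restricted to
#'   the members to embed (>= 5 points). Undefined entries are imputed to
#'   the maximum observed dissimilarity.
#' @param perplexity target perplexity (default 30).
#' @param rngSeed integer seed for the initial layout.
#' @param maxIter gradient-descent iterations (default 500).
#' @return data.frame with columns \code{protein}, \code{x}, \code{y}.
#' @export
embedTsne <- function(d, perplexity = 30, rngSeed = 1L, maxIter = 500L) {
    dm <- if (is(d, "DissimilarityMatrix")) d@d else as.matrix(d)
    n <- nrow(dm)
    if (n < 5L) stop("need >= 5 members to embed")
    ids <- rownames(dm)
    if (is.null(ids)) ids <- as.character(seq_len(n))
    if (anyNA(dm)) dm[is.na(dm)] <- max(dm, na.rm = TRUE)
    diag(dm) <- 0
    maxPerp <- (n - 1) / 3
    if (perplexity > maxPerp) {
        warning(sprintf("perplexity %.1f too large for %d points; using %.2f",
                        perplexity, n, maxPerp))
        perplexity <- maxPerp
    }
    P <- tsneAffinities(dm^2, perplexity)
    P <- (P + t(P)) / (2 * n)
    P <- pmax(P / sum(P), .Machine$double.eps)
    set.seed(rngSeed)
    Y <- matrix(stats::rnorm(n * 2L, sd = 1e-4), n, 2L)
    gain <- matrix(1, n, 2L); inc <- matrix(0, n, 2L)
    eta <- 200
    exag <- 12
    for (iter in seq_len(maxIter)) {
        Pi <- if (iter <= 100L) P * exag else P
        num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
        diag(num) <- 0
        Q <- pmax(num / sum(num), .Machine$double.eps)
        L <- (Pi - Q) * num
        grad <- 4 * (diag(rowSums(L)) - L) %*% Y
        momentum <- if (iter <= 250L) 0.5 else 0.8
        sameSign <- sign(grad) == sign(inc)
        gain <- pmax(0.01, ifelse(sameSign, gain * 0.8, gain + 0.2))
        inc <- momentum * inc - eta * gain * grad
        Y <- Y + inc
        Y <- sweep(Y, 2L, colMeans(Y))
    }
    data.frame(protein = ids, x = Y[, 1L], y = Y[, 2L],
               stringsAsFactors = FALSE)
}

# per-point binary search for the precision beta matching the perplexity
tsneAffinities <- function(D2, perplexity, tol = 1e-5, maxTries = 50L) {
    n <- nrow(D2)
    target <- log(perplexity)
    P <- matrix(0, n, n)
    for (i in seq_len(n)) {
        beta <- 1; betaMin <- -Inf; betaMax <- Inf
        di <- D2[i, -i]
        for (try in seq_len(maxTries)) {
            p <- exp(-di * beta)
            sumP <- sum(p)
            if (sumP < .Machine$double.eps) sumP <- .Machine$double.eps
            H <- log(sumP) + beta * sum(di * p) / sumP
            if (abs(H - target) < tol) break
            if (H > target) {
                betaMin <- beta
                beta <- if (is.finite(betaMax)) (beta + betaMax) / 2 else beta * 2
            } else {
                betaMax <- beta
                beta <- if (is.finite(betaMin)) (beta + betaMin) / 2 else beta / 2
            }
        }
        P[i, -i] <- p / sumP
    }
    P
}
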