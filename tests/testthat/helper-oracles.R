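# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# one-sided (enrichment) Fisher P by hypergeometric tail enumeration
fisherGreaterOracle <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    xs <- a:min(m, k)
    sum(stats::dhyper(xs, m, n, k))
}

# two-sided Fisher P: sum of table probabilities not exceeding the observed
fisherTwoSidedOracle <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    xs <- max(0, k - n):min(m, k)
    probs <- stats::dhyper(xs, m, n, k)
    pObs <- stats::dhyper(a, m, n, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# pairwise-concordance AUC: ties count one half
aucOracle <- function(pos, neg) {
    cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
    mean(cmp)
}

# leaf-co-membership dissimilarity by explicit double loop over pairs/trees
treeClustOracle <- function(leaves) {
    n <- nrow(leaves)
    d <- matrix(NA_real_, n, n, dimnames = list(rownames(leaves),
                                                rownames(leaves)))
    for (i in seq_len(n)) for (k in seq_len(n)) {
        dis <- 0; usable <- 0
        for (t in seq_len(ncol(leaves))) {
            li <- leaves[i, t]; lk <- leaves[k, t]
            if (is.na(li) || is.na(lk)) next
            usable <- usable + 1
            if (li != lk) dis <- dis + 1
        }
        d[i, k] <- if (usable == 0) NA_real_ else dis / usable
    }
    d
}

# exhaustive search for the connected vertex subset maximizing cohesiveness
cohesivenessOracle <- function(W, penalty = 2) {
    n <- nrow(W)
    stopifnot(n <= 10)
    bestF <- -Inf; bestSet <- NULL
    for (mask in 1:(2^n - 1)) {
        idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
        if (length(idx) < 2) next
        # connectivity check by flood fill
        seen <- idx[1]
        repeat {
            nb <- which(colSums(W[seen, , drop = FALSE] > 0) > 0)
            grow <- intersect(setdiff(nb, seen), idx)
            if (!length(grow)) break
            seen <- c(seen, grow)
        }
        if (length(seen) < length(idx)) next
        f <- cohesiveness(W, idx, penalty)
        if (f > bestF + 1e-12) { bestF <- f; bestSet <- idx }
    }
    list(f = bestF, set = sort(rownames(W)[bestSet]))
}

# small two-block ratio matrix: proteins split into two groups with
# opposing responses over half the experiments
twoBlockMatrix <- function(nPerBlock = 10, nExp = 6, seed = 1) {
    set.seed(seed)
    z <- rep(c(2, -2), each = nExp / 2)
    m <- rbind(
        t(replicate(nPerBlock, z + rnorm(nExp, sd = 0.3))),
        t(replicate(nPerBlock, -z + rnorm(nExp, sd = 0.3))))
    dimnames(m) <- list(sprintf("P%02d", seq_len(2 * nPerBlock)),
                        sprintf("E%d", seq_len(nExp)))
    m
}

# hand-built screen dataset: one plate per readout, controls centred at
# given offset, gene siRNA activities specified directly
miniScreen <- function(geneValues, readout = "EdU", ctrl = c(-0.1, 0, 0.1),
                       plateOffset = 0) {
    rows <- list()
    for (rep in 1:3) {
        rows[[length(rows) + 1L]] <- data.frame(
            plate = "p1", well = sprintf("C%d", seq_along(ctrl)),
            sirna = sprintf("siCTRL_%d", seq_along(ctrl)), gene = "CTRL",
            readout = readout, condition = NA_character_, replicate = rep,
            value = plateOffset + ctrl, isNegativeControl = TRUE)
        for (g in names(geneValues)) {
            v <- geneValues[[g]]
            rows[[length(rows) + 1L]] <- data.frame(
                plate = "p1", well = sprintf("W%s%d", g, 1:3),
                sirna = sprintf("si%s_%d", g, 1:3), gene = g,
                readout = readout, condition = NA_character_,
                replicate = rep, value = plateOffset + v,
                isNegativeControl = FALSE)
        }
    }
    ScreenDataset(do.call(rbind, rows))
}
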