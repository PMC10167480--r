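#' Connectivity P-value of a candidate module
#'
#' One-sided (enrichment) Fisher's exact test asking whether the pairs
#' internal to the candidate member set are over-represented among the
#' edges of the top co-regulation network. The 2x2 table is built over all
#' unordered pairs within the universe: \{pair internal to members\} x
#' \{pair is a network edge\}. Pairs with undefined similarity (non-edges)
#' count as non-edges.
#'
#' @param memberIds character vector of member proteins (>= 2).
#' @param net a [CoregulationNetwork-class].
#' @param universe character vector of all proteins in the analysis;
#'   members must be contained in it.
#' @return the one-sided Fisher P-value.
#' @export
connectivityPvalue <- function(memberIds, net, universe) {
    stopifnot(length(universe) >= 2L, length(memberIds) >= 2L,
              all(memberIds %in% universe))
    e <- net@edges
    keep <- e$idA %in% universe & e$idB %in% universe
    e <- e[keep, , drop = FALSE]
    nU <- length(universe)
    totalPairs <- nU * (nU - 1) / 2
    m <- length(memberIds)
    internalPairs <- m * (m - 1) / 2
    isInt <- e$idA %in% memberIds & e$idB %in% memberIds
    edgeInt <- sum(isInt)
    edgeExt <- nrow(e) - edgeInt
    tab <- matrix(c(edgeInt, internalPairs - edgeInt,
                    edgeExt, (totalPairs - internalPairs) - edgeExt),
                  nrow = 2, byrow = TRUE)
    stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Select the minimal RF-score cutoff giving an interconnected module
#'
#' Walks the cutoff grid \{0.50, 0.51, ..., 1.00\} in ascending order and
#' returns the first cutoff at which the member set (proteins whose
#' effective score — LOO score for training positives, ensemble score
#' otherwise — reaches the cutoff) has at least two members and a
#' connectivity P-value below \code{alpha}. If no grid point qualifies the
#' progulon is discarded (\code{discard = TRUE}), which is a value, not an
#' error.
#'
#' @param scores a [ProgulonScores-class] (LOO scores present).
#' @param net a [CoregulationNetwork-class].
#' @param universe proteins forming the pair universe (default: all scored
#'   proteins).
#' @param alpha significance level (default 0.05).
#' @return list with \code{cutoff}, \code{connectivityP}, \code{discard},
#'   and \code{grid} (the per-cutoff P-values actually evaluated).
#' @export
selectCutoff <- function(scores, net, universe = NULL, alpha = 0.05) {
    tab <- scoreTable(scores)
    if (is.null(universe)) universe <- tab$protein
    eff <- effectiveScores(scores)
    grid <- round(seq(50L, 100L) / 100, 2)
    pvals <- rep(NA_real_, length(grid))
    for (k in seq_along(grid)) {
        mem <- tab$protein[eff >= grid[k] - 1e-9]
        if (length(mem) < 2L) { pvals[k] <- NA_real_; next }
        pvals[k] <- connectivityPvalue(mem, net, universe)
        if (pvals[k] < alpha) {
            return(list(cutoff = grid[k], connectivityP = pvals[k],
                        discard = FALSE,
                        grid = data.frame(cutoff = grid[seq_len(k)],
                                          p = pvals[seq_len(k)])))
        }
    }
    list(cutoff = NA_real_, connectivityP = NA_real_, discard = TRUE,
         grid = data.frame(cutoff = grid, p = pvals))
}

# effective score: LOO for training positives, ensemble score otherwise
effectiveScores <- function(scores) {
    tab <- scoreTable(scores)
    ifelse(tab$isTraining & !is.na(tab$looScore), tab$looScore, tab$rfScore)
}

#' Materialize a progulon from scores, cutoff and QC
#'
#' @param name module label.
#' @param scores a [ProgulonScores-class].
#' @param cutoff RF-score cutoff in [0.5, 1.0].
#' @param connectivityP the connectivity P-value at that cutoff.
#' @param qc a passing [QcReport-class].
#' @return a [Progulon-class].
#' @export
finalizeProgulon <- function(name, scores, cutoff, connectivityP, qc) {
    if (!isTRUE(qc@pass)) stop("assembly error: QC did not pass")
    if (is.na(cutoff) || cutoff < 0.5 || cutoff > 1)
        stop("assembly error: cutoff must lie in [0.5, 1.0]")
    tab <- scoreTable(scores)
    eff <- effectiveScores(scores)
    mem <- tab$protein[eff >= cutoff - 1e-9]
    obj <- new("Progulon", name = name, members = mem, cutoff = cutoff,
               connectivityP = connectivityP, qc = qc, scores = scores)
    validObject(obj)
    obj
}

#' Write per-protein scores and membership as TSV
#' @param scores a [ProgulonScores-class].
#' @param path destination file.
#' @param cutoff optional cutoff; adds a \code{member} column.
#' @export
writeScores <- function(scores, path, cutoff = NULL) {
    tab <- scoreTable(scores)
    if (!is.null(cutoff))
        tab$member <- effectiveScores(scores) >= cutoff - 1e-9
    utils::write.table(tab, path, sep = "\t", quote = FALSE, na = "",
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
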