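#' Pairwise-complete Spearman correlation matrix
#'
#' Correlations use only experiments in which both proteins were quantified
#' (missing values are ignored); pairs sharing fewer than \code{minOverlap}
#' experiments are undefined.
#'
#' @param x a [RatioMatrix-class] (or numeric matrix, rows = proteins).
#' @param minOverlap minimum shared non-missing experiments (>= 3).
#' @return a [CorrelationMatrix-class].
#' @export
spearmanMatrix <- function(x, minOverlap = 3L) {
    stopifnot(minOverlap >= 3L)
    v <- if (is(x, "RatioMatrix")) ratios(x) else as.matrix(x)
    rho <- suppressWarnings(
        stats::cor(t(v), method = "spearman", use = "pairwise.complete.obs"))
    obs <- !is.na(v)
    nov <- tcrossprod(obs * 1L)
    storage.mode(nov) <- "integer"
    rho[nov < minOverlap] <- NA_real_
    diag(rho)[diag(nov) >= minOverlap] <- 1
    new("CorrelationMatrix", rho = rho, nOverlap = nov,
        minOverlap = as.integer(minOverlap))
}

#' The top-fraction co-regulation network
#'
#' Keeps the ceiling(fraction x number of defined pairs) most similar
#' protein pairs: lowest dissimilarity for a [DissimilarityMatrix-class],
#' highest rho for a [CorrelationMatrix-class]. Boundary ties are broken by
#' lexicographic pair order so the edge set is deterministic.
#'
#' @param sim a DissimilarityMatrix or CorrelationMatrix.
#' @param fraction fraction of defined pairs to keep (default 0.005, the
#'   top 0.5\%).
#' @return a [CoregulationNetwork-class]; edge weights are similarities
#'   (1 - d for dissimilarities, rho for correlations).
#' @export
topEdges <- function(sim, fraction = 0.005) {
    stopifnot(fraction > 0, fraction < 1)
    if (is(sim, "DissimilarityMatrix")) {
        s <- 1 - sim@d
    } else if (is(sim, "CorrelationMatrix")) {
        s <- sim@rho
    } else stop("sim must be a DissimilarityMatrix or CorrelationMatrix")
    ids <- rownames(s)
    ut <- upper.tri(s)
    ii <- row(s)[ut]; jj <- col(s)[ut]; w <- s[ut]
    def <- !is.na(w)
    if (!any(def)) stop("all pairwise similarities are undefined")
    ii <- ii[def]; jj <- jj[def]; w <- w[def]
    nKeep <- min(ceiling(fraction * length(w)), length(w))
    ord <- order(-w, ids[ii], ids[jj])
    pick <- ord[seq_len(nKeep)]
    new("CoregulationNetwork", nodes = ids,
        edges = data.frame(idA = ids[ii[pick]], idB = ids[jj[pick]],
                           weight = w[pick], stringsAsFactors = FALSE),
        selectionFraction = fraction)
}

# dense symmetric weight matrix over the network's nodes (0 = no edge)
networkWeightMatrix <- function(net) {
    n <- length(net@nodes)
    W <- matrix(0, n, n, dimnames = list(net@nodes, net@nodes))
    e <- net@edges
    ia <- match(e$idA, net@nodes); ib <- match(e$idB, net@nodes)
    W[cbind(ia, ib)] <- e$weight
    W[cbind(ib, ia)] <- e$weight
    W
}

#' Write a square similarity/dissimilarity matrix as TSV
#' @param m matrix with dimnames, or DissimilarityMatrix/CorrelationMatrix.
#' @param path destination file.
#' @export
writeSquareTsv <- function(m, path) {
    m <- as.matrix(m)
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Write a network edge list as 3-column TSV
#' @param net a [CoregulationNetwork-class].
#' @param path destination file.
#' @export
writeEdgeList <- function(net, path) {
    utils::write.table(net@edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
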