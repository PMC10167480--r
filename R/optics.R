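#' OPTICS density clustering on a dissimilarity matrix
#'
#' Runs the OPTICS ordering (eps = Inf) on a precomputed protein
#' dissimilarity matrix and extracts clusters with the xi steepness
#' criterion. Undefined dissimilarities are imputed to the maximum observed
#' distance (reported via a message). Noise points remain unassigned.
#'
#' @param d a [DissimilarityMatrix-class] or square numeric matrix.
#' @param xi steepness threshold for cluster extraction (default 1e-4).
#' @param minPts density parameter; also the minimum cluster size
#'   (default 5).
#' @return list of character vectors (protein sets), one per flat cluster;
#'   attributes \code{order}, \code{reachability} (in ordering order) and
#'   \code{hierarchy} (all raw xi clusters as index ranges) expose the
#'   reachability profile for diagnostics.
#' @export
opticsClusters <- function(d, xi = 1e-4, minPts = 5L) {
    stopifnot(xi > 0, xi < 1, minPts >= 2L)
    dm <- if (is(d, "DissimilarityMatrix")) d@d else as.matrix(d)
    n <- nrow(dm)
    if (n < minPts) stop("fewer points than minPts")
    ids <- rownames(dm)
    if (is.null(ids)) ids <- as.character(seq_len(n))
    if (anyNA(dm)) {
        mx <- max(dm, na.rm = TRUE)
        message(sprintf("opticsClusters: %d undefined dissimilarities imputed to max distance %.4g",
                        sum(is.na(dm[upper.tri(dm)])), mx))
        dm[is.na(dm)] <- mx
    }
    diag(dm) <- 0
    ord <- opticsOrder(dm, minPts)
    reach <- ord$reach[ord$order]
    clus <- extractXiClusters(reach, xi, minPts)
    flat <- flattenXi(clus, n)
    grp <- split(seq_len(n), flat)
    grp <- grp[names(grp) != "0"]
    sets <- lapply(grp, function(ix) ids[ord$order[ix]])
    names(sets) <- NULL
    structure(sets, order = ids[ord$order], reachability = reach,
              hierarchy = clus)
}

# OPTICS ordering with eps = Inf; core distance = distance to the
# (minPts-1)-th nearest other point (the point itself counts towards minPts).
opticsOrder <- function(dm, minPts) {
    n <- nrow(dm)
    core <- vapply(seq_len(n), function(i)
        sort(dm[i, -i])[minPts - 1L], numeric(1))
    processed <- logical(n)
    reach <- rep(Inf, n)
    ordering <- integer(n)
    pos <- 0L
    seedsReach <- rep(Inf, n)  # tentative reachability for unprocessed points
    for (start in seq_len(n)) {
        if (processed[start]) next
        cur <- start
        repeat {
            processed[cur] <- TRUE
            pos <- pos + 1L
            ordering[pos] <- cur
            reach[cur] <- seedsReach[cur]
            newReach <- pmax(core[cur], dm[cur, ])
            upd <- !processed & newReach < seedsReach
            seedsReach[upd] <- newReach[upd]
            cand <- which(!processed & is.finite(seedsReach))
            if (!length(cand)) break
            cur <- cand[which.min(seedsReach[cand])]
        }
    }
    list(order = ordering, reach = reach, core = core)
}

# xi steep-area cluster extraction on a reachability profile (Ankerst et al).
# Returns a list of index ranges [s, e] on the ordering. A sentinel value
# above every reachability is appended so clusters reaching the end of the
# plot are closed by a final steep-up area.
extractXiClusters <- function(reach, xi, minPts) {
    n <- length(reach)
    r <- reach
    finMax <- max(r[is.finite(r)], 0)
    cap <- finMax * 1.05 + 1e-9
    r[!is.finite(r)] <- cap
    r <- c(r, cap * 1.05)
    ixi <- 1 - xi
    steepDown <- function(i) i <= n && r[i] * ixi >= r[i + 1L]
    steepUp <- function(i) i <= n && r[i] <= r[i + 1L] * ixi
    sdas <- list()
    clusters <- list()
    index <- 1L
    mib <- 0
    filterSdas <- function(sdas, mib) {
        keep <- list()
        for (D in sdas) {
            if (r[D$s] * ixi >= mib) {
                D$mib <- max(D$mib, mib)
                keep[[length(keep) + 1L]] <- D
            }
        }
        keep
    }
    while (index <= n) {
        mib <- max(mib, r[index])
        if (steepDown(index)) {
            sdas <- filterSdas(sdas, mib)
            s <- index
            lastSteep <- index
            cur <- index + 1L
            while (cur <= n) {
                if (r[cur] < r[cur + 1L]) break
                if (steepDown(cur)) lastSteep <- cur
                else if (cur - lastSteep >= minPts) break
                cur <- cur + 1L
            }
            e <- lastSteep
            sdas[[length(sdas) + 1L]] <- list(s = s, e = e, mib = 0)
            index <- e + 1L
            mib <- r[min(index, n + 1L)]
        } else if (steepUp(index)) {
            sdas <- filterSdas(sdas, mib)
            us <- index
            lastSteep <- index
            cur <- index + 1L
            while (cur <= n) {
                if (r[cur] > r[cur + 1L]) break
                if (steepUp(cur)) lastSteep <- cur
                else if (cur - lastSteep >= minPts) break
                cur <- cur + 1L
            }
            ue <- lastSteep
            rEnd <- r[ue + 1L]
            for (D in sdas) {
                if (rEnd * ixi < D$mib) next
                if (D$mib > r[D$s] * ixi) next
                if (r[D$s] * ixi >= rEnd) {
                    cand <- which(r[D$s:D$e] <= rEnd)
                    cs <- if (length(cand)) D$s + cand[1L] - 1L else D$s
                    ce <- ue
                } else if (rEnd * ixi >= r[D$s]) {
                    cand <- which(r[us:ue] <= r[D$s])
                    cs <- D$s
                    ce <- if (length(cand)) us + cand[length(cand)] - 1L else ue
                } else {
                    cs <- D$s
                    ce <- ue
                }
                ce <- min(ce, n)
                if (ce - cs + 1L >= minPts && cs < ce)
                    clusters[[length(clusters) + 1L]] <- c(cs, ce)
            }
            index <- ue + 1L
            mib <- r[min(index, n + 1L)]
        } else {
            index <- index + 1L
        }
    }
    clusters
}

# flat assignment: each ordering position gets its smallest enclosing xi
# cluster; 0 = noise
flattenXi <- function(clusters, n) {
    flat <- integer(n)
    if (!length(clusters)) return(flat)
    sizes <- vapply(clusters, function(cl) cl[2L] - cl[1L] + 1L, numeric(1))
    for (k in order(sizes, decreasing = TRUE)) {
        cl <- clusters[[k]]
        flat[cl[1L]:cl[2L]] <- k
    }
    # renumber consecutively
    u <- unique(flat[flat > 0L])
    match(flat, u, nomatch = 0L)
}
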