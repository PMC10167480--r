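#' Cohesiveness (ClusterONE-style) graph clustering
#'
#' Greedy growth of cohesive vertex groups on the weighted co-regulation
#' network. The cohesiveness of a vertex set V is
#' \deqn{f(V) = w_{in} / (w_{in} + w_{bound} + penalty |V|)}
#' where \eqn{w_{in}} is the total weight of edges inside V and
#' \eqn{w_{bound}} the total weight of edges crossing its boundary. Each
#' unused vertex, taken in order of decreasing weighted degree, seeds a
#' candidate group which grows by the single vertex addition or removal
#' that most increases f, until no move improves it. Candidates whose
#' overlap (match coefficient \eqn{|A \cap B|^2 / (|A||B|)}) reaches
#' \code{mergeOverlap} are merged, and only groups with at least
#' \code{minSize} members and internal edge density at least
#' \code{densityThreshold} are kept.
#'
#' @param net a [CoregulationNetwork-class] with edge weights.
#' @param minSize minimum cluster size (default 4).
#' @param densityThreshold minimum internal density, i.e. sum of internal
#'   edge weights over the number of vertex pairs (default 0.4).
#' @param penalty cohesiveness penalty per vertex (default 2).
#' @param mergeOverlap match-coefficient threshold for merging (default 0.8).
#' @return list of character vectors (protein sets), ordered by decreasing
#'   cohesiveness; each set carries its cohesiveness as attribute
#'   \code{"cohesiveness"}.
#' @export
clusterOneClusters <- function(net, minSize = 4L, densityThreshold = 0.4,
                               penalty = 2, mergeOverlap = 0.8) {
    stopifnot(is(net, "CoregulationNetwork"), minSize >= 2L,
              densityThreshold >= 0, densityThreshold <= 1)
    if (nrow(net@edges) == 0L) stop("empty graph")
    touched <- sort(unique(c(net@edges$idA, net@edges$idB)))
    W <- networkWeightMatrix(net)[touched, touched, drop = FALSE]
    n <- nrow(W)
    deg <- rowSums(W)
    cands <- list()
    for (v in order(-deg, rownames(W))) {
        grp <- growCohesive(W, v, penalty)
        cands[[length(cands) + 1L]] <- grp
    }
    sets <- unique(lapply(cands, function(g) sort(rownames(W)[g$members])))
    sets <- mergeOverlapping(sets, mergeOverlap)
    keep <- list()
    for (s in sets) {
        idx <- match(s, rownames(W))
        win <- sum(W[idx, idx]) / 2
        npair <- length(idx) * (length(idx) - 1) / 2
        dens <- if (npair > 0) win / npair else 0
        if (length(idx) >= minSize && dens >= densityThreshold) {
            attr(s, "cohesiveness") <- cohesiveness(W, idx, penalty)
            keep[[length(keep) + 1L]] <- s
        }
    }
    ord <- order(-vapply(keep, attr, numeric(1), "cohesiveness"))
    keep[ord]
}

#' Cohesiveness of a vertex set
#' @param W symmetric weight matrix.
#' @param idx integer (or logical) indices of the vertex set.
#' @param penalty per-vertex penalty.
#' @return the cohesiveness value f(V).
#' @export
cohesiveness <- function(W, idx, penalty = 2) {
    win <- sum(W[idx, idx, drop = FALSE]) / 2
    wtot <- sum(W[idx, , drop = FALSE])
    wbound <- wtot - 2 * win
    win / (win + wbound + penalty * length(idx))
}

# greedy add/remove growth from a single seed vertex
growCohesive <- function(W, seed, penalty) {
    n <- nrow(W)
    inV <- logical(n)
    inV[seed] <- TRUE
    wToV <- W[, seed]            # weight from every vertex to V
    win <- 0
    wbound <- sum(wToV)
    size <- 1L
    f <- win / (win + wbound + penalty * size)
    repeat {
        ext <- which(!inV & wToV > 0)
        bestGain <- 0; bestV <- NA_integer_; bestAdd <- NA
        if (length(ext)) {
            addWin <- win + wToV[ext]
            addBound <- wbound - wToV[ext] + (rowSums(W)[ext] - wToV[ext])
            addF <- addWin / (addWin + addBound + penalty * (size + 1L))
            k <- which.max(addF)
            if (addF[k] > f + 1e-12) {
                bestGain <- addF[k] - f; bestV <- ext[k]; bestAdd <- TRUE
            }
        }
        if (size > 1L) {
            int <- which(inV)
            remWin <- win - wToV[int]
            remBound <- wbound + wToV[int] - (rowSums(W)[int] - wToV[int])
            remF <- remWin / (remWin + remBound + penalty * (size - 1L))
            k <- which.max(remF)
            if (remF[k] > f + bestGain + 1e-12) {
                bestV <- int[k]; bestAdd <- FALSE
            }
        }
        if (is.na(bestV)) break
        if (bestAdd) {
            win <- win + wToV[bestV]
            wbound <- wbound - wToV[bestV] + (sum(W[bestV, ]) - wToV[bestV])
            inV[bestV] <- TRUE
            size <- size + 1L
            wToV <- wToV + W[, bestV]
        } else {
            wToV <- wToV - W[, bestV]
            win <- win - wToV[bestV]
            wbound <- wbound + wToV[bestV] - (sum(W[bestV, ]) - wToV[bestV])
            inV[bestV] <- FALSE
            size <- size - 1L
        }
        f <- win / (win + wbound + penalty * size)
    }
    list(members = which(inV), f = f)
}

# transitively merge sets whose match coefficient reaches the threshold
mergeOverlapping <- function(sets, threshold) {
    repeat {
        m <- length(sets)
        if (m < 2L) return(sets)
        bestOm <- threshold - 1e-12; bi <- 0L; bj <- 0L
        for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
            ov <- length(intersect(sets[[i]], sets[[j]]))
            om <- ov^2 / (length(sets[[i]]) * length(sets[[j]]))
            if (om > bestOm) { bestOm <- om; bi <- i; bj <- j }
        }
        if (bi == 0L) return(sets)
        sets[[bi]] <- sort(union(sets[[bi]], sets[[bj]]))
        sets[[bj]] <- NULL
    }
}

#' Derive seed groups by intersecting OPTICS and cohesiveness clusters
#'
#' For each OPTICS cluster the single cohesiveness cluster with the largest
#' member overlap is selected (ties broken by larger Jaccard index, then
#' lexicographically); each cohesiveness cluster can serve at most one
#' OPTICS cluster (the best match wins globally). The seed is the
#' intersection — only proteins grouped by both algorithms — and seeds
#' smaller than \code{minSeed} are dropped.
#'
#' @param opticsSets list of protein sets from [opticsClusters()].
#' @param c1Sets list of protein sets from [clusterOneClusters()].
#' @param minSeed minimum seed size (default 4).
#' @return list of [SeedGroup-class] objects (possibly empty).
#' @export
deriveSeeds <- function(opticsSets, c1Sets, minSeed = 4L) {
    stopifnot(length(opticsSets) > 0, length(c1Sets) > 0)
    pairs <- NULL
    for (i in seq_along(opticsSets)) for (j in seq_along(c1Sets)) {
        ov <- length(intersect(opticsSets[[i]], c1Sets[[j]]))
        if (ov == 0L) next
        jac <- ov / length(union(opticsSets[[i]], c1Sets[[j]]))
        pairs <- rbind(pairs, data.frame(
            i = i, j = j, overlap = ov, jaccard = jac,
            key = paste(sort(opticsSets[[i]]), collapse = "|")))
    }
    seeds <- list()
    if (is.null(pairs)) return(seeds)
    pairs <- pairs[order(-pairs$overlap, -pairs$jaccard, pairs$key), ]
    usedO <- logical(length(opticsSets)); usedC <- logical(length(c1Sets))
    k <- 0L
    for (r in seq_len(nrow(pairs))) {
        i <- pairs$i[r]; j <- pairs$j[r]
        if (usedO[i] || usedC[j]) next
        usedO[i] <- TRUE; usedC[j] <- TRUE
        inter <- sort(intersect(opticsSets[[i]], c1Sets[[j]]))
        if (length(inter) < minSeed) next
        k <- k + 1L
        seeds[[k]] <- SeedGroup(sprintf("seed_%02d", k), inter, "clustering")
    }
    seeds
}
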