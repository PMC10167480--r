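#' Annotation enrichment of protein groups
#'
#' One-sided Fisher's exact enrichment of each group in each annotation set
#' of at least \code{minSetSize} members, Bonferroni-corrected over all
#' tested (group, set) combinations. The universe is restricted to analysed
#' proteins that carry at least one annotation.
#'
#' @param groups named list of protein sets (e.g. progulon memberships).
#' @param annotations named list of annotation sets (e.g. from [readGmt()]).
#' @param universe character vector of analysed proteins; the effective
#'   universe is its intersection with the annotated proteins.
#' @param minSetSize minimum annotation-set size after restriction to the
#'   universe (default 20).
#' @return data.frame with columns \code{group}, \code{set}, \code{overlap},
#'   \code{groupSize}, \code{setSize}, \code{pRaw}, \code{pBonferroni}.
#' @export
annotationEnrichment <- function(groups, annotations, universe,
                                 minSetSize = 20L) {
    annotated <- unique(unlist(annotations))
    uni <- intersect(universe, annotated)
    if (!length(uni)) stop("empty universe: no analysed protein is annotated")
    sets <- lapply(annotations, intersect, y = uni)
    sets <- sets[lengths(sets) >= minSetSize]
    groupsU <- lapply(groups, intersect, y = uni)
    out <- list()
    for (g in names(groupsU)) for (s in names(sets)) {
        grp <- groupsU[[g]]; st <- sets[[s]]
        a <- length(intersect(grp, st))
        tab <- matrix(c(a, length(grp) - a,
                        length(st) - a,
                        length(uni) - length(grp) - length(st) + a),
                      nrow = 2, byrow = TRUE)
        p <- stats::fisher.test(tab, alternative = "greater")$p.value
        out[[length(out) + 1L]] <- data.frame(
            group = g, set = s, overlap = a, groupSize = length(grp),
            setSize = length(st), pRaw = p, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    if (is.null(res)) return(data.frame())
    res$pBonferroni <- pmin(1, res$pRaw * nrow(res))
    res[order(res$pRaw), ]
}

#' Per-gene mRNA-to-protein contribution
#'
#' Pairwise-complete Spearman correlation between a gene's mRNA and protein
#' abundance changes across samples — the extent to which transcript
#' changes explain protein changes.
#'
#' @param po a [PairedOmics-class].
#' @param genes genes to evaluate (default: all).
#' @param minOverlap minimum complete sample pairs (default 3).
#' @return named numeric vector of rho (NA when overlap is insufficient).
#' @export
contributionRho <- function(po, genes = NULL, minOverlap = 3L) {
    if (is.null(genes)) genes <- rownames(po@mrna)
    vapply(genes, function(g) {
        a <- po@mrna[g, ]; b <- po@protein[g, ]
        ok <- !is.na(a) & !is.na(b)
        if (sum(ok) < minOverlap) return(NA_real_)
        suppressWarnings(stats::cor(a[ok], b[ok], method = "spearman"))
    }, numeric(1))
}

#' Monte-Carlo permutation test for a group median
#'
#' Tests whether the median of a per-gene statistic over a gene group is
#' extreme relative to random gene sets of the same size drawn from the
#' universe. The P estimator is (r + 1) / (B + 1), so the smallest
#' attainable P is 1 / (B + 1).
#'
#' @param perGeneStat named numeric vector (per-gene statistic; NAs are
#'   excluded from medians).
#' @param group character vector of genes, a subset of the universe.
#' @param universe character vector (default: names of perGeneStat).
#' @param B Monte-Carlo replications (default 10000).
#' @param side "high" (observed median larger than null), "low", or
#'   "two.sided".
#' @param rngSeed integer seed.
#' @return list with \code{p}, \code{observed}, \code{nullMedians}.
#' @export
groupPermutationTest <- function(perGeneStat, group, universe = NULL,
                                 B = 10000L, side = c("high", "low", "two.sided"),
                                 rngSeed = 1L) {
    side <- match.arg(side)
    stopifnot(B >= 1L)
    if (is.null(universe)) universe <- names(perGeneStat)
    if (length(group) > length(universe)) stop("group larger than universe")
    stopifnot(all(group %in% universe))
    obs <- stats::median(perGeneStat[group], na.rm = TRUE)
    set.seed(rngSeed)
    nullMed <- vapply(seq_len(B), function(b)
        stats::median(perGeneStat[sample(universe, length(group))],
                      na.rm = TRUE),
        numeric(1))
    r <- switch(side,
                high = sum(nullMed >= obs),
                low = sum(nullMed <= obs),
                two.sided = {
                    ctr <- stats::median(nullMed)
                    sum(abs(nullMed - ctr) >= abs(obs - ctr))
                })
    list(p = (r + 1) / (B + 1), observed = obs, nullMedians = nullMed)
}

#' Within-group expression coordination
#'
#' Median pairwise-complete Spearman correlation over all within-group
#' pairs of rows; undefined pairs are excluded. Applied to the mRNA matrix
#' this measures mRNA coordination, to the protein matrix protein
#' coordination.
#'
#' @param mat gene x sample numeric matrix.
#' @param group genes in the group (>= 2).
#' @param minOverlap minimum shared samples per pair (default 3).
#' @return median pairwise rho (NA if every pair is undefined).
#' @export
groupCoordination <- function(mat, group, minOverlap = 3L) {
    stopifnot(length(group) >= 2L)
    sub <- mat[group, , drop = FALSE]
    rho <- suppressWarnings(
        stats::cor(t(sub), method = "spearman", use = "pairwise.complete.obs"))
    obs <- !is.na(sub)
    nov <- tcrossprod(obs * 1L)
    rho[nov < minOverlap] <- NA
    vals <- rho[upper.tri(rho)]
    if (all(is.na(vals))) return(NA_real_)
    stats::median(vals, na.rm = TRUE)
}

#' Summary statistics for a gene group on a paired omics panel
#'
#' Bundles the contribution (median per-gene mRNA-to-protein rho), mRNA and
#' protein coordination (median within-group pairwise rho), the scale of
#' variation (median MAD of protein changes), and permutation P-values for
#' enrichment of high and low contribution.
#'
#' @param po a [PairedOmics-class].
#' @param group gene set.
#' @param B permutation replications (default 10000).
#' @param rngSeed integer seed.
#' @return one-row data.frame of group statistics.
#' @export
groupStats <- function(po, group, B = 10000L, rngSeed = 1L) {
    contrib <- contributionRho(po)
    pHigh <- groupPermutationTest(contrib, group, B = B, side = "high",
                                  rngSeed = rngSeed)$p
    pLow <- groupPermutationTest(contrib, group, B = B, side = "low",
                                 rngSeed = rngSeed)$p
    data.frame(
        contribution = stats::median(contrib[group], na.rm = TRUE),
        mrnaCoordination = groupCoordination(po@mrna, group),
        proteinCoordination = groupCoordination(po@protein, group),
        scale = scaleOfVariation(po@protein, group),
        permPHigh = pHigh, permPLow = pLow)
}

#' Conservation of co-regulation between two datasets
#'
#' Among protein pairs co-regulated (rho > rhoMin) in dataset A, counts the
#' fraction that are also co-regulated in dataset B, split by progulon
#' category: both proteins in the same progulon, in different progulons, or
#' neither assigned to any progulon. Fisher's exact test compares
#' same-progulon pairs against the rest.
#'
#' @param rhoA,rhoB symmetric correlation matrices ([CorrelationMatrix-class]
#'   or plain matrices) for datasets A and B.
#' @param orthologMap named character vector mapping A-protein IDs to
#'   B-protein IDs (one-to-one).
#' @param membership named character vector: protein -> progulon name;
#'   proteins absent from it are unassigned.
#' @param rhoMin co-regulation threshold (default 0.5).
#' @return list with \code{table} (per-category counts and conservation
#'   rates) and \code{fisherP}.
#' @export
conservationOfCoregulation <- function(rhoA, rhoB, orthologMap, membership,
                                       rhoMin = 0.5) {
    A <- as.matrix(rhoA); B <- as.matrix(rhoB)
    if (anyDuplicated(orthologMap) || anyDuplicated(names(orthologMap)))
        stop("orthologMap must be one-to-one")
    prots <- intersect(rownames(A), names(orthologMap))
    prots <- prots[orthologMap[prots] %in% rownames(B)]
    if (length(prots) < 2L) stop("no mappable pairs")
    A <- A[prots, prots]
    B <- B[orthologMap[prots], orthologMap[prots]]
    ut <- upper.tri(A)
    coA <- !is.na(A[ut]) & A[ut] > rhoMin
    coB <- !is.na(B[ut]) & B[ut] > rhoMin
    pi <- row(A)[ut][coA]; pj <- col(A)[ut][coA]
    consB <- coB[coA]
    mi <- membership[prots[pi]]; mj <- membership[prots[pj]]
    cat3 <- ifelse(is.na(mi) & is.na(mj), "no_progulon",
                   ifelse(!is.na(mi) & !is.na(mj) & mi == mj,
                          "same_progulon", "different_progulons"))
    tab <- do.call(rbind, lapply(
        c("no_progulon", "different_progulons", "same_progulon"),
        function(ct) {
            sel <- cat3 == ct
            data.frame(category = ct, pairs = sum(sel),
                       conserved = sum(consB[sel]),
                       rate = if (sum(sel)) mean(consB[sel]) else NA_real_)
        }))
    same <- cat3 == "same_progulon"
    ft <- matrix(c(sum(consB[same]), sum(!consB[same]),
                   sum(consB[!same]), sum(!consB[!same])), nrow = 2)
    p <- if (any(is.na(ft)) || sum(ft) == 0) NA_real_
         else stats::fisher.test(ft)$p.value
    list(table = tab, fisherP = p)
}

#' Same-chromosome enrichment of a gene group
#'
#' Compares the fraction of within-group gene pairs located on the same
#' chromosome against the same-chromosome pair fraction of the full mapped
#' universe, with a two-sided Fisher's exact test on the pair counts.
#' Unmapped group genes are excluded with a warning.
#'
#' @param group gene set.
#' @param chromMap named character vector: gene -> chromosome (the mapped
#'   universe).
#' @return list with \code{observed}, \code{expected}, \code{fisherP},
#'   \code{unmapped}.
#' @export
sameChromosomeEnrichment <- function(group, chromMap) {
    unmapped <- setdiff(group, names(chromMap))
    if (length(unmapped))
        warning("unmapped genes excluded: ", paste(unmapped, collapse = ", "))
    group <- intersect(group, names(chromMap))
    stopifnot(length(group) >= 2L)
    samePairFrac <- function(chroms) {
        n <- length(chroms)
        tot <- n * (n - 1) / 2
        same <- sum(choose(table(chroms), 2))
        c(same = same, total = tot)
    }
    og <- samePairFrac(chromMap[group])
    ou <- samePairFrac(chromMap)
    tab <- matrix(c(og["same"], og["total"] - og["same"],
                    ou["same"] - og["same"],
                    (ou["total"] - og["total"]) - (ou["same"] - og["same"])),
                  nrow = 2, byrow = TRUE)
    list(observed = unname(og["same"] / og["total"]),
         expected = unname(ou["same"] / ou["total"]),
         fisherP = stats::fisher.test(tab, alternative = "two.sided")$p.value,
         unmapped = unmapped)
}

#' Scale of expression variation of a group
#'
#' Per-member median absolute deviation of the row across samples (raw MAD,
#' no consistency scaling), then the median over members.
#'
#' @param mat gene x sample matrix.
#' @param group gene set (>= 1).
#' @return median per-member MAD.
#' @export
scaleOfVariation <- function(mat, group) {
    stopifnot(length(group) >= 1L)
    mads <- apply(mat[group, , drop = FALSE], 1L, function(r)
        stats::mad(r, constant = 1, na.rm = TRUE))
    stats::median(mads, na.rm = TRUE)
}
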