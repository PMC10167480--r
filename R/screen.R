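#' The default siRNA validation screen catalog
#'
#' Twenty-one readouts grouped into three phenotype processes. Replication
#' readouts (max 5 points): EdU incorporation with and without aphidicolin,
#' RPA loading untreated and under hydroxyurea or aphidicolin. DNA-damage
#' readouts (max 4): 53BP1 foci and gamma-H2A.X untreated and under HU or
#' Aph. Cell-cycle phase readouts (G1/S/G2M population changes) are grouped
#' into four experimental conditions (EdU-based and PCNA-based without
#' stress, PCNA-based + HU, EdU-based + Aph), each capped at one point,
#' giving a maximum cumulative score of 13.
#'
#' @return data.frame with columns \code{readout}, \code{process},
#'   \code{condition} (NA outside cell cycle).
#' @export
defaultReadoutCatalog <- function() {
    repl <- c("EdU", "EdU_Aph", "RPA", "RPA_HU", "RPA_Aph")
    dmg <- c("53BP1", "gH2AX", "gH2AX_HU", "gH2AX_Aph")
    ccCond <- c("cc_EdU", "cc_PCNA", "cc_PCNA_HU", "cc_EdU_Aph")
    cc <- unlist(lapply(ccCond, function(cd) paste(cd, c("G1", "S", "G2M"),
                                                   sep = "_")))
    data.frame(
        readout = c(repl, dmg, cc),
        process = c(rep("replication", length(repl)),
                    rep("dna_damage", length(dmg)),
                    rep("cell_cycle", length(cc))),
        condition = c(rep(NA_character_, length(repl) + length(dmg)),
                      rep(ccCond, each = 3L)),
        stringsAsFactors = FALSE)
}

#' Construct a ScreenDataset
#'
#' @param wells long-format data.frame (columns \code{plate}, \code{well},
#'   \code{sirna}, \code{gene}, \code{readout}, \code{condition},
#'   \code{replicate}, \code{value}, \code{isNegativeControl}).
#' @param catalog readout catalog (default [defaultReadoutCatalog()]).
#' @return a [ScreenDataset-class].
#' @export
ScreenDataset <- function(wells, catalog = defaultReadoutCatalog()) {
    obj <- new("ScreenDataset", wells = as.data.frame(wells),
               catalog = as.data.frame(catalog))
    validObject(obj)
    obj
}

#' Read a screen dataset from long-format TSV
#' @param path TSV with the well columns of [ScreenDataset()].
#' @param catalog readout catalog.
#' @export
readScreenTsv <- function(path, catalog = defaultReadoutCatalog()) {
    w <- data.table::fread(path, sep = "\t", data.table = FALSE)
    w$isNegativeControl <- as.logical(w$isNegativeControl)
    ScreenDataset(w, catalog)
}

#' Normalize plate-to-plate variability against negative controls
#'
#' Subtracts, within each (plate, readout, replicate), the median of the
#' negative-control wells from every value — the screen library is biased,
#' so the plate median is not a valid reference. Adds a \code{normValue}
#' column.
#'
#' @param s a [ScreenDataset-class].
#' @return the dataset with normalized values.
#' @export
normalizePlates <- function(s) {
    w <- s@wells
    chk <- stats::aggregate(isNegativeControl ~ plate + readout, data = w,
                            FUN = sum)
    bad <- chk$plate[chk$isNegativeControl < 2L]
    if (length(bad))
        stop("plate(s) without >= 2 negative-control wells: ",
             paste(unique(bad), collapse = ", "))
    key <- interaction(w$plate, w$readout, w$replicate, drop = TRUE)
    ctrlMed <- tapply(w$value[w$isNegativeControl],
                      key[w$isNegativeControl], stats::median)
    shift <- ctrlMed[as.character(key)]
    if (anyNA(shift))
        stop("plate/readout/replicate group without negative controls: ",
             paste(unique(w$plate[is.na(shift)]), collapse = ", "))
    w$normValue <- w$value - as.numeric(shift)
    initialize(s, wells = w)
}

# per-siRNA activity: mean (or median) of normalized replicate values
sirnaActivity <- function(s, combine = c("mean", "median")) {
    combine <- match.arg(combine)
    w <- s@wells
    if (is.null(w$normValue)) stop("run normalizePlates() first")
    fun <- if (combine == "mean") mean else stats::median
    stats::aggregate(normValue ~ gene + sirna + readout + isNegativeControl,
                     data = w, FUN = fun)
}

#' Per-readout hit threshold from negative-control variability
#'
#' The threshold tier depends on the assay's variability, measured as the
#' standard deviation of the replicate-combined normalized negative-control
#' activities across plates: 3x SD for SD <= 0.05 (low variability), 2x SD
#' for 0.05 < SD <= 0.13 (medium), 1x SD for SD > 0.13 (high).
#'
#' @param ctrlValues numeric vector of combined negative-control values for
#'   one readout (>= 3 values).
#' @return the threshold; SD of exactly 0 yields threshold 0 with a warning.
#' @export
readoutThreshold <- function(ctrlValues) {
    ctrlValues <- ctrlValues[!is.na(ctrlValues)]
    if (length(ctrlValues) < 3L) stop("need >= 3 control values")
    s <- stats::sd(ctrlValues)
    if (s == 0) {
        warning("control SD is 0; threshold set to 0")
        return(0)
    }
    mult <- if (s <= 0.05) 3 else if (s <= 0.13) 2 else 1
    mult * s
}

#' Per-readout thresholds for a whole screen
#' @param s a normalized [ScreenDataset-class].
#' @param combine replicate combination, "mean" (default) or "median".
#' @return named numeric vector, one threshold per readout.
#' @export
screenThresholds <- function(s, combine = "mean") {
    act <- sirnaActivity(s, combine)
    ctrl <- act[act$isNegativeControl, ]
    vapply(split(ctrl$normValue, ctrl$readout), readoutThreshold, numeric(1))
}

#' Call per-gene, per-readout hits with the 2-of-3 siRNA rule
#'
#' A gene is a hit in a readout when at least two of its three siRNAs
#' deviate beyond the readout's threshold in the same direction; a readout
#' contributes at most one hit regardless of direction. Readouts can
#' restrict the biologically meaningful direction via the \code{direction}
#' column of the catalog ("both" when absent).
#'
#' @param s a normalized [ScreenDataset-class].
#' @param thresholds named vector from [screenThresholds()].
#' @param combine replicate combination ("mean" default).
#' @return data.frame with columns \code{gene}, \code{readout}, \code{hit},
#'   \code{direction}.
#' @export
callGeneHits <- function(s, thresholds = screenThresholds(s),
                         combine = "mean") {
    act <- sirnaActivity(s, combine)
    act <- act[!act$isNegativeControl, ]
    dirAllowed <- s@catalog$direction
    if (is.null(dirAllowed)) dirAllowed <- rep("both", nrow(s@catalog))
    names(dirAllowed) <- s@catalog$readout
    out <- list()
    for (ro in unique(act$readout)) {
        thr <- thresholds[[ro]]
        sub <- act[act$readout == ro, ]
        for (g in unique(sub$gene)) {
            v <- sub$normValue[sub$gene == g]
            if (length(v) != 3L)
                stop(sprintf("gene %s has %d siRNAs in readout %s (need 3)",
                             g, length(v), ro))
            allow <- dirAllowed[[ro]]
            up <- sum(v > thr) >= 2L && allow %in% c("both", "up")
            down <- sum(v < -thr) >= 2L && allow %in% c("both", "down")
            hit <- up || down
            out[[length(out) + 1L]] <- data.frame(
                gene = g, readout = ro, hit = hit,
                direction = if (up) "up" else if (down) "down" else NA_character_,
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out)
}

#' Cumulative siRNA validation score per gene
#'
#' Sums per-readout hits under the process caps: each replication and
#' DNA-damage readout contributes at most +1 (maxima 5 and 4), and each of
#' the four cell-cycle experimental conditions contributes at most +1 no
#' matter how many phase readouts change (maximum 4), for a maximum
#' cumulative score of 13. Confidence tiers: high above half the maximum,
#' medium above a third, otherwise unvalidated.
#'
#' @param hits data.frame from [callGeneHits()].
#' @param catalog readout catalog (default [defaultReadoutCatalog()]).
#' @return data.frame (one row per gene): \code{replication},
#'   \code{dnaDamage}, \code{cellCycle}, \code{cumulative},
#'   \code{confidence}.
#' @export
cumulativeScore <- function(hits, catalog = defaultReadoutCatalog()) {
    unknown <- setdiff(hits$readout, catalog$readout)
    if (length(unknown))
        stop("readout(s) missing from catalog: ",
             paste(unknown, collapse = ", "))
    maxScore <- 13L
    proc <- catalog$process[match(hits$readout, catalog$readout)]
    cond <- catalog$condition[match(hits$readout, catalog$readout)]
    out <- lapply(split(seq_len(nrow(hits)), hits$gene), function(ix) {
        h <- hits$hit[ix]; p <- proc[ix]; cd <- cond[ix]
        repl <- min(5L, sum(h & p == "replication"))
        dmg <- min(4L, sum(h & p == "dna_damage"))
        ccHits <- tapply(h[p == "cell_cycle"], cd[p == "cell_cycle"],
                         function(z) as.integer(any(z)))
        cc <- min(4L, sum(ccHits, na.rm = TRUE))
        total <- repl + dmg + cc
        conf <- if (total > maxScore / 2) "high"
                else if (total > maxScore / 3) "medium" else "unvalidated"
        data.frame(gene = hits$gene[ix][1L], replication = repl,
                   dnaDamage = dmg, cellCycle = cc, cumulative = total,
                   confidence = conf, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res[order(-res$cumulative, res$gene), ]
}
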