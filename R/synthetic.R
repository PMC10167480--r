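#' Specify a planted co-regulation module
#'
#' A module's members share a latent perturbation-response vector; each
#' member adds independent noise. The implied pairwise correlation between
#' two members with noise scales s1, s2 is
#' responseSd^2 / sqrt((responseSd^2 + s1^2)(responseSd^2 + s2^2)); with
#' the defaults (responseSd 2, noiseSd 1) a body-body pair has correlation
#' 0.8, in the range of tightly co-regulated complexes.
#'
#' Modules have heterogeneous tightness, as real co-regulation modules do:
#' the first \code{coreSize} members form a tight core with reduced noise
#' (\code{coreNoiseSd}), emulating the strictly clustered or
#' well-characterised proteins that serve as seeds, while the remaining
#' body is looser. Set \code{coreSize = 0} for a homogeneous module.
#'
#' @param size module size (>= 4).
#' @param responseSd latent effect scale (log2-ratio units).
#' @param noiseSd member-specific noise scale of the module body.
#' @param coreSize members in the tight core (default a third of the
#'   module).
#' @param coreNoiseSd noise scale of core members (default noiseSd / 2).
#' @param detectionFraction expected non-missing rate per member.
#' @return a "moduleSpec" list.
#' @export
moduleSpec <- function(size, responseSd = 2, noiseSd = 1,
                       coreSize = ceiling(size / 3),
                       coreNoiseSd = noiseSd / 2, detectionFraction = 1) {
    stopifnot(size >= 4L, coreSize >= 0L, coreSize <= size,
              detectionFraction > 0, detectionFraction <= 1)
    structure(list(size = as.integer(size), responseSd = responseSd,
                   noiseSd = noiseSd, coreSize = as.integer(coreSize),
                   coreNoiseSd = coreNoiseSd,
                   targetPairwiseRho = responseSd^2 / (responseSd^2 + noiseSd^2),
                   detectionFraction = detectionFraction),
              class = "moduleSpec")
}

#' Simulate a perturbation-response ratio matrix with planted modules
#'
#' Emulates a large isotope-labelling compendium: each planted module rides
#' a shared latent response across experiments, background proteins are
#' independent noise, and missingness is block-structured — each protein is
#' quantified in a contiguous run of "project" columns sized to its
#' detection fraction — because proteins are typically quantified only in
#' the subset of projects that detected them (uniform missingness is
#' available via \code{missingness = "uniform"}). Latents and noise are
#' Gaussian by default; \code{heavyTails = TRUE} draws noise from a t
#' distribution (df = 3) to mimic ratio outliers.
#'
#' @param nProteins total proteins (module members + background).
#' @param nExperiments perturbation experiments (columns).
#' @param modules list of [moduleSpec()] objects (sum of sizes <=
#'   nProteins).
#' @param backgroundDetection detection fraction of background proteins.
#' @param missingness "block" (default) or "uniform".
#' @param heavyTails use t(3) noise instead of Gaussian.
#' @param rngSeed integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @return list with \code{matrix} (a [RatioMatrix-class]) and
#'   \code{truth} (module membership, latents and parameters).
#' @export
simulateProteomeHd <- function(nProteins, nExperiments, modules = list(),
                               backgroundDetection = 1,
                               missingness = c("block", "uniform"),
                               heavyTails = FALSE, rngSeed = 1L) {
    missingness <- match.arg(missingness)
    sizes <- vapply(modules, function(m) m$size, integer(1))
    if (sum(sizes) > nProteins) stop("module sizes exceed nProteins")
    set.seed(rngSeed)
    rnoise <- function(n, sd) {
        if (heavyTails) sd * stats::rt(n, df = 3) / sqrt(3)
        else stats::rnorm(n, sd = sd)
    }
    mat <- matrix(NA_real_, nProteins, nExperiments,
                  dimnames = list(sprintf("P%04d", seq_len(nProteins)),
                                  sprintf("E%03d", seq_len(nExperiments))))
    memb <- rep(NA_character_, nProteins)
    core <- logical(nProteins)
    latents <- list()
    row <- 0L
    for (k in seq_along(modules)) {
        ms <- modules[[k]]
        z <- stats::rnorm(nExperiments, sd = ms$responseSd)
        latents[[k]] <- z
        for (i in seq_len(ms$size)) {
            row <- row + 1L
            inCore <- i <= ms$coreSize
            sdN <- if (inCore) ms$coreNoiseSd else ms$noiseSd
            mat[row, ] <- z + rnoise(nExperiments, sdN)
            memb[row] <- sprintf("module_%02d", k)
            core[row] <- inCore
        }
    }
    if (row < nProteins)
        mat[(row + 1L):nProteins, ] <-
            rnoise((nProteins - row) * nExperiments, 1)
    detect <- vapply(seq_len(nProteins), function(i) {
        if (is.na(memb[i])) backgroundDetection
        else modules[[as.integer(sub("module_", "", memb[i]))]]$detectionFraction
    }, numeric(1))
    for (i in seq_len(nProteins)) {
        nObs <- max(2L, round(detect[i] * nExperiments))
        if (nObs >= nExperiments) next
        if (missingness == "block") {
            start <- sample.int(nExperiments - nObs + 1L, 1L)
            keep <- seq(start, length.out = nObs)
        } else {
            keep <- sample.int(nExperiments, nObs)
        }
        mat[i, -keep] <- NA_real_
    }
    list(matrix = RatioMatrix(mat),
         truth = list(membership = stats::setNames(memb, rownames(mat)),
                      core = stats::setNames(core, rownames(mat)),
                      latents = latents, modules = modules,
                      rngSeed = rngSeed))
}

#' Simulate a paired mRNA/protein abundance panel
#'
#' Gene groups share an mRNA-level latent (scaled by
#' \code{mrnaCoordination}, which controls mRNA-mRNA correlation) and a
#' protein-level latent (\code{proteinLatentSd}); protein change = coupling
#' x mRNA change + protein latent + noise. The coupling controls the
#' mRNA-to-protein contribution, and the protein latent lets protein
#' coordination exceed what the mRNA transmits — so coordination and
#' contribution can be tuned independently.
#'
#' @param nGenes genes outside any group are independent background.
#' @param nSamples samples (e.g. cell lines of a panel).
#' @param groups list of lists with fields \code{size}, \code{coupling}
#'   (alpha in [0, 1]), \code{mrnaLatentSd}, \code{proteinLatentSd},
#'   \code{noiseSd}.
#' @param rngSeed integer seed.
#' @return list with \code{omics} (a [PairedOmics-class]) and \code{truth}.
#' @export
simulatePairedOmics <- function(nGenes, nSamples, groups = list(),
                                rngSeed = 1L) {
    sizes <- vapply(groups, function(g) g$size, numeric(1))
    if (sum(sizes) > nGenes) stop("group sizes exceed nGenes")
    set.seed(rngSeed)
    gid <- sprintf("G%04d", seq_len(nGenes))
    sid <- sprintf("S%02d", seq_len(nSamples))
    mrna <- matrix(stats::rnorm(nGenes * nSamples), nGenes, nSamples,
                   dimnames = list(gid, sid))
    prot <- matrix(NA_real_, nGenes, nSamples, dimnames = list(gid, sid))
    memb <- rep(NA_character_, nGenes)
    row <- 0L
    for (k in seq_along(groups)) {
        g <- groups[[k]]
        zM <- stats::rnorm(nSamples, sd = g$mrnaLatentSd)
        zP <- stats::rnorm(nSamples, sd = g$proteinLatentSd)
        for (i in seq_len(g$size)) {
            row <- row + 1L
            mrna[row, ] <- zM + stats::rnorm(nSamples, sd = g$noiseSd)
            prot[row, ] <- g$coupling * mrna[row, ] + zP +
                stats::rnorm(nSamples, sd = g$noiseSd)
            memb[row] <- sprintf("group_%02d", k)
        }
    }
    if (row < nGenes) {
        bg <- (row + 1L):nGenes
        prot[bg, ] <- 0.5 * mrna[bg, ] +
            matrix(stats::rnorm(length(bg) * nSamples), length(bg))
    }
    list(omics = PairedOmics(mrna, prot),
         truth = list(membership = stats::setNames(memb, gid),
                      groups = groups, rngSeed = rngSeed))
}

#' Simulate a plate-structured siRNA screen
#'
#' Each gene gets three siRNAs; each plate carries negative-control wells.
#' Control wells draw from N(plate offset, readout SD); wells of true
#' positive genes are shifted by \code{effectSize} x readout SD in the
#' designated readouts, with per-siRNA efficacy jitter (one siRNA in three
#' may be weak, as in real libraries). Replicates follow the assay design:
#' three per readout, six under aphidicolin.
#'
#' @param genes character vector of gene names.
#' @param truePositives subset of genes carrying the phenotype.
#' @param effectSize shift in units of the readout SD (default 5).
#' @param effectReadouts readouts in which true positives respond
#'   (default: all catalog readouts).
#' @param readoutSd within-plate control SD per readout (default 0.1,
#'   medium variability tier).
#' @param plateOffsetSd between-plate offset SD (default 0.3).
#' @param nControls negative-control wells per plate (default 8).
#' @param sirnaEfficacySd per-siRNA multiplicative efficacy jitter.
#' @param catalog readout catalog (default [defaultReadoutCatalog()]).
#' @param rngSeed integer seed.
#' @return a [ScreenDataset-class].
#' @export
simulateScreen <- function(genes, truePositives = character(0),
                           effectSize = 5, effectReadouts = NULL,
                           readoutSd = 0.1, plateOffsetSd = 0.3,
                           nControls = 8L, sirnaEfficacySd = 0.15,
                           catalog = defaultReadoutCatalog(), rngSeed = 1L) {
    stopifnot(all(truePositives %in% genes))
    if (is.null(effectReadouts)) effectReadouts <- catalog$readout
    set.seed(rngSeed)
    rows <- list()
    effic <- matrix(pmax(0, 1 + stats::rnorm(length(genes) * 3L,
                                             sd = sirnaEfficacySd)),
                    nrow = length(genes),
                    dimnames = list(genes, NULL))
    for (ro in catalog$readout) {
        nRep <- if (grepl("Aph", ro)) 6L else 3L
        plate <- paste0("plate_", ro)
        offset <- stats::rnorm(1L, sd = plateOffsetSd)
        eff <- if (ro %in% effectReadouts) effectSize * readoutSd else 0
        for (rep in seq_len(nRep)) {
            ctrl <- data.frame(
                plate = plate, well = sprintf("C%02d", seq_len(nControls)),
                sirna = sprintf("siCTRL_%02d", seq_len(nControls)),
                gene = "CTRL", readout = ro,
                condition = catalog$condition[catalog$readout == ro],
                replicate = rep,
                value = offset + stats::rnorm(nControls, sd = readoutSd),
                isNegativeControl = TRUE, stringsAsFactors = FALSE)
            gi <- rep(genes, each = 3L)
            si <- paste0("si", gi, "_", rep(1:3, length(genes)))
            shift <- ifelse(gi %in% truePositives,
                            eff * effic[cbind(match(gi, genes),
                                              rep(1:3, length(genes)))],
                            0)
            gw <- data.frame(
                plate = plate,
                well = sprintf("W%03d", seq_along(gi)),
                sirna = si, gene = gi, readout = ro,
                condition = catalog$condition[catalog$readout == ro],
                replicate = rep,
                value = offset + shift +
                    stats::rnorm(length(gi), sd = readoutSd),
                isNegativeControl = FALSE, stringsAsFactors = FALSE)
            rows[[length(rows) + 1L]] <- rbind(ctrl, gw)
        }
    }
    ScreenDataset(do.call(rbind, rows), catalog)
}
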