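#' Derive seed groups de novo from a ratio matrix
#'
#' Runs the full dual-clustering route: surrogate-tree dissimilarities,
#' OPTICS (on the complete dissimilarity matrix) and cohesiveness
#' clustering (on the top-fraction network only — the two algorithms
#' deliberately see different inputs), then intersects matched clusters
#' into seed groups.
#'
#' @param x a [RatioMatrix-class].
#' @param xi OPTICS steepness threshold (default 1e-4).
#' @param minPts OPTICS density parameter (default 5).
#' @param fraction network edge fraction (default 0.005).
#' @param minSize,densityThreshold,penalty,mergeOverlap cohesiveness
#'   clustering parameters (defaults 4, 0.4, 2, 0.8).
#' @param minSeed minimum seed size (default 4).
#' @param rngSeed integer seed.
#' @return list with \code{seeds} (list of [SeedGroup-class]),
#'   \code{dissimilarity}, \code{network}, \code{opticsSets},
#'   \code{clusterOneSets}.
#' @export
findSeeds <- function(x, xi = 1e-4, minPts = 5L, fraction = 0.005,
                      minSize = 4L, densityThreshold = 0.4, penalty = 2,
                      mergeOverlap = 0.8, minSeed = 4L, rngSeed = 1L) {
    forest <- fitSurrogateTrees(x, seed = rngSeed)
    d <- treeClustDissimilarity(forest)
    net <- topEdges(d, fraction)
    op <- opticsClusters(d, xi = xi, minPts = minPts)
    c1 <- clusterOneClusters(net, minSize = minSize,
                             densityThreshold = densityThreshold,
                             penalty = penalty, mergeOverlap = mergeOverlap)
    seeds <- deriveSeeds(op, c1, minSeed = minSeed)
    list(seeds = seeds, dissimilarity = d, network = net,
         opticsSets = op, clusterOneSets = c1)
}

#' Find a progulon from a seed group
#'
#' The complete search for one seed: training assembly, balanced ensemble
#' scoring, leave-one-out cross-validation, QC gates, and selection of the
#' minimal RF-score cutoff that yields a significantly interconnected
#' module against the top co-regulation network. A failed QC or a cutoff
#' grid with no significant point yields a discard result
#' (\code{status != "ok"}), not an error.
#'
#' @param x a [RatioMatrix-class].
#' @param seed a [SeedGroup-class] or character vector of protein IDs.
#' @param net optional [CoregulationNetwork-class]; computed from the
#'   matrix (surrogate trees, top \code{fraction}) when NULL.
#' @param name progulon name (defaults to the seed's name).
#' @param nNegatives,nTrees,minTrainFeatures,minTestFeatures training
#'   parameters (defaults 1000, 500, 45, 30).
#' @param fraction network edge fraction when the network is computed here.
#' @param alpha connectivity significance level (default 0.05).
#' @param rngSeed integer seed.
#' @return list with \code{status} ("ok", "qc_fail" or "discard"),
#'   \code{progulon} (NULL unless ok), \code{scores}, \code{qc},
#'   \code{cutoff}, \code{connectivityP}, \code{config}.
#' @export
findProgulon <- function(x, seed, net = NULL, name = NULL,
                         nNegatives = 1000L, nTrees = 500L,
                         minTrainFeatures = 45L, minTestFeatures = 30L,
                         fraction = 0.005, alpha = 0.05, rngSeed = 1L) {
    if (!is(seed, "SeedGroup"))
        seed <- SeedGroup(if (is.null(name)) "user_seed" else name,
                          seed, "user")
    if (is.null(name)) name <- seed@name
    cfg <- assembleTraining(seed, x, nNegatives = nNegatives,
                            nTrees = nTrees,
                            minTrainFeatures = minTrainFeatures,
                            minTestFeatures = minTestFeatures,
                            rngSeed = rngSeed)
    scores <- ensembleScores(x, cfg, loo = TRUE)
    qc <- qcCheck(scores, cfg@negatives)
    if (!qc@pass)
        return(list(status = "qc_fail", progulon = NULL, scores = scores,
                    qc = qc, cutoff = NA_real_, connectivityP = NA_real_,
                    config = cfg))
    if (is.null(net)) {
        forest <- fitSurrogateTrees(x, seed = rngSeed)
        net <- topEdges(treeClustDissimilarity(forest), fraction)
    }
    sel <- selectCutoff(scores, net, universe = scoreTable(scores)$protein,
                        alpha = alpha)
    if (sel$discard)
        return(list(status = "discard", progulon = NULL, scores = scores,
                    qc = qc, cutoff = NA_real_, connectivityP = NA_real_,
                    config = cfg))
    pg <- finalizeProgulon(name, scores, sel$cutoff, sel$connectivityP, qc)
    list(status = "ok", progulon = pg, scores = scores, qc = qc,
         cutoff = sel$cutoff, connectivityP = sel$connectivityP,
         config = cfg)
}

#' Export a progulon search as files
#'
#' Writes the score table (TSV), the membership as GMT, and a JSON run
#' report with all resolved parameters, seeds and QC values.
#'
#' @param result list from [findProgulon()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default: the progulon/seed name).
#' @return invisibly, the report list.
#' @export
exportProgulon <- function(result, dir, prefix = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (is.null(prefix))
        prefix <- if (!is.null(result$progulon)) result$progulon@name
                  else "progulon"
    writeScores(result$scores, file.path(dir, paste0(prefix, "_scores.tsv")),
                cutoff = result$cutoff)
    if (!is.null(result$progulon)) {
        sets <- stats::setNames(list(result$progulon@members),
                                result$progulon@name)
        writeGmt(sets, file.path(dir, paste0(prefix, ".gmt")))
        writeGmt(sets, file.path(dir, paste0(prefix, ".gmx")),
                 format = "gmx")
    }
    cfg <- result$config
    report <- list(
        status = result$status,
        name = prefix,
        parameters = list(nPositives = length(cfg@positives),
                          nNegatives = length(cfg@negatives),
                          nTrees = cfg@nTrees,
                          minTrainFeatures = cfg@minTrainFeatures,
                          minTestFeatures = cfg@minTestFeatures,
                          rngSeed = cfg@rngSeed,
                          nModels = result$scores@nModels),
        qc = list(auc = result$qc@auc,
                  top10TrainingCount = result$qc@top10TrainingCount,
                  pass = result$qc@pass),
        cutoff = result$cutoff,
        connectivityP = result$connectivityP,
        nMembers = if (!is.null(result$progulon))
            length(result$progulon@members) else 0L)
    jsonlite::write_json(report, file.path(dir, paste0(prefix, "_report.json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(report)
}
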