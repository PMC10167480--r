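#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' RatioMatrix: a protein x perturbation log2-ratio matrix
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a single
#' assay \code{"lratio"} of log2 expression ratios (proteins in rows,
#' perturbation experiments in columns). Missing values (\code{NA}) mark
#' experiments in which a protein was not quantified; the number of
#' non-missing values of a protein is its feature count, which gates
#' eligibility for model training and scoring.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @seealso [RatioMatrix()], [featureCounts()], [eligibleProteins()]
#' @exportClass RatioMatrix
setClass("RatioMatrix", contains = "SummarizedExperiment")

setValidity("RatioMatrix", function(object) {
    msg <- character()
    if (!"lratio" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'lratio' is required")
    ids <- rownames(object)
    if (is.null(ids) || is.null(colnames(object)))
        msg <- c(msg, "protein (row) and experiment (column) names are required")
    if (!is.null(ids) && anyDuplicated(ids))
        msg <- c(msg, paste0("duplicated protein IDs: ",
                             paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (!is.null(colnames(object)) && anyDuplicated(colnames(object)))
        msg <- c(msg, paste0("duplicated experiment IDs: ",
                             paste(unique(colnames(object)[duplicated(colnames(object))]),
                                   collapse = ", ")))
    if ("lratio" %in% SummarizedExperiment::assayNames(object)) {
        v <- SummarizedExperiment::assay(object, "lratio")
        if (!is.numeric(v)) msg <- c(msg, "ratios must be numeric")
        else if (any(is.infinite(v))) msg <- c(msg, "ratios must be finite where present")
    }
    if (length(msg)) msg else TRUE
})

#' SeedGroup: a small set of tightly co-regulated proteins
#'
#' Seed groups are the positive training class for the Random-Forest search.
#' They come either from dual clustering ([deriveSeeds()]) or from a
#' user-supplied protein list ([mapSeedIds()]). A seed must contain at least
#' four members.
#'
#' @slot name single character, the seed's label.
#' @slot members character vector of protein IDs (unique).
#' @slot provenance either \code{"clustering"} or \code{"user"}.
#' @exportClass SeedGroup
setClass("SeedGroup", representation(
    name = "character", members = "character", provenance = "character"))

setValidity("SeedGroup", function(object) {
    msg <- character()
    if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
    if (anyDuplicated(object@members)) msg <- c(msg, "members must be unique")
    if (length(object@members) < 4L)
        msg <- c(msg, sprintf("a seed group needs >= 4 members, got %d",
                              length(object@members)))
    if (!object@provenance %in% c("clustering", "user"))
        msg <- c(msg, "provenance must be 'clustering' or 'user'")
    if (length(msg)) msg else TRUE
})

#' DissimilarityMatrix: tree-based pairwise protein dissimilarities
#'
#' Symmetric matrix of leaf-disagreement dissimilarities in [0, 1] computed
#' from a forest of per-experiment surrogate regression trees
#' ([treeClustDissimilarity()]). \code{NA} marks pairs with no usable tree.
#'
#' @slot d symmetric numeric matrix with protein IDs as dimnames.
#' @slot nTreesUsed number of retained (informative) trees.
#' @exportClass DissimilarityMatrix
setClass("DissimilarityMatrix",
         representation(d = "matrix", nTreesUsed = "integer"))

setValidity("DissimilarityMatrix", function(object) {
    d <- object@d
    msg <- character()
    if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
        msg <- c(msg, "d must have identical row/column protein IDs")
    if (any(d < -1e-12 | d > 1 + 1e-12, na.rm = TRUE))
        msg <- c(msg, "dissimilarities must lie in [0, 1]")
    if (any(abs(diag(d)) > 1e-12, na.rm = TRUE))
        msg <- c(msg, "self-dissimilarity must be 0")
    if (any(abs(d - t(d)) > 1e-12, na.rm = TRUE))
        msg <- c(msg, "d must be symmetric")
    if (length(msg)) msg else TRUE
})

#' CorrelationMatrix: pairwise-complete Spearman correlations
#'
#' @slot rho symmetric numeric matrix in [-1, 1]; \code{NA} below the
#'   overlap threshold.
#' @slot nOverlap integer matrix of shared non-missing experiments per pair.
#' @slot minOverlap minimum overlap below which rho is undefined.
#' @exportClass CorrelationMatrix
setClass("CorrelationMatrix",
         representation(rho = "matrix", nOverlap = "matrix",
                        minOverlap = "integer"))

setValidity("CorrelationMatrix", function(object) {
    msg <- character()
    if (any(abs(object@rho) > 1 + 1e-8, na.rm = TRUE))
        msg <- c(msg, "|rho| must be <= 1")
    if (!identical(dim(object@rho), dim(object@nOverlap)))
        msg <- c(msg, "rho and nOverlap must have identical dimensions")
    if (length(msg)) msg else TRUE
})

#' CoregulationNetwork: the top-fraction co-regulation graph
#'
#' Undirected graph over proteins whose edges are the most similar fraction
#' (default 0.5\%) of all pairs with a defined similarity; see [topEdges()].
#'
#' @slot nodes protein IDs spanning the similarity universe.
#' @slot edges data.frame with columns \code{idA}, \code{idB},
#'   \code{weight} (similarity, higher = more co-regulated).
#' @slot selectionFraction fraction of defined pairs kept.
#' @exportClass CoregulationNetwork
setClass("CoregulationNetwork",
         representation(nodes = "character", edges = "data.frame",
                        selectionFraction = "numeric"))

setValidity("CoregulationNetwork", function(object) {
    e <- object@edges
    msg <- character()
    if (!all(c("idA", "idB", "weight") %in% names(e)))
        msg <- c(msg, "edges need columns idA, idB, weight")
    else {
        if (any(e$idA == e$idB)) msg <- c(msg, "self-edges are not allowed")
        if (!all(c(e$idA, e$idB) %in% object@nodes))
            msg <- c(msg, "edge endpoints must be network nodes")
    }
    if (length(msg)) msg else TRUE
})

#' TrainingConfig: resolved training set-up for one progulon search
#'
#' @slot positives seed proteins surviving the training feature filter.
#' @slot negatives randomly drawn eligible non-seed proteins (the pool).
#' @slot nTrees trees per balanced model (default 500, unlimited depth).
#' @slot minTrainFeatures,minTestFeatures feature-count minima (45 / 30 by
#'   default; 7 / 5 for small experiment subsets).
#' @slot rngSeed integer seed governing all random draws.
#' @exportClass TrainingConfig
setClass("TrainingConfig", representation(
    positives = "character", negatives = "character", nTrees = "integer",
    minTrainFeatures = "integer", minTestFeatures = "integer",
    rngSeed = "integer"))

setValidity("TrainingConfig", function(object) {
    msg <- character()
    if (length(intersect(object@positives, object@negatives)))
        msg <- c(msg, "positives and negatives must be disjoint")
    if (length(object@positives) < 4L)
        msg <- c(msg, "need >= 4 eligible positives")
    if (object@nTrees < 1L) msg <- c(msg, "nTrees must be >= 1")
    if (length(msg)) msg else TRUE
})

#' ProgulonScores: per-protein Random-Forest scores
#'
#' Result of [ensembleScores()] (plus [looCrossValidate()]): for every
#' scoreable protein the averaged fraction of trees voting it into the
#' positive class, and for every training protein the leave-one-out
#' cross-validated score.
#'
#' @slot table data.frame with columns \code{protein}, \code{rfScore},
#'   \code{isTraining}, \code{looScore} (NA for non-positives),
#'   \code{featureCount}.
#' @slot nModels number of balanced models averaged.
#' @exportClass ProgulonScores
setClass("ProgulonScores",
         representation(table = "data.frame", nModels = "integer"))

setValidity("ProgulonScores", function(object) {
    tab <- object@table
    msg <- character()
    need <- c("protein", "rfScore", "isTraining", "looScore", "featureCount")
    if (!all(need %in% names(tab)))
        msg <- c(msg, paste("table needs columns:", paste(need, collapse = ", ")))
    else {
        if (any(tab$rfScore < 0 | tab$rfScore > 1, na.rm = TRUE))
            msg <- c(msg, "rfScore must lie in [0, 1]")
        if (any(tab$looScore < 0 | tab$looScore > 1, na.rm = TRUE))
            msg <- c(msg, "looScore must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' QcReport: quality-control verdict for a progulon model
#'
#' A model passes only if the ROC AUC on leave-one-out cross-validated
#' training data is at least 0.99 and at least four of the ten
#' highest-scoring proteins are cross-validated training proteins.
#'
#' @slot auc ROC AUC (positives = LOO scores of seed proteins, negatives =
#'   ensemble scores of the negative training pool).
#' @slot top10TrainingCount cross-validated training proteins among the 10
#'   top-scoring proteins.
#' @slot pass logical verdict.
#' @exportClass QcReport
setClass("QcReport", representation(
    auc = "numeric", top10TrainingCount = "integer", pass = "logical"))

setValidity("QcReport", function(object) {
    expect <- (object@auc >= 0.99) && (object@top10TrainingCount >= 4L)
    if (!identical(object@pass, expect))
        "pass must equal (auc >= 0.99) && (top10TrainingCount >= 4)"
    else TRUE
})

#' Progulon: a finalized co-regulation module
#'
#' @slot name module label.
#' @slot members proteins whose (cross-validated) score clears the cutoff.
#' @slot cutoff minimal RF-score cutoff in [0.5, 1.0] at which the module is
#'   significantly interconnected.
#' @slot connectivityP Fisher's exact enrichment P of internal pairs among
#'   the top co-regulation network edges.
#' @slot qc the [QcReport-class] of the underlying model.
#' @slot scores the [ProgulonScores-class] the module was cut from.
#' @exportClass Progulon
setClass("Progulon", representation(
    name = "character", members = "character", cutoff = "numeric",
    connectivityP = "numeric", qc = "QcReport", scores = "ProgulonScores"))

setValidity("Progulon", function(object) {
    msg <- character()
    if (object@cutoff < 0.5 - 1e-9 || object@cutoff > 1 + 1e-9)
        msg <- c(msg, "cutoff must lie in [0.5, 1.0]")
    if (!isTRUE(object@qc@pass)) msg <- c(msg, "qc must pass")
    if (length(msg)) msg else TRUE
})

#' PairedOmics: matched mRNA and protein abundance-change matrices
#'
#' @slot mrna,protein gene x sample numeric matrices with identical
#'   dimnames; missing values allowed.
#' @exportClass PairedOmics
setClass("PairedOmics", representation(mrna = "matrix", protein = "matrix"))

setValidity("PairedOmics", function(object) {
    if (!identical(dimnames(object@mrna), dimnames(object@protein)) ||
        !identical(dim(object@mrna), dim(object@protein)))
        "mrna and protein must share dimensions and dimnames"
    else TRUE
})

#' ScreenDataset: plate-structured high-content siRNA screen readouts
#'
#' @slot wells long-format data.frame with columns \code{plate},
#'   \code{well}, \code{sirna}, \code{gene}, \code{readout},
#'   \code{condition}, \code{replicate}, \code{value},
#'   \code{isNegativeControl}.
#' @slot catalog data.frame mapping each readout to a process group
#'   (\code{replication}, \code{dna_damage} or \code{cell_cycle}) and, for
#'   cell-cycle readouts, the experimental condition it belongs to.
#' @exportClass ScreenDataset
setClass("ScreenDataset",
         representation(wells = "data.frame", catalog = "data.frame"))

setValidity("ScreenDataset", function(object) {
    msg <- character()
    need <- c("plate", "well", "sirna", "gene", "readout", "condition",
              "replicate", "value", "isNegativeControl")
    if (!all(need %in% names(object@wells)))
        msg <- c(msg, paste("wells needs columns:", paste(need, collapse = ", ")))
    needc <- c("readout", "process", "condition")
    if (!all(needc %in% names(object@catalog)))
        msg <- c(msg, "catalog needs columns readout, process, condition")
    else if (!all(object@catalog$process %in%
                  c("replication", "dna_damage", "cell_cycle")))
        msg <- c(msg, "catalog process must be replication/dna_damage/cell_cycle")
    if (length(msg)) msg else TRUE
})
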