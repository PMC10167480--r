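#' Construct a RatioMatrix
#'
#' @param mat numeric matrix of log2 ratios; rownames = protein IDs,
#'   colnames = experiment IDs. \code{NA} marks missing quantifications.
#' @return a [RatioMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("P", 1:4), paste0("E", 1:3)))
#' rm <- RatioMatrix(m)
#' featureCounts(rm)
#' @export
RatioMatrix <- function(mat) {
    mat <- as.matrix(mat)
    storage.mode(mat) <- "double"
    obj <- new("RatioMatrix",
               SummarizedExperiment::SummarizedExperiment(
                   assays = list(lratio = mat)))
    validObject(obj)
    obj
}

#' @rdname RatioMatrix
#' @param x a RatioMatrix.
#' @export
setMethod("ratios", "RatioMatrix", function(x)
    SummarizedExperiment::assay(x, "lratio"))

#' @rdname RatioMatrix
#' @export
setMethod("featureCounts", "RatioMatrix", function(x) {
    v <- ratios(x)
    n <- as.integer(rowSums(!is.na(v)))
    names(n) <- rownames(v)
    n
})

#' @rdname RatioMatrix
#' @export
setMethod("proteinIds", "RatioMatrix", function(x) rownames(x))

#' @rdname RatioMatrix
#' @export
setMethod("experimentIds", "RatioMatrix", function(x) colnames(x))

setMethod("show", "RatioMatrix", function(object) {
    v <- ratios(object)
    cat("RatioMatrix:", nrow(v), "proteins x", ncol(v), "experiments\n")
    cat(sprintf("  missing: %.1f%%; median feature count: %d\n",
                100 * mean(is.na(v)),
                as.integer(stats::median(featureCounts(object)))))
})

#' @rdname SeedGroup
#' @param name seed label.
#' @param members character vector of protein IDs.
#' @param provenance \code{"clustering"} or \code{"user"}.
#' @export
SeedGroup <- function(name, members, provenance = c("user", "clustering")) {
    obj <- new("SeedGroup", name = as.character(name),
               members = unique(as.character(members)),
               provenance = match.arg(provenance))
    validObject(obj)
    obj
}

#' @rdname SeedGroup
#' @param x a SeedGroup.
#' @export
setMethod("members", "SeedGroup", function(x) x@members)

setMethod("show", "SeedGroup", function(object) {
    cat(sprintf("SeedGroup '%s' (%s): %d proteins\n", object@name,
                object@provenance, length(object@members)))
})

setMethod("show", "DissimilarityMatrix", function(object) {
    cat(sprintf("DissimilarityMatrix: %d proteins, %d trees used, %.1f%% undefined\n",
                nrow(object@d), object@nTreesUsed,
                100 * mean(is.na(object@d[upper.tri(object@d)]))))
})

#' @export
#' @method as.matrix DissimilarityMatrix
as.matrix.DissimilarityMatrix <- function(x, ...) x@d

#' @export
#' @method as.matrix CorrelationMatrix
as.matrix.CorrelationMatrix <- function(x, ...) x@rho

setMethod("show", "CorrelationMatrix", function(object) {
    cat(sprintf("CorrelationMatrix: %d proteins (min overlap %d)\n",
                nrow(object@rho), object@minOverlap))
})

#' @rdname CoregulationNetwork-class
#' @param x a CoregulationNetwork.
#' @export
setMethod("edges", "CoregulationNetwork", function(x) x@edges)

setMethod("show", "CoregulationNetwork", function(object) {
    cat(sprintf("CoregulationNetwork: %d nodes, %d edges (top %.2f%% of pairs)\n",
                length(object@nodes), nrow(object@edges),
                100 * object@selectionFraction))
})

#' @rdname ProgulonScores-class
#' @param x a ProgulonScores object.
#' @export
setMethod("scoreTable", "ProgulonScores", function(x) x@table)

setMethod("show", "ProgulonScores", function(object) {
    tab <- object@table
    cat(sprintf("ProgulonScores: %d proteins (%d training), %d balanced models\n",
                nrow(tab), sum(tab$isTraining), object@nModels))
})

setMethod("show", "QcReport", function(object) {
    cat(sprintf("QcReport: AUC = %.4f, top-10 training count = %d -> %s\n",
                object@auc, object@top10TrainingCount,
                if (object@pass) "PASS" else "FAIL"))
})

setMethod("show", "Progulon", function(object) {
    cat(sprintf("Progulon '%s': %d members at cutoff %.2f (connectivity P = %.3g)\n",
                object@name, length(object@members), object@cutoff,
                object@connectivityP))
})

setMethod("show", "PairedOmics", function(object) {
    cat(sprintf("PairedOmics: %d genes x %d samples\n",
                nrow(object@mrna), ncol(object@mrna)))
})

setMethod("show", "ScreenDataset", function(object) {
    w <- object@wells
    cat(sprintf("ScreenDataset: %d wells, %d genes, %d readouts, %d plates\n",
                nrow(w), length(unique(w$gene[!w$isNegativeControl])),
                length(unique(w$readout)), length(unique(w$plate))))
})

#' @rdname PairedOmics-class
#' @param mrna,protein gene x sample matrices with identical dimnames.
#' @export
PairedOmics <- function(mrna, protein) {
    obj <- new("PairedOmics", mrna = as.matrix(mrna),
               protein = as.matrix(protein))
    validObject(obj)
    obj
}
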