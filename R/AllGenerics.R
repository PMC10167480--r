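#' @rdname RatioMatrix
#' @export
setGeneric("ratios", function(x) standardGeneric("ratios"))

#' @rdname RatioMatrix
#' @export
setGeneric("featureCounts", function(x) standardGeneric("featureCounts"))

#' @rdname RatioMatrix
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname RatioMatrix
#' @export
setGeneric("experimentIds", function(x) standardGeneric("experimentIds"))

#' @rdname SeedGroup
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname ProgulonScores-class
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname CoregulationNetwork-class
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))
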