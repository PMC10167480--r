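#' Read a protein x experiment ratio matrix from TSV/CSV
#'
#' The first column holds protein IDs, the header row experiment IDs.
#' Empty cells and "NA" are read as missing. Duplicated protein or
#' experiment IDs are rejected.
#'
#' @param path file path.
#' @param dialect "tsv" or "csv".
#' @return a [RatioMatrix-class].
#' @export
readRatioMatrix <- function(path, dialect = c("tsv", "csv")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- if (dialect == "tsv") "\t" else ","
    dt <- data.table::fread(path, sep = sep, header = TRUE,
                            na.strings = c("", "NA"), data.table = FALSE,
                            colClasses = list(character = 1))
    if (ncol(dt) < 2L) stop("malformed header: need an ID column plus >= 1 experiment")
    ids <- dt[[1L]]
    if (anyNA(ids) || any(ids == "")) stop("malformed header or missing protein IDs")
    dup <- unique(ids[duplicated(ids)])
    if (length(dup)) stop("duplicated protein ID(s): ", paste(dup, collapse = ", "))
    mat <- as.matrix(dt[, -1L, drop = FALSE])
    if (!is.numeric(mat)) stop("non-numeric ratio values")
    rownames(mat) <- ids
    RatioMatrix(mat)
}

#' Write a ratio matrix to TSV/CSV
#'
#' Missing values are written as empty cells, so that read/write round-trips
#' preserve values, the missingness mask and ID order exactly.
#'
#' @param x a [RatioMatrix-class].
#' @param path destination file.
#' @param dialect "tsv" or "csv".
#' @export
writeRatioMatrix <- function(x, path, dialect = c("tsv", "csv")) {
    dialect <- match.arg(dialect)
    sep <- if (dialect == "tsv") "\t" else ","
    v <- ratios(x)
    df <- data.frame(Protein = rownames(v), v, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, na = "",
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Proteins with enough quantified experiments
#'
#' Training proteins require 45 quantified experiments by default and test
#' proteins 30; for small experiment subsets (e.g. a 15-experiment
#' nascent-chromatin panel) these drop to 7 and 5. Eligibility is always
#' evaluated on the matrix actually passed, so column-subset runs re-derive
#' feature counts.
#'
#' @param x a [RatioMatrix-class].
#' @param minFeatures minimum non-missing values per protein (>= 1).
#' @return character vector of eligible protein IDs.
#' @export
eligibleProteins <- function(x, minFeatures) {
    stopifnot(is(x, "RatioMatrix"), minFeatures >= 1)
    fc <- featureCounts(x)
    names(fc)[fc >= minFeatures]
}

#' Map user-supplied protein IDs onto the matrix
#'
#' Matching proceeds in a fixed order: exact match, then synonym table, then
#' case-insensitive match. Unmatched IDs are reported, never silently
#' dropped. Fewer than four matches is an error (seed groups need at least
#' four members).
#'
#' @param userIds character vector of IDs as supplied by the user.
#' @param x a [RatioMatrix-class].
#' @param synonyms optional named character vector mapping synonym ->
#'   matrix protein ID.
#' @param name label for the resulting seed group.
#' @return list with elements \code{seed} (a [SeedGroup-class]) and
#'   \code{unmatched} (character).
#' @export
mapSeedIds <- function(userIds, x, synonyms = NULL, name = "user_seed") {
    stopifnot(length(userIds) > 0)
    userIds <- as.character(userIds)
    ids <- proteinIds(x)
    lowmap <- ids
    names(lowmap) <- tolower(ids)
    matched <- character(length(userIds))
    for (i in seq_along(userIds)) {
        u <- userIds[i]
        if (u %in% ids) {
            matched[i] <- u
        } else if (!is.null(synonyms) && u %in% names(synonyms) &&
                   synonyms[[u]] %in% ids) {
            matched[i] <- synonyms[[u]]
        } else if (tolower(u) %in% names(lowmap)) {
            matched[i] <- lowmap[[tolower(u)]]
        } else {
            matched[i] <- NA_character_
        }
    }
    unmatched <- userIds[is.na(matched)]
    got <- unique(matched[!is.na(matched)])
    if (length(got) < 4L)
        stop(sprintf("seed too small: only %d of %d IDs matched (unmatched: %s)",
                     length(got), length(userIds),
                     paste(unmatched, collapse = ", ")))
    list(seed = SeedGroup(name, got, "user"), unmatched = unmatched)
}

#' Read a plain-text seed list (one protein ID per line)
#'
#' Blank lines and lines starting with '#' are skipped.
#' @param path file path.
#' @return character vector of IDs.
#' @export
readSeedList <- function(path) {
    x <- trimws(readLines(path, warn = FALSE))
    x[nzchar(x) & !startsWith(x, "#")]
}

#' Read annotation sets in GMT format
#'
#' GMT is tab-separated: set name, description, then member IDs. The
#' annotation universe is restricted to \code{universe} when given; IDs
#' outside it are kept in an \code{unmapped} attribute per set.
#'
#' @param path GMT file.
#' @param universe optional character vector restricting set members.
#' @return named list of character vectors; attribute \code{unmapped} holds
#'   per-set IDs outside the universe.
#' @export
readGmt <- function(path, universe = NULL) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
    names(sets) <- vapply(parts, `[[`, character(1), 1L)
    unmapped <- lapply(sets, function(s) character(0))
    if (!is.null(universe)) {
        unmapped <- lapply(sets, setdiff, y = universe)
        sets <- lapply(sets, intersect, y = universe)
    }
    attr(sets, "unmapped") <- unmapped
    sets
}

#' Write protein sets as GMT / GMX
#'
#' @param sets named list of character vectors.
#' @param path destination file.
#' @param descriptions optional character vector of set descriptions
#'   (defaults to the set names).
#' @param format "gmt" (one set per row) or "gmx" (one set per column).
#' @export
writeGmt <- function(sets, path, descriptions = NULL,
                     format = c("gmt", "gmx")) {
    format <- match.arg(format)
    if (is.null(descriptions)) descriptions <- names(sets)
    if (format == "gmt") {
        lines <- mapply(function(nm, desc, s)
            paste(c(nm, desc, s), collapse = "\t"),
            names(sets), descriptions, sets)
        writeLines(lines, path, useBytes = TRUE)
    } else {
        n <- max(lengths(sets))
        cols <- mapply(function(nm, desc, s)
            c(nm, desc, s, rep("", n - length(s))),
            names(sets), descriptions, sets, SIMPLIFY = FALSE)
        tab <- do.call(cbind, cols)
        utils::write.table(tab, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE,
                           fileEncoding = "UTF-8")
    }
    invisible(path)
}
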