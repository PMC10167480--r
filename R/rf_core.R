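#' Assemble the training configuration for a progulon search
#'
#' Positives are the seed members that survive the training feature filter
#' (at least \code{minTrainFeatures} quantified experiments). Negatives are
#' \code{nNegatives} proteins drawn uniformly without replacement from the
#' eligible non-seed proteins; if the pool is smaller, all of it is used
#' with a warning. The draw is reproducible from \code{rngSeed}.
#'
#' @param seed a [SeedGroup-class] (or character vector of protein IDs).
#' @param x a [RatioMatrix-class].
#' @param nNegatives size of the negative training pool (default 1000).
#' @param nTrees trees per balanced model (default 500).
#' @param minTrainFeatures,minTestFeatures feature minima (45 / 30 default;
#'   use 7 / 5 for small experiment subsets).
#' @param rngSeed integer seed.
#' @return a [TrainingConfig-class].
#' @export
assembleTraining <- function(seed, x, nNegatives = 1000L, nTrees = 500L,
                             minTrainFeatures = 45L, minTestFeatures = 30L,
                             rngSeed = 1L) {
    ids <- if (is(seed, "SeedGroup")) members(seed) else as.character(seed)
    stopifnot(is(x, "RatioMatrix"))
    missing <- setdiff(ids, proteinIds(x))
    if (length(missing))
        stop("seed proteins absent from the matrix: ",
             paste(missing, collapse = ", "))
    eligTrain <- eligibleProteins(x, minTrainFeatures)
    pos <- intersect(ids, eligTrain)
    if (length(pos) < 4L) {
        dropped <- setdiff(ids, pos)
        stop(sprintf(
            "seed ineligible: only %d members have >= %d features (dropped: %s)",
            length(pos), minTrainFeatures, paste(dropped, collapse = ", ")))
    }
    pool <- setdiff(eligibleProteins(x, minTrainFeatures), ids)
    nDraw <- min(nNegatives, length(pool))
    if (nDraw < nNegatives)
        warning(sprintf("negative pool limited to %d eligible proteins", nDraw))
    set.seed(rngSeed)
    negs <- sort(sample(pool, nDraw))
    new("TrainingConfig", positives = pos, negatives = negs,
        nTrees = as.integer(nTrees),
        minTrainFeatures = as.integer(minTrainFeatures),
        minTestFeatures = as.integer(minTestFeatures),
        rngSeed = as.integer(rngSeed))
}

# number of balanced models: enough that the negative pool is cycled ~once
nBalancedModels <- function(nPool, nPos) as.integer(ceiling(nPool / nPos))

# negatives for model m: the pool is shuffled and consumed in chunks of
# nPos without replacement; when exhausted it is reshuffled. Deterministic
# in the supplied RNG state.
negativeChunks <- function(negatives, nPos, nModels) {
    chunks <- vector("list", nModels)
    pool <- sample(negatives)
    for (m in seq_len(nModels)) {
        if (length(pool) < nPos) pool <- sample(negatives)
        chunks[[m]] <- pool[seq_len(nPos)]
        pool <- pool[-seq_len(nPos)]
    }
    chunks
}

# median-impute a feature matrix using medians of the given training rows;
# returns list(train, all) of fully observed matrices
imputeByTrainingMedian <- function(v, trainIds) {
    med <- apply(v[trainIds, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
    med[is.na(med)] <- 0
    for (k in seq_len(ncol(v))) {
        nas <- is.na(v[, k])
        if (any(nas)) v[nas, k] <- med[k]
    }
    v
}

#' Score all eligible proteins with a balanced Random-Forest ensemble
#'
#' Fits M = ceiling(pool size / number of positives) balanced models; each
#' model trains a forest of \code{nTrees} unlimited-depth trees on all
#' positives plus an equally sized negative draw (the pool is cycled
#' without replacement across models and reshuffled when exhausted). A
#' protein's RF score is the fraction of trees voting it into the positive
#' class, averaged over models. Only proteins with at least
#' \code{minTestFeatures} quantified experiments are scored; the rest are
#' excluded with their reason recorded (attribute \code{"excluded"}), not
#' scored as 0. Missing values are median-imputed per feature from each
#' model's training rows, with the imputation frozen for scoring.
#'
#' @param x a [RatioMatrix-class].
#' @param cfg a [TrainingConfig-class].
#' @param loo when TRUE, also computes leave-one-out scores (see
#'   [looCrossValidate()]).
#' @return a [ProgulonScores-class].
#' @export
ensembleScores <- function(x, cfg, loo = FALSE) {
    stopifnot(is(x, "RatioMatrix"), is(cfg, "TrainingConfig"))
    validObject(cfg)
    v <- ratios(x)
    testable <- eligibleProteins(x, cfg@minTestFeatures)
    excluded <- setdiff(proteinIds(x), testable)
    scoreIds <- union(testable, cfg@positives)
    vSub <- v[scoreIds, , drop = FALSE]
    nPos <- length(cfg@positives)
    nModels <- nBalancedModels(length(cfg@negatives), nPos)
    set.seed(cfg@rngSeed + 1L)
    chunks <- negativeChunks(cfg@negatives, nPos, nModels)
    rf <- matrix(0, nrow = length(scoreIds), ncol = nModels,
                 dimnames = list(scoreIds, NULL))
    for (m in seq_len(nModels)) {
        rf[, m] <- fitBalancedModel(vSub, cfg@positives, chunks[[m]],
                                    cfg@nTrees, cfg@rngSeed + 1000L + m)
    }
    tab <- data.frame(
        protein = scoreIds,
        rfScore = rowMeans(rf),
        isTraining = scoreIds %in% cfg@positives,
        looScore = NA_real_,
        featureCount = featureCounts(x)[scoreIds],
        row.names = NULL, stringsAsFactors = FALSE)
    res <- new("ProgulonScores", table = tab, nModels = nModels)
    attr(res@table, "excluded") <- excluded
    if (loo) res <- looCrossValidate(x, cfg, res)
    res
}

# one balanced model: forest on positives + one negative chunk, scores for
# all rows of vSub
fitBalancedModel <- function(vSub, positives, negChunk, nTrees, seed) {
    trainIds <- c(positives, negChunk)
    vImp <- imputeByTrainingMedian(vSub, trainIds)
    y <- factor(c(rep("pos", length(positives)), rep("neg", length(negChunk))),
                levels = c("neg", "pos"))
    set.seed(seed)
    fit <- randomForest::randomForest(
        x = vImp[trainIds, , drop = FALSE], y = y,
        ntree = nTrees, nodesize = 1L)
    stats::predict(fit, vImp, type = "prob")[, "pos"]
}

#' Leave-one-out cross-validation of the seed proteins
#'
#' For each positive q the full balanced ensemble (same number of models,
#' same negative pool, same RNG stream per fold) is retrained with q
#' removed from the positive class; q's LOO score is that ensemble's score
#' for q. Non-positives keep their [ensembleScores()] values.
#'
#' @param x a [RatioMatrix-class].
#' @param cfg a [TrainingConfig-class].
#' @param scores a [ProgulonScores-class] from [ensembleScores()].
#' @return the scores object with \code{looScore} filled for positives.
#' @export
looCrossValidate <- function(x, cfg, scores) {
    stopifnot(length(cfg@positives) >= 4L)
    v <- ratios(x)
    nPos <- length(cfg@positives)
    nModels <- nBalancedModels(length(cfg@negatives), nPos)
    tab <- scoreTable(scores)
    for (q in cfg@positives) {
        posQ <- setdiff(cfg@positives, q)
        vSub <- v[c(posQ, cfg@negatives, q), , drop = FALSE]
        set.seed(cfg@rngSeed + 1L)
        chunks <- negativeChunks(cfg@negatives, length(posQ), nModels)
        sc <- numeric(nModels)
        for (m in seq_len(nModels)) {
            trainIds <- c(posQ, chunks[[m]])
            vImp <- imputeByTrainingMedian(vSub[c(trainIds, q), , drop = FALSE],
                                           trainIds)
            y <- factor(c(rep("pos", length(posQ)),
                          rep("neg", length(chunks[[m]]))),
                        levels = c("neg", "pos"))
            set.seed(cfg@rngSeed + 1000L + m)
            fit <- randomForest::randomForest(
                x = vImp[trainIds, , drop = FALSE], y = y,
                ntree = cfg@nTrees, nodesize = 1L)
            sc[m] <- stats::predict(fit, vImp[q, , drop = FALSE],
                                    type = "prob")[, "pos"]
        }
        tab$looScore[tab$protein == q] <- mean(sc)
    }
    new("ProgulonScores", table = tab, nModels = scores@nModels)
}

#' Quality-control check of a progulon model
#'
#' The ROC AUC is computed with the LOO scores of the training positives
#' against the ensemble scores of the negative training pool. The model
#' also has to place at least four cross-validated training proteins among
#' the ten highest-scoring proteins overall (positives represented by their
#' LOO score). Pass requires AUC >= 0.99 and top-10 count >= 4.
#'
#' @param scores a [ProgulonScores-class] with LOO scores present.
#' @param negatives character vector, the negative training pool.
#' @return a [QcReport-class].
#' @export
qcCheck <- function(scores, negatives) {
    tab <- scoreTable(scores)
    posLoo <- tab$looScore[tab$isTraining]
    if (anyNA(posLoo)) stop("LOO scores missing; run looCrossValidate() first")
    negScores <- tab$rfScore[tab$protein %in% negatives]
    auc <- as.numeric(pROC::auc(
        response = c(rep(1L, length(posLoo)), rep(0L, length(negScores))),
        predictor = c(posLoo, negScores),
        direction = "<", quiet = TRUE))
    eff <- ifelse(tab$isTraining, tab$looScore, tab$rfScore)
    topIdx <- order(-eff, tab$protein)[seq_len(min(10L, nrow(tab)))]
    topCount <- sum(tab$isTraining[topIdx])
    new("QcReport", auc = auc, top10TrainingCount = as.integer(topCount),
        pass = (auc >= 0.99) && (topCount >= 4L))
}
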