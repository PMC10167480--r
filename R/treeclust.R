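#' Fit per-experiment surrogate regression trees
#'
#' For every experiment column j, a regression tree predicting column j from
#' all other columns is fitted (rpart) on the proteins quantified in j,
#' grown with at least \code{minBucket} proteins per leaf and pruned by
#' cost-complexity with the 1-SE rule on the internal cross-validation.
#' Trees pruned back to the root carry no co-regulation signal and are
#' discarded. Missing predictor values are median-imputed from the tree's
#' training rows, both for fitting and for routing all proteins to leaves;
#' the per-tree imputation medians are frozen so routing is deterministic.
#'
#' A protein is unassignable in a tree when none of the tree's split
#' variables are observed for it (its leaf would be pure imputation);
#' such (protein, tree) entries are \code{NA}.
#'
#' @param x a [RatioMatrix-class] with >= 2 experiments.
#' @param minBucket minimum proteins per leaf (default 5).
#' @param cp complexity parameter used to grow trees before pruning.
#' @param minFitRows minimum observed proteins needed to fit a column's tree.
#' @param seed integer; makes the internal cross-validation reproducible.
#' @return a "surrogateForest" list: \code{leaves} (protein x tree integer
#'   matrix of leaf node numbers, NA = unassignable), \code{quality}
#'   (per-tree proportion of deviance explained), \code{columns} (the
#'   experiment each tree predicts), \code{trees} (the pruned rpart fits).
#' @export
fitSurrogateTrees <- function(x, minBucket = 5L, cp = 0.001,
                              minFitRows = max(2L * minBucket, 10L),
                              seed = 1L) {
    stopifnot(is(x, "RatioMatrix"))
    v <- ratios(x)
    if (ncol(v) < 2L) stop("need >= 2 experiments to fit surrogate trees")
    cols <- colnames(v)
    leaves <- list(); quality <- numeric(); kept <- character()
    trees <- list()
    for (j in seq_along(cols)) {
        yobs <- !is.na(v[, j])
        if (sum(yobs) < minFitRows) next
        pred <- v[, -j, drop = FALSE]
        med <- apply(pred[yobs, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
        med[is.na(med)] <- 0
        predImp <- pred
        for (k in seq_len(ncol(predImp))) {
            nas <- is.na(predImp[, k])
            if (any(nas)) predImp[nas, k] <- med[k]
        }
        # canonical row order, so cross-validation folds (and hence 1-SE
        # pruning) do not depend on the order proteins arrive in
        fitRows <- rownames(v)[yobs][order(rownames(v)[yobs])]
        df <- data.frame(.y = v[fitRows, j], predImp[fitRows, , drop = FALSE],
                         check.names = FALSE)
        set.seed(seed + j)
        fit <- rpart::rpart(.y ~ ., data = df, method = "anova",
                            control = rpart::rpart.control(
                                minbucket = minBucket, cp = cp, xval = 10L))
        fit <- pruneOneSe(fit)
        if (is.null(fit) || nrow(fit$frame) <= 1L) next
        usedVars <- setdiff(unique(as.character(fit$frame$var)), "<leaf>")
        assignable <- rowSums(!is.na(pred[, usedVars, drop = FALSE])) > 0L
        newdf <- as.data.frame(predImp)
        lf <- routeToLeaves(fit, newdf)
        lf[!assignable] <- NA_integer_
        kept <- c(kept, cols[j])
        leaves[[length(leaves) + 1L]] <- lf
        # proportion of root deviance removed by the pruned tree
        dev <- fit$frame$dev
        quality <- c(quality, 1 - sum(dev[fit$frame$var == "<leaf>"]) / dev[1L])
        trees[[length(trees) + 1L]] <- fit
    }
    if (!length(leaves))
        stop("no informative trees: every surrogate tree was pruned to the root")
    lm <- do.call(cbind, leaves)
    dimnames(lm) <- list(rownames(v), kept)
    structure(list(leaves = lm, quality = quality, columns = kept,
                   trees = trees),
              class = "surrogateForest")
}

# 1-SE cost-complexity pruning on rpart's cptable; NULL if no split survives
pruneOneSe <- function(fit) {
    cptab <- fit$cptable
    if (is.null(cptab) || nrow(cptab) < 1L) return(NULL)
    if (!"xerror" %in% colnames(cptab)) return(fit)
    best <- which.min(cptab[, "xerror"])
    thr <- cptab[best, "xerror"] + cptab[best, "xstd"]
    pick <- which(cptab[, "xerror"] <= thr)[1L]
    if (cptab[pick, "nsplit"] == 0L) return(NULL)
    rpart::prune(fit, cp = cptab[pick, "CP"] * 1.0000001)
}

# Route rows of a (fully imputed) data.frame down an rpart tree; returns the
# terminal node number per row. Handles continuous splits only, which is all
# this package fits.
routeToLeaves <- function(fit, newdata) {
    frame <- fit$frame
    nodeNums <- as.integer(rownames(frame))
    isLeaf <- frame$var == "<leaf>"
    splitRow <- integer(nrow(frame))
    idx <- 1L
    for (i in seq_len(nrow(frame))) {
        if (!isLeaf[i]) {
            splitRow[i] <- idx
            idx <- idx + 1L + frame$ncompete[i] + frame$nsurrogate[i]
        }
    }
    out <- integer(nrow(newdata))
    todo <- list(list(node = 1L, rows = seq_len(nrow(newdata))))
    while (length(todo)) {
        cur <- todo[[length(todo)]]
        todo[[length(todo)]] <- NULL
        fi <- match(cur$node, nodeNums)
        if (isLeaf[fi]) {
            out[cur$rows] <- cur$node
            next
        }
        sr <- splitRow[fi]
        var <- rownames(fit$splits)[sr]
        cutp <- fit$splits[sr, "index"]
        ncat <- fit$splits[sr, "ncat"]
        vals <- newdata[cur$rows, var]
        goLeft <- if (ncat < 0) vals < cutp else vals >= cutp
        if (any(goLeft))
            todo[[length(todo) + 1L]] <- list(node = 2L * cur$node,
                                              rows = cur$rows[goLeft])
        if (any(!goLeft))
            todo[[length(todo) + 1L]] <- list(node = 2L * cur$node + 1L,
                                              rows = cur$rows[!goLeft])
    }
    out
}

#' Tree-based (leaf-disagreement) dissimilarity
#'
#' The default dissimilarity between proteins i and k is the fraction of
#' retained surrogate trees in which they fall into different leaves,
#' computed over the trees where both are assignable. With
#' \code{weighting = "deviance"} each tree is weighted by the proportion of
#' deviance it explains. Pairs with no usable tree are \code{NA}, never 0.
#'
#' @param forest a "surrogateForest" from [fitSurrogateTrees()].
#' @param proteins optional subset of protein IDs.
#' @param weighting "none" (default) or "deviance".
#' @return a [DissimilarityMatrix-class].
#' @export
treeClustDissimilarity <- function(forest, proteins = NULL,
                                   weighting = c("none", "deviance")) {
    weighting <- match.arg(weighting)
    stopifnot(inherits(forest, "surrogateForest"))
    L <- forest$leaves
    if (!is.null(proteins)) L <- L[proteins, , drop = FALSE]
    n <- nrow(L); Tn <- ncol(L)
    w <- if (weighting == "deviance") forest$quality else rep(1, Tn)
    # accumulate per-pair agreement weight and usable weight tree by tree
    agree <- matrix(0, n, n)
    usable <- matrix(0, n, n)
    for (t in seq_len(Tn)) {
        lt <- L[, t]
        ok <- !is.na(lt)
        if (!any(ok)) next
        okIdx <- which(ok)
        sameLeaf <- outer(lt[okIdx], lt[okIdx], "==")
        agree[okIdx, okIdx] <- agree[okIdx, okIdx] + w[t] * sameLeaf
        usable[okIdx, okIdx] <- usable[okIdx, okIdx] + w[t]
    }
    d <- 1 - agree / usable
    d[usable == 0] <- NA_real_
    diag(d)[!is.na(diag(d))] <- 0
    dimnames(d) <- list(rownames(L), rownames(L))
    new("DissimilarityMatrix", d = d, nTreesUsed = as.integer(Tn))
}
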