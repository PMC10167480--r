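# helper: scores object with chosen effective scores
mkScoreObj <- function(ids, score, training = rep(FALSE, length(ids))) {
    tab <- data.frame(protein = ids, rfScore = score, isTraining = training,
                      looScore = ifelse(training, score, NA_real_),
                      featureCount = 50L)
    new("ProgulonScores", table = tab, nModels = 5L)
}

mkNet <- function(nodes, edgePairs, w = 1) {
    new("CoregulationNetwork", nodes = nodes,
        edges = data.frame(idA = edgePairs[, 1], idB = edgePairs[, 2],
                           weight = w),
        selectionFraction = 0.005)
}

test_that("connectivity P-value equals the hypergeometric enumeration oracle", {
    set.seed(23)
    for (rep in 1:25) {
        universe <- sprintf("u%02d", 1:12)
        memberIds <- sample(universe, 4)
        nEdges <- sample(3:12, 1)
        pairs <- t(combn(universe, 2))
        pick <- sample(nrow(pairs), nEdges)
        net <- mkNet(universe, pairs[pick, , drop = FALSE])
        p <- connectivityPvalue(memberIds, net, universe)
        # oracle: build the pair table independently and enumerate the tail
        isInt <- apply(pairs, 1, function(pr) all(pr %in% memberIds))
        isEdge <- seq_len(nrow(pairs)) %in% pick
        a <- sum(isInt & isEdge); b <- sum(isInt & !isEdge)
        c_ <- sum(!isInt & isEdge); d <- sum(!isInt & !isEdge)
        expect_equal(p, fisherGreaterOracle(a, b, c_, d), tolerance = 1e-10)
    }
    # extreme enrichment: all internal pairs are edges of a sparse network
    universe <- sprintf("u%03d", 1:200)
    memberIds <- universe[1:10]
    intPairs <- t(combn(memberIds, 2))
    net <- mkNet(universe, intPairs)
    expect_lt(connectivityPvalue(memberIds, net, universe), 0.05)
    # zero overlap: P = 1 under one-sided enrichment
    netOut <- mkNet(universe, cbind(universe[11:20], universe[21:30]))
    expect_equal(connectivityPvalue(memberIds, netOut, universe), 1)
})

test_that("cutoff selection walks the 51-point grid to the first significant point", {
    # 30 members above 0.5 whose pairs are all edges -> significant at 0.50
    ids <- sprintf("m%03d", 1:120)
    score <- c(runif(30, 0.55, 0.95), runif(90, 0, 0.45))
    set.seed(3)
    sc <- mkScoreObj(ids, score)
    net <- mkNet(ids, t(combn(ids[1:30], 2)))
    sel <- selectCutoff(sc, net)
    expect_false(sel$discard)
    expect_equal(sel$cutoff, 0.50)
    expect_lt(sel$connectivityP, 0.05)

    # the full grid is {0.50, ..., 1.00}: 51 points, evaluated in order
    selAll <- selectCutoff(sc, mkNet(ids, cbind(ids[31:60], ids[61:90])))
    expect_true(selAll$discard)
    expect_equal(selAll$grid$cutoff, round(seq(0.50, 1.00, by = 0.01), 2))
    expect_equal(nrow(selAll$grid), 51L)

    # connectivity appears only above 0.53: members in (0.5, 0.53) are
    # hangers-on that dilute the module below significance, against a
    # background network dense enough to make the diluted module
    # unremarkable (the 20 top scorers share 30 edges, ~15% density,
    # against a ~6% global density)
    set.seed(7)
    idsB <- sprintf("b%03d", 1:400)
    scoreB <- c(runif(20, 0.95, 1), runif(90, 0.521, 0.525),
                runif(290, 0, 0.45))
    scB <- mkScoreObj(idsB, scoreB)
    allPairs <- t(combn(idsB, 2))
    intClique <- which(apply(allPairs, 1,
                             function(pr) all(pr %in% idsB[1:20])))
    netB <- mkNet(idsB, allPairs[c(sample(intClique, 30),
                                   sample(setdiff(seq_len(nrow(allPairs)),
                                                  intClique), 5000)), ])
    selB <- selectCutoff(scB, netB)
    expect_false(selB$discard)
    expect_equal(selB$cutoff, 0.53)
    # minimality: every evaluated grid point below the cutoff was not
    # significant
    expect_true(all(selB$grid$p[selB$grid$cutoff < selB$cutoff] >= 0.05,
                    na.rm = TRUE))

    # monotone in alpha: smaller alpha never yields a smaller cutoff
    for (alphas in list(c(0.05, 0.01), c(0.2, 0.05))) {
        c1 <- selectCutoff(scB, netB, alpha = alphas[1])$cutoff
        c2 <- selectCutoff(scB, netB, alpha = alphas[2])$cutoff
        expect_true(is.na(c2) || c2 >= c1)
    }
})

test_that("membership is monotone in the cutoff and finalize enforces its gates", {
    ids <- sprintf("m%03d", 1:50)
    set.seed(5)
    sc <- mkScoreObj(ids, runif(50), training = c(rep(TRUE, 6), rep(FALSE, 44)))
    eff <- progulons:::effectiveScores(sc)
    prev <- Inf
    for (cut in seq(0.5, 1, by = 0.1)) {
        n <- sum(eff >= cut)
        expect_lte(n, prev)
        prev <- n
    }
    qcPass <- new("QcReport", auc = 1, top10TrainingCount = 6L, pass = TRUE)
    qcFail <- new("QcReport", auc = 0.9, top10TrainingCount = 6L, pass = FALSE)
    pg <- finalizeProgulon("mod", sc, 0.6, 0.001, qcPass)
    expect_s4_class(pg, "Progulon")
    expect_equal(length(pg@members), sum(eff >= 0.6))
    expect_error(finalizeProgulon("mod", sc, 0.6, 0.001, qcFail), "QC")
    expect_error(finalizeProgulon("mod", sc, 0.4, 0.001, qcPass), "cutoff")
})

test_that("exact t-SNE separates planted sub-blocks and is deterministic", {
    m <- twoBlockMatrix(10, 8, seed = 31)
    d <- as.matrix(dist(m)) / max(dist(m))
    ts1 <- embedTsne(d, perplexity = 5, rngSeed = 4)
    ts2 <- embedTsne(d, perplexity = 5, rngSeed = 4)
    expect_identical(ts1, ts2)
    Y <- as.matrix(ts1[, c("x", "y")])
    dd <- as.matrix(dist(Y))
    intra <- mean(c(dd[1:10, 1:10][upper.tri(dd[1:10, 1:10])],
                    dd[11:20, 11:20][upper.tri(dd[11:20, 11:20])]))
    inter <- mean(dd[1:10, 11:20])
    expect_gt(inter, intra)
    # degenerate input: too few points refuse, small counts shrink perplexity
    expect_error(embedTsne(d[1:4, 1:4]), ">= 5")
    expect_warning(embedTsne(d[1:6, 1:6], perplexity = 30, rngSeed = 1),
                   "perplexity")
})
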