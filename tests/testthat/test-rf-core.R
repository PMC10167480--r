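# shared small-but-structured fixture: one planted module with a tight core
rfFixture <- function(seed = 11) {
    sim <- simulateProteomeHd(150, 40,
                              modules = list(moduleSpec(20, coreSize = 8)),
                              backgroundDetection = 0.9, rngSeed = seed)
    mem <- names(sim$truth$membership)[!is.na(sim$truth$membership)]
    list(x = sim$matrix, members = mem,
         core = names(sim$truth$core)[sim$truth$core])
}

test_that("training assembly draws negatives reproducibly and enforces eligibility", {
    fx <- rfFixture()
    cfg <- assembleTraining(fx$core, fx$x, nNegatives = 100, nTrees = 50,
                            minTrainFeatures = 20, minTestFeatures = 15,
                            rngSeed = 5)
    expect_length(cfg@positives, 8)
    expect_length(cfg@negatives, 100)
    expect_length(intersect(cfg@positives, cfg@negatives), 0)
    # same seed -> identical draw
    cfg2 <- assembleTraining(fx$core, fx$x, nNegatives = 100, nTrees = 50,
                             minTrainFeatures = 20, minTestFeatures = 15,
                             rngSeed = 5)
    expect_identical(cfg@negatives, cfg2@negatives)
    # pool-limited case: all eligible non-seed proteins, with a warning
    expect_warning(
        cfgL <- assembleTraining(fx$core, fx$x, nNegatives = 1000,
                                 minTrainFeatures = 20, minTestFeatures = 15,
                                 rngSeed = 5),
        "pool limited")
    expect_length(cfgL@negatives, 142)
    # a seed whose members lack features is rejected with the members named
    expect_error(assembleTraining(fx$core, fx$x, minTrainFeatures = 41L),
                 "seed ineligible")
})

test_that("balanced model count follows the ceiling rule", {
    expect_equal(progulons:::nBalancedModels(1000, 10), 100L)
    expect_equal(progulons:::nBalancedModels(1000, 7), 143L)
    expect_equal(progulons:::nBalancedModels(520, 10), 52L)
    # negative cycling covers the pool without replacement per cycle
    set.seed(1)
    chunks <- progulons:::negativeChunks(paste0("n", 1:20), 5, 4)
    expect_setequal(unlist(chunks), paste0("n", 1:20))
    expect_true(all(lengths(chunks) == 5))
})

test_that("ensemble scores separate module members from background", {
    fx <- rfFixture()
    cfg <- assembleTraining(fx$core, fx$x, nNegatives = 100, nTrees = 100,
                            minTrainFeatures = 20, minTestFeatures = 15,
                            rngSeed = 7)
    sc <- ensembleScores(fx$x, cfg)
    tab <- scoreTable(sc)
    expect_equal(sc@nModels, 13L)   # ceiling(100 / 8)
    expect_true(all(tab$rfScore >= 0 & tab$rfScore <= 1))
    held <- setdiff(fx$members, fx$core)
    bg <- setdiff(tab$protein, fx$members)
    expect_gt(min(tab$rfScore[tab$protein %in% held]),
              median(tab$rfScore[tab$protein %in% bg]))
    # a protein duplicating a core member's profile scores like the module
    expect_gt(median(tab$rfScore[tab$protein %in% held]), 0.5)
    # reproducible under the same seed
    sc2 <- ensembleScores(fx$x, cfg)
    expect_identical(scoreTable(sc2)$rfScore, tab$rfScore)
    # proteins under the test-feature minimum are excluded with a reason,
    # not scored as zero
    m <- ratios(fx$x)
    m["P0140", 16:40] <- NA
    x2 <- RatioMatrix(m)
    cfg2 <- assembleTraining(fx$core, x2, nNegatives = 100, nTrees = 50,
                             minTrainFeatures = 20, minTestFeatures = 15,
                             rngSeed = 7)
    sc3 <- ensembleScores(x2, cfg2)
    expect_false("P0140" %in% scoreTable(sc3)$protein)
    expect_true("P0140" %in% attr(scoreTable(sc3), "excluded"))
})

test_that("leave-one-out retrains once per positive and flags outliers", {
    fx <- rfFixture(13)
    # implant an outlier: replace one core member's profile with noise
    m <- ratios(fx$x)
    out <- fx$core[1]
    set.seed(99)
    m[out, ] <- rnorm(ncol(m))
    x <- RatioMatrix(m)
    cfg <- assembleTraining(fx$core, x, nNegatives = 80, nTrees = 100,
                            minTrainFeatures = 20, minTestFeatures = 15,
                            rngSeed = 3)
    sc <- ensembleScores(x, cfg, loo = TRUE)
    tab <- scoreTable(sc)
    loo <- tab$looScore[tab$isTraining]
    expect_true(all(!is.na(loo)))
    names(loo) <- tab$protein[tab$isTraining]
    # the implanted outlier scores below every genuine core member
    expect_lt(loo[out], min(loo[names(loo) != out]))
    # separable case: genuine members' LOO scores beat the negative pool
    negScores <- tab$rfScore[tab$protein %in% cfg@negatives]
    expect_gt(min(loo[names(loo) != out]), quantile(negScores, 0.95))
})

test_that("QC AUC equals the pairwise-concordance oracle and gates correctly", {
    mkScores <- function(loo, neg, other = numeric(0)) {
        tab <- data.frame(
            protein = c(sprintf("pos%02d", seq_along(loo)),
                        sprintf("neg%03d", seq_along(neg)),
                        sprintf("oth%02d", seq_along(other))),
            rfScore = c(rep(1, length(loo)), neg, other),
            isTraining = c(rep(TRUE, length(loo)),
                           rep(FALSE, length(neg) + length(other))),
            looScore = c(loo, rep(NA_real_, length(neg) + length(other))),
            featureCount = 40L)
        new("ProgulonScores", table = tab, nModels = 10L)
    }
    set.seed(17)
    loo <- runif(8, 0.6, 1)
    neg <- runif(50, 0, 0.7)
    qc <- qcCheck(mkScores(loo, neg), sprintf("neg%03d", 1:50))
    expect_equal(qc@auc, aucOracle(loo, neg))
    # perfect separation passes
    qcPass <- qcCheck(mkScores(rep(0.99, 8), runif(50, 0, 0.5)),
                      sprintf("neg%03d", 1:50))
    expect_true(qcPass@pass)
    expect_equal(qcPass@auc, 1)
    # AUC below 0.99 fails even with a good top-10
    qcA <- qcCheck(mkScores(c(0.2, rep(0.99, 7)), runif(50, 0.1, 0.6)),
                   sprintf("neg%03d", 1:50))
    expect_lt(qcA@auc, 0.99)
    expect_false(qcA@pass)
    # fewer than 4 cross-validated positives in the top 10 fails despite
    # perfect AUC: 8 non-training proteins outscore all but 3 positives
    qcT <- qcCheck(mkScores(c(0.97, 0.96, 0.95, rep(0.80, 5)),
                            runif(50, 0, 0.5),
                            other = rep(0.90, 8)),
                   sprintf("neg%03d", 1:50))
    expect_equal(qcT@auc, 1)
    expect_lt(qcT@top10TrainingCount, 4)
    expect_false(qcT@pass)
    # the QcReport invariant rejects an inconsistent verdict
    expect_error(new("QcReport", auc = 0.995, top10TrainingCount = 3L,
                     pass = TRUE), "pass")
})
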