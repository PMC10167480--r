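test_that("annotation enrichment filters small sets and applies Bonferroni", {
    universe <- sprintf("g%03d", 1:200)
    ann <- list(big = universe[1:25], small = universe[1:19],
                other = universe[26:60])
    groups <- list(mod = universe[1:10])
    res <- annotationEnrichment(groups, ann, universe, minSetSize = 20)
    expect_setequal(res$set, c("big", "other"))   # size-19 set excluded
    expect_equal(res$pBonferroni, pmin(1, res$pRaw * nrow(res)))
    # Fisher P equals the enumeration oracle for the (8,2,12,178) table
    # construction: group of 10 with 8 in a 20-protein set, universe 200
    # (a catch-all set keeps every protein annotated, so the effective
    # universe stays at 200)
    ann2 <- list(s = universe[1:20], all = universe)
    grp2 <- list(m = c(universe[1:8], universe[191:192]))
    res2 <- annotationEnrichment(grp2, ann2, universe, minSetSize = 20)
    expect_equal(res2$pRaw[res2$set == "s"],
                 fisherGreaterOracle(8, 2, 12, 178), tolerance = 1e-12)
    expect_error(annotationEnrichment(groups, ann, "not_annotated"),
                 "universe")
})

test_that("per-gene contribution is the pairwise-complete mRNA-protein rho", {
    set.seed(41)
    mrna <- matrix(rnorm(5 * 12), 5, 12,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
    prot <- mrna
    prot[2, ] <- -mrna[2, ]
    prot[3, 1:9] <- NA                         # 3 complete pairs left
    prot[4, ] <- NA
    po <- PairedOmics(mrna, prot)
    rho <- contributionRho(po)
    expect_equal(unname(rho["g1"]), 1)
    expect_equal(unname(rho["g2"]), -1)
    expect_false(is.na(rho["g3"]))
    expect_true(is.na(rho["g4"]))              # insufficient overlap
})

test_that("coupling strength orders the recovered contribution", {
    higher <- 0
    for (i in 1:20) {
        sim <- simulatePairedOmics(
            60, 30,
            groups = list(list(size = 25, coupling = 0.9, mrnaLatentSd = 1,
                               proteinLatentSd = 0, noiseSd = 0.5),
                          list(size = 25, coupling = 0.1, mrnaLatentSd = 1,
                               proteinLatentSd = 0, noiseSd = 0.5)),
            rngSeed = 500 + i)
        rho <- contributionRho(sim$omics)
        g1 <- names(sim$truth$membership)[sim$truth$membership %in% "group_01"]
        g2 <- names(sim$truth$membership)[sim$truth$membership %in% "group_02"]
        if (median(rho[g1], na.rm = TRUE) > median(rho[g2], na.rm = TRUE))
            higher <- higher + 1
    }
    expect_gte(higher, 19)
})

test_that("permutation test honours its estimator bounds and direction", {
    stat <- setNames(c(rep(10, 5), rnorm(95)), sprintf("g%03d", 1:100))
    grp <- sprintf("g%03d", 1:5)
    res <- groupPermutationTest(stat, grp, B = 200, side = "high",
                                rngSeed = 2)
    expect_equal(res$p, 1 / 201)               # beats every null median
    # degenerate: group = universe, null equals observed always
    resAll <- groupPermutationTest(stat, names(stat), B = 50, rngSeed = 2)
    expect_equal(resAll$p, 1)
    expect_error(groupPermutationTest(stat, c(names(stat), "extra")),
                 "larger than universe")
    # invariant to monotone transforms of the statistic
    res2 <- groupPermutationTest(exp(stat / 5), grp, B = 200, side = "high",
                                 rngSeed = 2)
    expect_equal(res2$p, res$p)
    # power at a 1-SD shift, B = 200
    hits <- 0
    for (i in 1:20) {
        set.seed(900 + i)
        st <- setNames(rnorm(200), sprintf("h%03d", 1:200))
        grp2 <- sample(names(st), 20)
        st[grp2] <- st[grp2] + 1
        p <- groupPermutationTest(st, grp2, B = 200, side = "high",
                                  rngSeed = i)$p
        if (p < 0.05) hits <- hits + 1
    }
    expect_gte(hits, 18)
})

test_that("group coordination recovers planted pairwise correlation", {
    set.seed(47)
    # perfect coordination: shared latent, no noise
    z <- rnorm(30)
    mat <- rbind(a = z, b = 2 * z, c = z - 1)
    colnames(mat) <- paste0("s", 1:30)
    expect_equal(groupCoordination(mat, c("a", "b", "c")), 1)
    # independent rows: coordination near zero in >= 19 of 20 simulations
    low <- 0
    for (i in 1:20) {
        set.seed(700 + i)
        m0 <- matrix(rnorm(10 * 30), 10, 30,
                     dimnames = list(paste0("r", 1:10), paste0("s", 1:30)))
        if (abs(groupCoordination(m0, rownames(m0))) < 0.2) low <- low + 1
    }
    expect_gte(low, 19)
    # planted rho 0.6 recovered within +/- 0.1 (median over seeds)
    med <- sapply(1:10, function(i) {
        sim <- simulateProteomeHd(
            30, 60, list(moduleSpec(30, responseSd = sqrt(1.5), noiseSd = 1,
                                    coreSize = 0)),
            rngSeed = 800 + i)
        groupCoordination(ratios(sim$matrix), proteinIds(sim$matrix))
    })
    expect_lt(abs(median(med) - 0.6), 0.1)
})

test_that("conservation splits by progulon category with a Fisher test", {
    set.seed(53)
    n <- 30
    ids <- sprintf("hs%02d", 1:n)
    m <- matrix(rnorm(n * 40), n, 40, dimnames = list(ids, NULL))
    # plant correlated pairs
    m[2, ] <- m[1, ] + rnorm(40, sd = 0.3)
    m[4, ] <- m[3, ] + rnorm(40, sd = 0.3)
    rhoA <- cor(t(m), method = "spearman")
    orth <- setNames(sprintf("mm%02d", 1:n), ids)
    rhoB <- rhoA
    dimnames(rhoB) <- list(orth, orth)
    membership <- setNames(c("p1", "p1", "p2", "p3"), ids[1:4])
    res <- conservationOfCoregulation(rhoA, rhoB, orth, membership)
    # a relabelled copy conserves every co-regulated pair in every category
    expect_true(all(res$table$rate[res$table$pairs > 0] == 1))
    expect_error(conservationOfCoregulation(
        rhoA, rhoB, setNames("mmX", "absent"), membership), "mappable")
})

test_that("same-chromosome enrichment matches the combinatorial expectation", {
    # all genes on one chromosome
    cmAll <- setNames(rep("chr1", 10), paste0("g", 1:10))
    res <- sameChromosomeEnrichment(paste0("g", 1:6), cmAll)
    expect_equal(res$observed, 1)
    # two equal chromosomes: expected fraction = (n/2 - 1) / (n - 1)
    n <- 100
    cm2 <- setNames(rep(c("chrA", "chrB"), each = n / 2), sprintf("g%03d", 1:n))
    res2 <- sameChromosomeEnrichment(sprintf("g%03d", 1:4), cm2)
    expect_equal(res2$expected, (n / 2 - 1) / (n - 1))
    # random groups show no enrichment in >= 18 of 20 draws
    flat <- 0
    for (i in 1:20) {
        set.seed(300 + i)
        grp <- sample(names(cm2), 12)
        if (sameChromosomeEnrichment(grp, cm2)$fisherP > 0.05) flat <- flat + 1
    }
    expect_gte(flat, 18)
    # two-sided Fisher equals the enumeration oracle
    grp <- names(cm2)[c(1:8, 51:52)]
    res3 <- sameChromosomeEnrichment(grp, cm2)
    og <- choose(8, 2) + choose(2, 2)
    tot <- choose(10, 2)
    ou <- 2 * choose(50, 2)
    totU <- choose(100, 2)
    expect_equal(res3$fisherP,
                 fisherTwoSidedOracle(og, tot - og, ou - og,
                                      (totU - tot) - (ou - og)),
                 tolerance = 1e-9)
    expect_warning(sameChromosomeEnrichment(c("g001", "g002", "nope"), cm2),
                   "unmapped")
})

test_that("scale of variation is the raw MAD with homogeneity", {
    mat <- rbind(flat = rep(2, 5), tri = c(-1, 0, 1, 0, 0))
    colnames(mat) <- paste0("s", 1:5)
    expect_equal(scaleOfVariation(mat, "flat"), 0)
    expect_equal(unname(stats::mad(c(-1, 0, 1), constant = 1)), 1)
    expect_equal(scaleOfVariation(rbind(x = c(-1, 0, 1)), "x"), 1)
    set.seed(61)
    m <- matrix(rnorm(40), 4, 10,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
    expect_equal(scaleOfVariation(3 * m, rownames(m)),
                 3 * scaleOfVariation(m, rownames(m)))
})
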