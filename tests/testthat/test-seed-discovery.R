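test_that("OPTICS reachability matches an independent implementation", {
    # tiny 1-D two-blob fixture; sklearn's OPTICS (precomputed metric) is
    # the independent oracle for the reachability profile
    set.seed(42)
    pts <- c(rnorm(6, 0, 0.3), rnorm(6, 10, 0.3))
    dm <- as.matrix(dist(pts))
    rownames(dm) <- colnames(dm) <- paste0("p", 1:12)
    res <- opticsClusters(dm, xi = 0.05, minPts = 3)
    reach <- attr(res, "reachability")
    ord <- attr(res, "order")

    csv <- withr::local_tempfile(fileext = ".csv")
    out <- withr::local_tempfile(fileext = ".txt")
    write.csv(dm, csv, row.names = FALSE)
    script <- sprintf(paste0(
        "import numpy as np, pandas as pd\n",
        "from sklearn.cluster import OPTICS\n",
        "D = pd.read_csv('%s').values\n",
        "o = OPTICS(metric='precomputed', min_samples=3,",
        " max_eps=np.inf).fit(D)\n",
        "np.savetxt('%s', np.column_stack([o.ordering_,",
        " o.reachability_[o.ordering_]]))\n"), csv, out)
    status <- system2("python", "-", input = script)
    expect_equal(status, 0L)
    sk <- read.table(out)
    expect_identical(ord, paste0("p", sk$V1 + 1))
    expect_equal(reach[-1], sk$V2[-1], tolerance = 1e-8)

    # both blobs recovered as clusters
    expect_length(res, 2)
    expect_setequal(res[[which.max(sapply(res, function(s) sum(s %in% paste0("p", 1:6))))]],
                    paste0("p", 1:6))
})

test_that("OPTICS separates tight blobs and leaves uniform noise unclustered", {
    set.seed(12)
    xy <- rbind(matrix(rnorm(20, 0, 0.2), 10),
                matrix(rnorm(20, 8, 0.2), 10))
    dm <- as.matrix(dist(xy))
    rownames(dm) <- colnames(dm) <- sprintf("n%02d", 1:20)
    cl <- opticsClusters(dm, xi = 0.05, minPts = 4)
    # the xi hierarchy must contain both blobs; the flat assignment may
    # additionally carve sub-clusters out of within-blob jitter
    ord <- attr(cl, "order")
    xiSets <- lapply(attr(cl, "hierarchy"),
                     function(h) ord[h[1]:h[2]])
    truth <- list(sprintf("n%02d", 1:10), sprintf("n%02d", 11:20))
    jac <- sapply(truth, function(tr) max(sapply(c(cl, xiSets), function(s)
        length(intersect(s, tr)) / length(union(s, tr)))))
    expect_true(all(jac >= 0.8))
    # every flat cluster respects a blob boundary
    for (s in cl)
        expect_true(all(s %in% truth[[1]]) || all(s %in% truth[[2]]))

    expect_error(opticsClusters(dm[1:3, 1:3], minPts = 5), "minPts")
})

test_that("cohesiveness clustering matches exhaustive search on small graphs", {
    # isolated 4-clique plus an isolated 3-clique (7 nodes):
    # the 4-clique is kept, the 3-clique falls below the size filter
    ids <- letters[1:7]
    e <- rbind(t(combn(ids[1:4], 2)), t(combn(ids[5:7], 2)))
    net <- new("CoregulationNetwork", nodes = ids,
               edges = data.frame(idA = e[, 1], idB = e[, 2], weight = 1),
               selectionFraction = 0.1)
    cl <- clusterOneClusters(net, minSize = 4, densityThreshold = 0.4)
    expect_length(cl, 1)
    expect_setequal(cl[[1]], ids[1:4])
    # greedy growth attains the exhaustive cohesiveness optimum
    W <- progulons:::networkWeightMatrix(net)
    oracle <- cohesivenessOracle(W, penalty = 2)
    expect_equal(attr(cl[[1]], "cohesiveness"), oracle$f, tolerance = 1e-12)
    expect_identical(sort(unclass(cl[[1]])), oracle$set)

    # weighted 7-node toy graph with cross-links
    set.seed(21)
    ids <- paste0("v", 1:7)
    pairs <- t(combn(ids, 2))
    w <- round(runif(nrow(pairs)), 2)
    keep <- w > 0.4
    net2 <- new("CoregulationNetwork", nodes = ids,
                edges = data.frame(idA = pairs[keep, 1], idB = pairs[keep, 2],
                                   weight = w[keep]),
                selectionFraction = 0.1)
    W2 <- progulons:::networkWeightMatrix(net2)
    oracle2 <- cohesivenessOracle(W2, penalty = 2)
    cl2 <- clusterOneClusters(net2, minSize = 2, densityThreshold = 0,
                              mergeOverlap = 1.1)
    best <- cl2[[1]]
    expect_equal(attr(best, "cohesiveness"), oracle2$f, tolerance = 1e-12)
    expect_identical(sort(unclass(best)), oracle2$set)

    expect_error(clusterOneClusters(
        new("CoregulationNetwork", nodes = ids,
            edges = data.frame(idA = character(), idB = character(),
                               weight = numeric()),
            selectionFraction = 0.1)), "empty graph")
})

test_that("seed derivation intersects best-matching cluster pairs", {
    op <- list(c("A", "B", "C", "D", "E"), c("P", "Q", "R", "S"))
    c1 <- list(c("A", "B", "C", "D", "F"),      # overlap 4 with op1
               c("A", "B", "C"),                # overlap 3 (redundant, loses)
               c("P", "Q", "R", "S", "T"))
    seeds <- deriveSeeds(op, c1, minSeed = 4)
    expect_length(seeds, 2)
    mem <- lapply(seeds, members)
    expect_true(any(sapply(mem, setequal, c("A", "B", "C", "D"))))
    expect_true(any(sapply(mem, setequal, c("P", "Q", "R", "S"))))
    # every seed is a subset of one OPTICS and one cohesiveness cluster
    for (s in seeds) {
        expect_equal(sum(sapply(op, function(o) all(members(s) %in% o))), 1)
        expect_true(any(sapply(c1, function(o) all(members(s) %in% o))))
    }
    # intersections below the minimum size produce no seed
    seeds2 <- deriveSeeds(list(c("A", "B", "C", "X", "Y")),
                          list(c("A", "B", "C", "Z")), minSeed = 4)
    expect_length(seeds2, 0)
})

test_that("dual clustering recovers planted tight modules", {
    # ten mutually independent tight modules (each is background for the
    # others); the edge fraction is sized so the network covers the
    # planted within-module pairs at this desk scale
    nMod <- 10
    mods <- replicate(nMod, moduleSpec(12, responseSd = 3, noiseSd = 1,
                                       coreSize = 0), simplify = FALSE)
    sim <- simulateProteomeHd(120, 40, mods, rngSeed = 31)
    fs <- findSeeds(sim$matrix, fraction = 0.12, rngSeed = 31)
    truthSets <- split(names(sim$truth$membership),
                       sim$truth$membership)
    recovered <- sapply(truthSets, function(tr) {
        if (!length(fs$seeds)) return(0)
        max(sapply(fs$seeds, function(s)
            length(intersect(members(s), tr)) /
                length(union(members(s), tr))))
    })
    expect_gte(mean(recovered >= 0.5), 0.8)
})
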