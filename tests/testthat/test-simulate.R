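test_that("random trees are valid and uniform over labelled trees", {
    expect_equal(randomTree(2), matrix(c(1L, 2L), 1L, 2L))
    set.seed(1)
    t3 <- randomTree(3)
    expect_equal(nrow(t3), 2)
    expect_equal(sort(unique(as.vector(t3))), 1:3)
    expect_error(randomTree(1), "at least 2")
    ## uniformity over the 16 labelled trees on 4 nodes (Cayley: 4^2)
    set.seed(99)
    draws <- replicate(4800, {
        e <- randomTree(4)
        paste(sort(paste(e[, 1], e[, 2])), collapse = ";")
    })
    counts <- table(draws)
    expect_length(counts, 16)
    expected <- 4800 / 16
    se <- sqrt(4800 * (1 / 16) * (15 / 16))
    expect_true(all(abs(counts - expected) <= 3 * se))
    ## connectivity: each tree spans all labels
    set.seed(5)
    for (m in c(2, 5, 9)) {
        e <- randomTree(m)
        expect_equal(nrow(e), m - 1)
        expect_equal(sort(unique(as.vector(e))), seq_len(m))
    }
})

test_that("planted maps are disjoint cliques and bicliques of stated sizes", {
    cfg <- simConfig(nNodes = 500, nModules = 6, nCliqueDecoys = 2,
                     nBicliqueDecoys = 2, seed = 4)
    set.seed(4)
    pl <- plantMap(cfg)
    tr <- pl$truth
    mods <- slot(tr, "modules")
    expect_length(mods, 6)
    expect_true(all(lengths(mods) >= 10 & lengths(mods) <= 20))
    allPlanted <- c(unlist(mods), unlist(slot(tr, "cliqueDecoys")),
                    unlist(lapply(slot(tr, "bicliqueDecoys"), unlist)))
    expect_false(anyDuplicated(allPlanted) > 0)
    ## modules are complete in H*, tree links complete bipartite in G*
    idx <- function(s) match(s, pl$nodes)
    for (m in mods) {
        sub <- pl$Hstar[idx(m), idx(m)]
        expect_true(all(sub[upper.tri(sub)]))
    }
    tl <- slot(tr, "treeLinks")
    for (e in seq_len(nrow(tl))) {
        a <- idx(mods[[tl[e, 1]]]); b <- idx(mods[[tl[e, 2]]])
        expect_true(all(pl$Gstar[a, b]))
    }
    ## spanning tree over module indices
    expect_equal(nrow(tl), 5)
    expect_equal(sort(unique(as.vector(tl))), 1:6)
})

test_that("noiseless planted structures are maximal cliques and bicliques", {
    sim <- simulateMap(simConfig(nNodes = 80, nModules = 3,
                                 nCliqueDecoys = 1, nBicliqueDecoys = 0,
                                 sizeRange = c(5, 8), seed = 7))
    A <- slot(sim$H, "adj") > 0
    for (m in slot(sim$truth, "modules")) {
        expect_true(all(A[m, m][upper.tri(diag(length(m)))]))
        out <- setdiff(nodes(sim$H), m)
        expect_false(any(vapply(out, function(v) all(A[v, m]),
                                logical(1))))
    }
    ## each tree link is among the maximal bicliques of noiseless G
    bics <- enumerateMaximalBicliques(sim$G, minSide = 2)
    keys <- bicKey(bics)
    tl <- slot(sim$truth, "treeLinks")
    mods <- slot(sim$truth, "modules")
    deg <- table(as.vector(tl))
    for (e in seq_len(nrow(tl))) {
        i <- tl[e, 1]; j <- tl[e, 2]
        ## a tree leaf's star is the maximal biclique containing its link
        if (deg[as.character(i)] == 1 || deg[as.character(j)] == 1) {
            leaf <- if (deg[as.character(i)] == 1) i else j
            hub <- setdiff(c(i, j), leaf)
            partners <- sort(unique(as.vector(
                tl[tl[, 1] == hub | tl[, 2] == hub, ])))
            partners <- setdiff(partners, hub)
            star <- sort(unlist(mods[partners]))
            k <- bicKey(list(list(sideA = sort(mods[[hub]]),
                                  sideB = star)))
            expect_true(k %in% keys)
        }
    }
})

test_that("flip noise hits the configured rate and edge cases", {
    cfg0 <- simConfig(nNodes = 120, nModules = 3, nCliqueDecoys = 1,
                      nBicliqueDecoys = 1, flipP = 0, seed = 11)
    set.seed(11)
    pl <- plantMap(cfg0)
    nets0 <- applyNoise(pl, cfg0)
    expect_equal(slot(nets0$H, "adj") > 0, unname(pl$Hstar),
                 ignore_attr = TRUE)
    ## P = 1 complements every pair
    cfg1 <- simConfig(nNodes = 120, nModules = 3, nCliqueDecoys = 1,
                      nBicliqueDecoys = 1, flipP = 1, seed = 11)
    nets1 <- applyNoise(pl, cfg1)
    a1 <- slot(nets1$H, "adj") > 0
    comp <- !pl$Hstar; diag(comp) <- FALSE
    expect_equal(unname(a1), unname(comp))
    ## P = 0.15: flipped fraction within 3 binomial SE
    cfg15 <- simConfig(nNodes = 500, nModules = 6, nCliqueDecoys = 2,
                       nBicliqueDecoys = 2, flipP = 0.15, seed = 12)
    set.seed(12)
    pl5 <- plantMap(cfg15)
    nets15 <- applyNoise(pl5, cfg15)
    ut <- upper.tri(pl5$Hstar)
    flipped <- sum((slot(nets15$H, "adj") > 0)[ut] != pl5$Hstar[ut])
    npairs <- sum(ut)
    se <- sqrt(npairs * 0.15 * 0.85)
    expect_lte(abs(flipped - 0.15 * npairs), 3 * se)
})

test_that("weighted noise is centred on the planted sign pattern", {
    cfg <- simConfig(nNodes = 400, nModules = 5, nCliqueDecoys = 2,
                     nBicliqueDecoys = 2, mode = "weighted",
                     sigma = 0.8, seed = 13)
    sim <- simulateMap(cfg)
    set.seed(13)
    pl <- plantMap(cfg)
    ut <- upper.tri(pl$Hstar)
    w <- slot(sim$H, "adj")[ut]
    planted <- pl$Hstar[ut]
    for (grp in list(planted, !planted)) {
        mu <- if (identical(grp, planted)) 1 else -1
        n <- sum(grp)
        expect_lte(abs(mean(w[grp]) - mu), 3 * 0.8 / sqrt(n))
    }
    ## sigma = 0 gives exact +-1 weights
    cfg0 <- simConfig(nNodes = 100, nModules = 3, nCliqueDecoys = 0,
                      nBicliqueDecoys = 1, mode = "weighted",
                      sigma = 0, seed = 14)
    sim0 <- simulateMap(cfg0)
    expect_true(all(slot(sim0$H, "adj")[upper.tri(diag(100))] %in%
                    c(-1, 1)))
})

test_that("simulation is reproducible and round-trips through files", {
    cfg <- simConfig(nNodes = 150, nModules = 3, nCliqueDecoys = 1,
                     nBicliqueDecoys = 1, flipP = 0.1, seed = 21)
    s1 <- simulateMap(cfg)
    s2 <- simulateMap(cfg)
    expect_identical(slot(s1$H, "adj"), slot(s2$H, "adj"))
    expect_identical(slot(s1$G, "adj"), slot(s2$G, "adj"))
    expect_identical(s1$truth, s2$truth)
    dir <- tempfile("sim")
    writeSim(s1, dir)
    H <- readEdgeList(file.path(dir, "H.tsv"))
    expect_identical(slot(H, "adj") > 0, slot(s1$H, "adj") > 0)
    tr <- readTruth(dir)
    expect_identical(slot(tr, "modules"), slot(s1$truth, "modules"))
    expect_identical(slot(tr, "treeLinks"), slot(s1$truth, "treeLinks"))
})

test_that("configurations that cannot fit are rejected", {
    expect_error(simConfig(nNodes = 50, nModules = 6), "fit")
    expect_error(simConfig(nNodes = 500, nModules = 6, flipP = 1.5))
})
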