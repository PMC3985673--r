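## small planted instance used by several initiator tests
smallSim <- function(seed = 3, flipP = 0, nModules = 4, nNodes = 200) {
    simulateMap(simConfig(nNodes = nNodes, nModules = nModules,
                          nCliqueDecoys = 1, nBicliqueDecoys = 1,
                          flipP = flipP, seed = seed))
}

test_that("dicerClean keeps cohesive sides and prunes loose nodes", {
    ## both sides are H-cliques: unchanged
    nm <- c(paste0("a", 1:4), paste0("b", 1:4))
    cl <- function(s) {
        pr <- combn(s, 2)
        data.frame(node_a = pr[1, ], node_b = pr[2, ])
    }
    H <- Network(rbind(cl(paste0("a", 1:4)), cl(paste0("b", 1:4))),
                 nodes = nm)
    G <- Network(expand.grid(node_a = paste0("a", 1:4),
                             node_b = paste0("b", 1:4),
                             stringsAsFactors = FALSE), nodes = nm)
    bic <- list(sideA = paste0("a", 1:4), sideB = paste0("b", 1:4))
    out <- dicerClean(H, G, bic, minSize = 3)
    expect_equal(out$sideA, paste0("a", 1:4))
    expect_equal(out$sideB, paste0("b", 1:4))
    expect_true(out$p >= 0 && out$p <= 1)

    ## a node without H-edges to its side is removed
    nm2 <- c(nm, "x")
    H2 <- Network(rbind(cl(paste0("a", 1:4)), cl(paste0("b", 1:4))),
                  nodes = nm2)
    G2 <- Network(expand.grid(node_a = c(paste0("a", 1:4), "x"),
                              node_b = paste0("b", 1:4),
                              stringsAsFactors = FALSE), nodes = nm2)
    out2 <- dicerClean(H2, G2, list(sideA = c(paste0("a", 1:4), "x"),
                                    sideB = paste0("b", 1:4)),
                       minSize = 3)
    expect_equal(out2$sideA, paste0("a", 1:4))

    ## minimum-size rejection
    expect_null(dicerClean(H2, G2, list(sideA = c("a1", "a2", "x"),
                                        sideB = paste0("b", 1:3)),
                           minSize = 3))
})

test_that("MBC-DICER recovers a noiseless planted map exactly", {
    sim <- smallSim(seed = 3)
    init <- mbcDicerInit(sim$H, sim$G, minSize = 5)
    expect_equal(pairJaccard(seedSets(init), slot(sim$truth, "modules")), 1)
    expect_gte(nrow(seedLinks(init)), 1)
    ## empty G -> empty solution
    emptyG <- emptyNetwork(nodes(sim$G))
    init0 <- mbcDicerInit(sim$H, emptyG, minSize = 5)
    expect_length(seedSets(init0), 0)
})

test_that("overlapping cleaned pairs resolve by score, first-come per node", {
    ## two bicliques sharing three a-nodes; the higher-scoring pair keeps
    ## them, the other keeps its remainder or drops below the size floor
    aa <- paste0("a", 1:9); bb <- paste0("b", 1:6); cc <- paste0("c", 1:5)
    nm <- c(aa, bb, cc)
    cl <- function(s) {
        pr <- combn(s, 2)
        data.frame(node_a = pr[1, ], node_b = pr[2, ])
    }
    H <- Network(rbind(cl(aa), cl(bb), cl(cc)), nodes = nm)
    G <- Network(rbind(
        expand.grid(node_a = aa[1:6], node_b = bb,
                    stringsAsFactors = FALSE),
        expand.grid(node_a = aa[4:9], node_b = cc,
                    stringsAsFactors = FALSE)), nodes = nm)
    init <- mbcDicerInit(H, G, minSize = 5)
    sets <- seedSets(init)
    expect_true(!anyDuplicated(unlist(sets)))
    keys <- vapply(sets, paste, character(1), collapse = ",")
    ## the (a1..a6, b) pair outscores (a4..a9, c); a7..a9 alone is below
    ## the floor, so c survives only as an unlinked set
    expect_true(paste(aa[1:6], collapse = ",") %in% keys)
    expect_true(paste(bb, collapse = ",") %in% keys)
    expect_true(paste(cc, collapse = ",") %in% keys)
    expect_false(any(aa[7:9] %in% unlist(sets)))
})

test_that("dicer-k seeds a linked clique pair from its cross structure", {
    ## two H-cliques joined by a G biclique: recovered as one linked pair
    nm <- c(paste0("a", 1:4), paste0("b", 1:4))
    cl <- function(s) {
        pr <- combn(s, 2)
        data.frame(node_a = pr[1, ], node_b = pr[2, ])
    }
    H <- Network(rbind(cl(paste0("a", 1:4)), cl(paste0("b", 1:4))),
                 nodes = nm)
    G <- Network(expand.grid(node_a = paste0("a", 1:4),
                             node_b = paste0("b", 1:4),
                             stringsAsFactors = FALSE), nodes = nm)
    init <- dicerKInit(H, G, k = 2, pairAlpha = 1)
    sets <- seedSets(init)
    expect_length(sets, 2)
    expect_equal(sets[[1]], paste0("a", 1:4))
    expect_equal(sets[[2]], paste0("b", 1:4))
    expect_equal(nrow(seedLinks(init)), 1)
    ## minimum size filter: same instance with k above the clique size
    init5 <- dicerKInit(H, G, k = 5, pairAlpha = 1)
    expect_length(seedSets(init5), 0)
})

test_that("dicer-k seeds only genuine planted pairs on noiseless data", {
    ## pair seeding consumes partner modules, so full recovery is not
    ## guaranteed even without noise (tree leaves can be orphaned), but
    ## every accepted set must coincide exactly with a planted module
    sim <- smallSim(seed = 6)
    set.seed(6)
    init <- dicerKInit(sim$H, sim$G, k = 5)
    sets <- seedSets(init)
    expect_gte(length(sets), 2)
    tkeys <- vapply(slot(sim$truth, "modules"), paste, character(1),
                    collapse = ",")
    for (s in sets)
        expect_true(paste(sort(s), collapse = ",") %in% tkeys)
})

test_that("hierarchical clustering splits clean and noisy block structure", {
    nm <- sprintf("v%02d", 1:20)
    cl <- function(s) {
        pr <- combn(s, 2)
        data.frame(node_a = pr[1, ], node_b = pr[2, ])
    }
    H <- Network(rbind(cl(nm[1:10]), cl(nm[11:20])), nodes = nm)
    init <- hclustInit(H, minSize = 5)
    expect_equal(lapply(seedSets(init), sort), list(nm[1:10], nm[11:20]))
    ## a single clique stays whole
    H1 <- Network(cl(sprintf("w%02d", 1:12)))
    expect_equal(lengths(seedSets(hclustInit(H1, minSize = 5))), 12)
    ## noisy two-block structure is recovered to high pair-Jaccard
    js <- vapply(1:5, function(seed) {
        set.seed(seed)
        n <- 40
        nm2 <- sprintf("u%02d", 1:n)
        truthBlocks <- list(nm2[1:20], nm2[21:40])
        adj <- matrix(0, n, n, dimnames = list(nm2, nm2))
        block <- matrix(0, n, n)
        block[1:20, 1:20] <- 1; block[21:40, 21:40] <- 1
        ut <- upper.tri(adj)
        flip <- runif(sum(ut)) < 0.1
        adj[ut] <- abs(block[ut] - flip)
        adj <- adj + t(adj); diag(adj) <- 0
        Hn <- new("Network", nodes = nm2, mode = "unweighted", adj = adj)
        pairJaccard(seedSets(hclustInit(Hn, minSize = 5)), truthBlocks)
    }, numeric(1))
    expect_true(all(js >= 0.9))
})

test_that("greedy node addition finds cliques and respects its filters", {
    nm <- c(paste0("a", 1:6), paste0("z", 1:4))
    pr <- combn(paste0("a", 1:6), 2)
    H <- Network(data.frame(node_a = pr[1, ], node_b = pr[2, ]),
                 nodes = nm)
    init <- greedyInit(H, minSize = 5)
    expect_equal(seedSets(init), list(paste0("a", 1:6)))
    ## all pairwise weights negative -> nothing to seed
    n <- 6
    adj <- matrix(-1, n, n); diag(adj) <- 0
    nmw <- paste0("w", 1:n)
    dimnames(adj) <- list(nmw, nmw)
    Hw <- new("Network", nodes = nmw, mode = "weighted", adj = adj)
    expect_length(seedSets(greedyInit(Hw, minSize = 2)), 0)
    ## overlapping near-cliques: the first-seeded one claims shared nodes
    s1 <- paste0("p", 1:6); s2 <- c(paste0("p", 4:6), paste0("q", 1:4))
    pr1 <- combn(s1, 2); pr2 <- combn(s2, 2)
    Ho <- Network(unique(rbind(
        data.frame(node_a = pr1[1, ], node_b = pr1[2, ]),
        data.frame(node_a = pr2[1, ], node_b = pr2[2, ]))))
    out <- greedyInit(Ho, minSize = 4)
    expect_true(!anyDuplicated(unlist(out@sets)))
    expect_true(all(s1 %in% out@sets[[1]]))
})

test_that("compiled side cleaning matches the reference fixpoint rule", {
    ## the batched C++ cleaner used by mbcDicerInit must agree with the
    ## R-level iterated fixpoint on arbitrary side sets
    for (seed in 1:5) {
        H <- randomNetwork(30, 0.4, seed = seed + 70)
        adj <- slot(H, "adj")
        set.seed(seed)
        sideA <- replicate(20, sort(sample(30, sample(4:12, 1))),
                           simplify = FALSE)
        sideB <- replicate(20, sort(sample(30, sample(4:12, 1))),
                           simplify = FALSE)
        got <- modmapr:::.clean_biclique_pairs_cpp(adj, TRUE, sideA,
                                                   sideB, 3L)
        want <- list()
        seen <- character()
        for (i in seq_along(sideA)) {
            ca <- modmapr:::.cleanComponentsIdx(adj, TRUE, sideA[[i]], 3L)
            if (!length(ca)) next
            cb <- modmapr:::.cleanComponentsIdx(adj, TRUE, sideB[[i]], 3L)
            for (a0 in ca) for (b0 in cb) {
                if (b0[1] < a0[1]) { a <- b0; b <- a0 }
                else { a <- a0; b <- b0 }
                key <- paste(c(a, -1, b), collapse = ",")
                if (key %in% seen) next
                seen <- c(seen, key)
                want[[length(want) + 1]] <- list(a = a, b = b)
            }
        }
        expect_equal(length(got$sideA), length(want))
        for (i in seq_along(want)) {
            expect_equal(got$sideA[[i]], want[[i]]$a)
            expect_equal(got$sideB[[i]], want[[i]]$b)
        }
    }
})

test_that("initiators return disjoint sets and are reproducible", {
    sim <- smallSim(seed = 8, flipP = 0.1)
    run <- function() {
        set.seed(11)
        list(m = mbcDicerInit(sim$H, sim$G, minSize = 5),
             d = dicerKInit(sim$H, sim$G, k = 5),
             h = hclustInit(sim$H, minSize = 5),
             g = greedyInit(sim$H, minSize = 5))
    }
    a <- run(); b <- run()
    expect_identical(a, b)
    for (ini in a)
        expect_true(!anyDuplicated(unlist(seedSets(ini))))
})
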