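## Planted-map simulator: matched H/G network pairs containing a perfect
## module map (modules are cliques in H, links are bicliques in G arranged
## on a random tree) plus decoy cliques/bicliques, degraded by flip noise
## (unweighted) or Gaussian weights (weighted).

#' Simulation configuration
#'
#' Defaults reproduce the 500-node study condition: 6 planted modules on a
#' random tree, two decoy cliques in H and two decoy bicliques in G, all
#' structure sizes uniform on 10..20.
#'
#' @param nNodes total number of nodes.
#' @param nModules number of planted modules (>= 2).
#' @param nCliqueDecoys decoy cliques planted in H only.
#' @param nBicliqueDecoys decoy bicliques planted in G only.
#' @param sizeRange inclusive size range for modules, decoy cliques and
#'   each biclique side.
#' @param mode `"unweighted"` (flip noise) or `"weighted"` (Gaussian
#'   weights).
#' @param flipP flip probability P for unweighted mode (each planted pair
#'   independently deleted, each background pair independently turned into
#'   an edge).
#' @param sigma Gaussian standard deviation for weighted mode (planted
#'   pairs ~ N(1, sigma), background pairs ~ N(-1, sigma)).
#' @param seed integer seed driving all randomness of [simulateMap()].
#' @return a list of class `SimConfig`.
#' @export
simConfig <- function(nNodes = 500L, nModules = 6L, nCliqueDecoys = 2L,
                      nBicliqueDecoys = 2L, sizeRange = c(10L, 20L),
                      mode = c("unweighted", "weighted"),
                      flipP = 0, sigma = 0, seed = 1L) {
    mode <- match.arg(mode)
    stopifnot(nModules >= 2L, nCliqueDecoys >= 0L, nBicliqueDecoys >= 0L,
              length(sizeRange) == 2L, sizeRange[1L] >= 2L,
              sizeRange[2L] >= sizeRange[1L],
              flipP >= 0, flipP <= 1, sigma >= 0)
    maxPlanted <- (nModules + nCliqueDecoys + 2L * nBicliqueDecoys) *
        sizeRange[2L]
    if (maxPlanted > nNodes)
        stop("planted structures cannot be guaranteed to fit in 'nNodes'")
    structure(list(nNodes = as.integer(nNodes),
                   nModules = as.integer(nModules),
                   nCliqueDecoys = as.integer(nCliqueDecoys),
                   nBicliqueDecoys = as.integer(nBicliqueDecoys),
                   sizeRange = as.integer(sizeRange),
                   mode = mode, flipP = flipP, sigma = sigma,
                   seed = as.integer(seed)),
              class = "SimConfig")
}

#' Uniform random labelled tree
#'
#' Draws a labelled tree on `m` nodes uniformly among the `m^(m-2)`
#' possibilities via a random Pruefer sequence.
#'
#' @param m number of labels (>= 2).
#' @return two-column integer matrix of `m - 1` edges (1-based labels).
#' @export
randomTree <- function(m) {
    m <- as.integer(m)
    if (m < 2L) stop("a tree needs at least 2 nodes")
    if (m == 2L) return(matrix(c(1L, 2L), 1L, 2L))
    prufer <- sample.int(m, m - 2L, replace = TRUE)
    degree <- rep(1L, m)
    for (p in prufer) degree[p] <- degree[p] + 1L
    edges <- matrix(0L, m - 1L, 2L)
    ptr <- 1L
    for (i in seq_len(m - 2L)) {
        leaf <- which(degree == 1L)[1L]
        edges[i, ] <- c(min(leaf, prufer[i]), max(leaf, prufer[i]))
        degree[leaf] <- 0L
        degree[prufer[i]] <- degree[prufer[i]] - 1L
        ptr <- ptr + 1L
    }
    rest <- which(degree == 1L)
    edges[m - 1L, ] <- c(min(rest), max(rest))
    edges
}

#' Plant a perfect module map into empty networks
#'
#' Modules become cliques in H*, tree links become complete bipartite
#' subgraphs in G*, decoy cliques are added to H* and decoy bicliques
#' (pairs of fresh node sets) to G*; all planted node sets are pairwise
#' disjoint and occupy the lowest node identifiers.  All remaining pairs
#' are non-edges.
#'
#' @param cfg a [simConfig()] object (the caller controls the RNG state).
#' @return list with logical adjacency matrices `Hstar`, `Gstar`, the node
#'   name vector `nodes`, and `truth` (a [PlantedTruth-class]).
#' @export
plantMap <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    n <- cfg$nNodes
    lo <- cfg$sizeRange[1L]; hi <- cfg$sizeRange[2L]
    m <- cfg$nModules
    digits <- max(4L, nchar(as.character(n)))
    nodes <- sprintf(paste0("n%0", digits, "d"), seq_len(n))
    rsize <- function(k) sample(seq(lo, hi), k, replace = TRUE)
    msize <- rsize(m)
    csize <- rsize(cfg$nCliqueDecoys)
    bsizeA <- rsize(cfg$nBicliqueDecoys)
    bsizeB <- rsize(cfg$nBicliqueDecoys)
    total <- sum(msize, csize, bsizeA, bsizeB)
    if (total > n)
        stop("planted sizes exceed the node count")
    cuts <- cumsum(c(0L, msize, csize, rbind(bsizeA, bsizeB)))
    takeSet <- function(k) seq(cuts[k] + 1L, cuts[k + 1L])
    mods <- lapply(seq_len(m), takeSet)
    cliques <- lapply(seq_len(cfg$nCliqueDecoys), function(i)
        takeSet(m + i))
    bics <- lapply(seq_len(cfg$nBicliqueDecoys), function(i)
        list(sideA = takeSet(m + cfg$nCliqueDecoys + 2L * i - 1L),
             sideB = takeSet(m + cfg$nCliqueDecoys + 2L * i)))
    tree <- randomTree(m)
    Hs <- matrix(FALSE, n, n)
    Gs <- matrix(FALSE, n, n)
    for (s in c(mods, cliques)) {
        Hs[s, s] <- TRUE
    }
    diag(Hs) <- FALSE
    for (e in seq_len(nrow(tree))) {
        a <- mods[[tree[e, 1L]]]; b <- mods[[tree[e, 2L]]]
        Gs[a, b] <- TRUE; Gs[b, a] <- TRUE
    }
    for (bc in bics) {
        Gs[bc$sideA, bc$sideB] <- TRUE
        Gs[bc$sideB, bc$sideA] <- TRUE
    }
    truth <- new("PlantedTruth",
                 modules = lapply(mods, function(s) nodes[s]),
                 treeLinks = tree,
                 cliqueDecoys = lapply(cliques, function(s) nodes[s]),
                 bicliqueDecoys = lapply(bics, function(bc)
                     list(sideA = nodes[bc$sideA],
                          sideB = nodes[bc$sideB])))
    list(Hstar = Hs, Gstar = Gs, nodes = nodes, truth = truth)
}

#' Apply noise to planted adjacency structure
#'
#' Unweighted mode flips every node pair independently with probability
#' `flipP` (planted edges are deleted, background pairs become edges).
#' Weighted mode draws every pair's weight from N(1, sigma) when planted
#' and N(-1, sigma) otherwise.
#'
#' @param planted output of [plantMap()].
#' @param cfg the [simConfig()] used (the caller controls the RNG state).
#' @return list with [Network-class] objects `H` and `G`.
#' @export
applyNoise <- function(planted, cfg) {
    n <- length(planted$nodes)
    ut <- upper.tri(matrix(0, n, n))
    noisy <- function(S) {
        if (cfg$mode == "unweighted") {
            x <- S
            flips <- runif(sum(ut)) < cfg$flipP
            x[ut][flips] <- !x[ut][flips]
            x[lower.tri(x)] <- t(x)[lower.tri(x)]
            adj <- x * 1
        } else {
            mu <- ifelse(S[ut], 1, -1)
            w <- rnorm(length(mu), mean = mu, sd = cfg$sigma)
            adj <- matrix(0, n, n)
            adj[ut] <- w
            adj <- adj + t(adj)
        }
        .networkFromAdj(adj, planted$nodes, cfg$mode)
    }
    H <- noisy(planted$Hstar)
    G <- noisy(planted$Gstar)
    list(H = H, G = G)
}

#' Simulate a matched H/G pair with planted truth
#'
#' Seeds the RNG from `cfg$seed`, plants a perfect module map plus decoys
#' and applies the configured noise.  Identical configurations produce
#' identical output.
#'
#' @param cfg a [simConfig()].
#' @return list with `H`, `G` ([Network-class]) and `truth`
#'   ([PlantedTruth-class]).
#' @export
simulateMap <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed)
    planted <- plantMap(cfg)
    nets <- applyNoise(planted, cfg)
    list(H = nets$H, G = nets$G, truth = planted$truth)
}

#' Write a simulated instance to a directory
#'
#' Emits `H.tsv` and `G.tsv` edge lists (all-pair weight lists in weighted
#' mode), a `truth.tsv` with one row per planted set (type, index,
#' comma-separated members) and `tree.tsv` with the planted link pairs.
#'
#' @param sim output of [simulateMap()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSim <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeNetwork(sim$H, file.path(dir, "H.tsv"))
    writeNetwork(sim$G, file.path(dir, "G.tsv"))
    tr <- sim$truth
    rows <- data.frame(type = character(), index = integer(),
                       members = character())
    addRow <- function(type, idx, members)
        rbind(rows, data.frame(type = type, index = idx,
                               members = paste(members, collapse = ",")))
    for (i in seq_along(tr@modules))
        rows <- addRow("module", i, tr@modules[[i]])
    for (i in seq_along(tr@cliqueDecoys))
        rows <- addRow("clique", i, tr@cliqueDecoys[[i]])
    for (i in seq_along(tr@bicliqueDecoys)) {
        rows <- addRow("bicliqueA", i, tr@bicliqueDecoys[[i]]$sideA)
        rows <- addRow("bicliqueB", i, tr@bicliqueDecoys[[i]]$sideB)
    }
    write.table(rows, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(tr@treeLinks),
                file.path(dir, "tree.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = c("module_i", "module_j"))
    invisible(dir)
}

#' Read back the planted truth written by [writeSim()]
#'
#' @param dir directory holding `truth.tsv` and `tree.tsv`.
#' @return a [PlantedTruth-class].
#' @export
readTruth <- function(dir) {
    rows <- read.table(file.path(dir, "truth.tsv"), sep = "\t",
                       header = TRUE, stringsAsFactors = FALSE)
    tree <- as.matrix(read.table(file.path(dir, "tree.tsv"), sep = "\t",
                                 header = TRUE))
    getType <- function(tp) {
        sub <- rows[rows$type == tp, , drop = FALSE]
        sub <- sub[order(sub$index), , drop = FALSE]
        lapply(strsplit(sub$members, ","), identity)
    }
    ba <- getType("bicliqueA"); bb <- getType("bicliqueB")
    new("PlantedTruth",
        modules = getType("module"),
        treeLinks = matrix(as.integer(tree), ncol = 2L),
        cliqueDecoys = getType("clique"),
        bicliqueDecoys = lapply(seq_along(ba), function(i)
            list(sideA = ba[[i]], sideB = bb[[i]])))
}
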