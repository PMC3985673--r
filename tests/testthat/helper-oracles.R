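## Independent oracles and fixture builders shared across the suite.

## random unweighted network fixture
randomNetwork <- function(n, p, seed, mode = "unweighted") {
    set.seed(seed)
    nodes <- sprintf("v%02d", seq_len(n))
    adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
    ut <- upper.tri(adj)
    if (mode == "unweighted") {
        adj[ut] <- as.numeric(runif(sum(ut)) < p)
    } else {
        adj[ut] <- rnorm(sum(ut))
    }
    adj <- adj + t(adj)
    new("Network", nodes = nodes, mode = mode, adj = adj)
}

## brute-force maximal non-induced bicliques: a pair (a, b) with every
## cross pair an edge is maximal iff b is the full common neighbourhood of
## a and vice versa; enumerate all vertex subsets a and test that directly
bfBicliques <- function(net, minSide = 1L) {
    nm <- nodes(net)
    n <- length(nm)
    A <- slot(net, "adj") > 0
    commonNbrs <- function(s) {
        keep <- rep(TRUE, n)
        for (v in s) keep <- keep & A[v, ]
        unname(which(keep))
    }
    out <- list()
    for (k in seq_len(n)) {
        for (a in combn(n, k, simplify = FALSE)) {
            b <- commonNbrs(a)
            if (length(b) < minSide || length(a) < minSide) next
            if (!identical(commonNbrs(b), a)) next
            if (min(a) > min(b)) next   # each unordered pair once
            out[[length(out) + 1L]] <-
                list(sideA = sort(nm[a]), sideB = sort(nm[b]))
        }
    }
    out
}

## canonical string form of a biclique list, order-independent
bicKey <- function(bics) {
    sort(vapply(bics, function(b) {
        s <- list(b$sideA, b$sideB)
        s <- s[order(vapply(s, paste, character(1), collapse = ","))]
        paste(vapply(s, paste, character(1), collapse = ","),
              collapse = " | ")
    }, character(1)))
}

## brute-force global score by direct pair enumeration
bfGlobalScore <- function(H, G, map) {
    sw <- function(net, u, v) {
        w <- slot(net, "adj")[u, v]
        if (isWeighted(net)) w else if (w > 0) 1 else -1
    }
    mods <- modules(map)
    s <- 0
    for (m in mods) {
        if (length(m) >= 2) {
            pr <- combn(m, 2)
            for (i in seq_len(ncol(pr))) s <- s + sw(H, pr[1, i], pr[2, i])
        }
    }
    lk <- mapLinks(map)
    for (i in seq_len(nrow(lk))) {
        U <- mods[[lk$from[i]]]; V <- mods[[lk$to[i]]]
        for (u in U) for (v in V) s <- s + sw(G, u, v)
    }
    s
}

## exhaustive-enumeration oracle for the per-node hypergeometric test:
## the fraction of |target|-subsets of V \ {x} with at least as many
## edges to x as the observed target
bfHypergeomP <- function(net, x, target) {
    nm <- nodes(net)
    A <- slot(net, "adj") > 0
    others <- setdiff(nm, x)
    k <- sum(A[x, target])
    hits <- 0; tot <- 0
    for (s in combn(others, length(target), simplify = FALSE)) {
        tot <- tot + 1
        if (sum(A[x, s]) >= k) hits <- hits + 1
    }
    hits / tot
}

## Fig 1D-style toy instance: module1 = 3-clique, module2 = 4-clique,
## module3 = 6-clique; G has 8 of 12 cross edges between modules 1 and 2
## and 10 of 24 between modules 2 and 3; four background nodes.
fig1dInstance <- function() {
    m1 <- paste0("a", 1:3)
    m2 <- paste0("b", 1:4)
    m3 <- paste0("c", 1:6)
    bg <- paste0("d", 1:4)
    nodesAll <- c(m1, m2, m3, bg)
    cliqueEdges <- function(s) {
        pr <- combn(s, 2)
        data.frame(node_a = pr[1, ], node_b = pr[2, ])
    }
    H <- Network(rbind(cliqueEdges(m1), cliqueEdges(m2), cliqueEdges(m3)),
                 nodes = nodesAll)
    ## 8 of the 12 pairs m1 x m2 (drop 4), 10 of the 24 pairs m2 x m3
    e12 <- expand.grid(node_a = m1, node_b = m2,
                       stringsAsFactors = FALSE)[1:8, ]
    e23 <- expand.grid(node_a = m2, node_b = m3,
                       stringsAsFactors = FALSE)[1:10, ]
    G <- Network(rbind(e12, e23), nodes = nodesAll)
    list(H = H, G = G, m1 = m1, m2 = m2, m3 = m3, bg = bg)
}
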