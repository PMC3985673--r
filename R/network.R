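## Construction of Network objects and the score arithmetic of the module
## map objective: module internal scores in H, link weights in G, and the
## global score of a map.

#' Build a Network from an edge table
#'
#' @param edges data.frame with columns `node_a`, `node_b` and, in weighted
#'   mode, `weight`.  Duplicate rows for the same unordered pair collapse to
#'   one (the last weight wins, with a warning); self-loops are dropped with
#'   a warning.
#' @param nodes optional character vector fixing the node universe; defaults
#'   to the union of identifiers seen in `edges`.  Nodes never mentioned in
#'   `edges` are isolated (unweighted) or have zero weight to every partner
#'   (weighted).
#' @param mode `"unweighted"` or `"weighted"`.  In unweighted mode a listed
#'   pair is an edge (signed weight +1) and an unlisted pair a non-edge
#'   (signed weight -1); non-edges are never materialised.
#' @return a [Network-class] object.
#' @examples
#' net <- Network(data.frame(node_a = c("a", "b"), node_b = c("b", "c")))
#' signedWeight(net, "a", "b")   # +1
#' signedWeight(net, "a", "c")   # -1
#' @export
Network <- function(edges, nodes = NULL,
                    mode = c("unweighted", "weighted")) {
    mode <- match.arg(mode)
    stopifnot(is.data.frame(edges))
    if (!all(c("node_a", "node_b") %in% names(edges)))
        stop("edge table must have columns 'node_a' and 'node_b'")
    a <- as.character(edges$node_a)
    b <- as.character(edges$node_b)
    if (mode == "weighted") {
        if (!"weight" %in% names(edges))
            stop("weighted mode requires a 'weight' column")
        w <- as.numeric(edges$weight)
        if (anyNA(w)) stop("weights must be numeric and non-missing")
    } else {
        w <- rep(1, length(a))
    }
    if (is.null(nodes)) nodes <- sort(unique(c(a, b)))
    self <- a == b
    if (any(self)) {
        warning(sprintf("dropping %d self-loop(s)", sum(self)))
        a <- a[!self]; b <- b[!self]; w <- w[!self]
    }
    if (!is.null(nodes)) {
        nodes <- as.character(nodes)
        bad <- setdiff(c(a, b), nodes)
        if (length(bad))
            stop("edge endpoints outside the declared node universe: ",
                 paste(head(bad, 5L), collapse = ", "))
    }
    key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
    if (anyDuplicated(key)) {
        warning(sprintf(
            "%d duplicate pair row(s) collapsed (last weight wins)",
            sum(duplicated(key))))
        keep <- !duplicated(key, fromLast = TRUE)
        a <- a[keep]; b <- b[keep]; w <- w[keep]
    }
    n <- length(nodes)
    adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
    ia <- match(a, nodes); ib <- match(b, nodes)
    adj[cbind(ia, ib)] <- w
    adj[cbind(ib, ia)] <- w
    new("Network", nodes = nodes, mode = mode, adj = adj)
}

#' An edgeless Network over a given node set
#'
#' @param nodes character vector of node identifiers.
#' @param mode network mode.
#' @return a [Network-class] with no edges (all weights zero in weighted
#'   mode).
#' @export
emptyNetwork <- function(nodes, mode = c("unweighted", "weighted")) {
    mode <- match.arg(mode)
    nodes <- as.character(nodes)
    n <- length(nodes)
    new("Network", nodes = nodes, mode = mode,
        adj = matrix(0, n, n, dimnames = list(nodes, nodes)))
}

## internal: build a Network directly from a symmetric adjacency matrix
.networkFromAdj <- function(adj, nodes, mode) {
    dimnames(adj) <- list(nodes, nodes)
    diag(adj) <- 0
    new("Network", nodes = nodes, mode = mode, adj = adj)
}

#' Restrict two networks to their shared node universe
#'
#' H and G must be defined on the same node set before a module map can be
#' built; nodes present in only one network are dropped and their count
#' reported.
#'
#' @param H,G [Network-class] objects.
#' @param quiet suppress the message about dropped nodes.
#' @return list with elements `H` and `G` restricted to the intersection.
#' @export
intersectNetworks <- function(H, G, quiet = FALSE) {
    stopifnot(is(H, "Network"), is(G, "Network"))
    common <- intersect(H@nodes, G@nodes)
    if (!length(common)) stop("the networks share no nodes")
    dh <- length(H@nodes) - length(common)
    dg <- length(G@nodes) - length(common)
    if (!quiet && (dh || dg))
        message(sprintf(
            "restricting to %d shared nodes (dropped %d from H, %d from G)",
            length(common), dh, dg))
    common <- sort(common)
    list(H = .subsetNetwork(H, common), G = .subsetNetwork(G, common))
}

.subsetNetwork <- function(net, keep) {
    idx <- match(keep, net@nodes)
    new("Network", nodes = keep, mode = net@mode,
        adj = net@adj[idx, idx, drop = FALSE])
}

.checkNodes <- function(net, ids, what = "node") {
    idx <- match(ids, net@nodes)
    if (anyNA(idx))
        stop(sprintf("unknown %s identifier(s): %s", what,
                     paste(head(ids[is.na(idx)], 5L), collapse = ", ")))
    idx
}

#' Signed weight of a node pair
#'
#' In unweighted mode an edge weighs +1 and a non-edge -1; in weighted mode
#' the stored weight is returned.  `u` and `v` may be vectors of equal
#' length, in which case weights are returned pairwise.
#'
#' @param net a [Network-class].
#' @param u,v node identifiers (`u[i] != v[i]` required).
#' @return numeric vector of signed weights.
#' @export
signedWeight <- function(net, u, v) {
    stopifnot(is(net, "Network"))
    iu <- .checkNodes(net, u)
    iv <- .checkNodes(net, v)
    if (length(iu) != length(iv))
        stop("'u' and 'v' must have the same length")
    if (any(iu == iv)) stop("self-pairs have no signed weight")
    w <- net@adj[cbind(iu, iv)]
    if (identical(net@mode, "unweighted")) ifelse(w > 0, 1, -1) else w
}

## fast internal score primitives on integer index sets
.intScoreIdx <- function(adj, unweighted, idx) {
    k <- length(idx)
    if (k <= 1L) return(0)
    s <- sum(adj[idx, idx]) / 2          # edge count or weight sum
    if (unweighted) 2 * s - k * (k - 1) / 2 else s
}

.linkWIdx <- function(adj, unweighted, iU, iV) {
    s <- sum(adj[iU, iV, drop = FALSE])
    if (unweighted) 2 * s - length(iU) * length(iV) else s
}

#' Module internal score: sum of signed H-weights within a node set
#'
#' @param H a [Network-class].
#' @param S character vector of nodes (a candidate module).
#' @return the sum of [signedWeight()] over all unordered pairs within `S`;
#'   0 when `|S| <= 1`.
#' @examples
#' H <- Network(data.frame(node_a = c("a","a","a","b","b","c"),
#'                         node_b = c("b","c","d","c","d","d")))
#' moduleInternalScore(H, c("a","b","c","d"))  # 4-clique -> 6
#' @export
moduleInternalScore <- function(H, S) {
    stopifnot(is(H, "Network"))
    idx <- .checkNodes(H, unique(S))
    .intScoreIdx(H@adj, !isWeighted(H), idx)
}

#' Link weight: sum of signed G-weights across two disjoint node sets
#'
#' @param G a [Network-class].
#' @param U,V disjoint non-empty character vectors of nodes.
#' @return the sum of [signedWeight()] over all `|U| * |V|` cross pairs.
#' @export
linkWeight <- function(G, U, V) {
    stopifnot(is(G, "Network"))
    if (!length(U) || !length(V)) stop("'U' and 'V' must be non-empty")
    if (length(intersect(U, V)))
        stop("'U' and 'V' must be disjoint")
    iU <- .checkNodes(G, U)
    iV <- .checkNodes(G, V)
    .linkWIdx(G@adj, !isWeighted(G), iU, iV)
}

#' Global score of a module map
#'
#' The global score is the sum of the module internal scores in H plus the
#' sum of the link weights in G over the map's links.
#'
#' @param H,G [Network-class] objects on a shared node universe.
#' @param map a [ModuleMap-class].
#' @return numeric scalar.
#' @export
globalScore <- function(H, G, map) {
    stopifnot(is(map, "ModuleMap"))
    mods <- map@modules
    s <- 0
    for (m in mods) s <- s + moduleInternalScore(H, m)
    lk <- map@links
    if (nrow(lk))
        for (i in seq_len(nrow(lk)))
            s <- s + linkWeight(G, mods[[lk$from[i]]], mods[[lk$to[i]]])
    s
}

#' Assemble a ModuleMap by hand
#'
#' Mostly useful for tests and worked examples; maps produced by the
#' pipeline come from [finalizeMap()].
#'
#' @param modules list of disjoint character vectors.
#' @param links data.frame with columns `from`, `to` and optionally `p`,
#'   `weight` (defaults 0).
#' @param alpha link threshold to record on the object.
#' @return a [ModuleMap-class].
#' @export
moduleMap <- function(modules, links = NULL, alpha = 1) {
    if (is.null(links))
        links <- data.frame(from = integer(), to = integer(),
                            p = numeric(), weight = numeric())
    if (!"p" %in% names(links)) links$p <- 0
    if (!"weight" %in% names(links)) links$weight <- 0
    if (nrow(links)) {
        sw <- links$from > links$to
        tmp <- links$from[sw]
        links$from[sw] <- links$to[sw]
        links$to[sw] <- tmp
    }
    if (length(modules))
        names(modules) <- paste0("M", seq_along(modules))
    new("ModuleMap", modules = modules,
        links = links[, c("from", "to", "p", "weight")], alpha = alpha)
}
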