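#' Network: a signed symmetric relation over a node universe
#'
#' A `Network` holds either an unweighted graph (edges present/absent, with
#' the convention that an edge carries signed weight +1 and a non-edge -1) or
#' a weighted graph in which every node pair carries a real signed weight.
#' Self-pairs are excluded and the relation is symmetric.
#'
#' Internally the relation is stored as a dense symmetric adjacency matrix
#' with a zero diagonal: 0/1 entries in unweighted mode (non-edge signed
#' weights are derived on demand, never materialised), real entries in
#' weighted mode.
#'
#' @slot nodes character vector of unique node identifiers.
#' @slot mode `"unweighted"` or `"weighted"`.
#' @slot adj numeric adjacency matrix with `dimnames` equal to `nodes`.
#'
#' @seealso [Network()], [signedWeight()], [moduleInternalScore()]
#' @export
setClass("Network",
    slots = c(nodes = "character", mode = "character", adj = "matrix"))

setValidity("Network", function(object) {
    msg <- character()
    if (anyDuplicated(object@nodes))
        msg <- c(msg, "node identifiers must be unique")
    if (length(object@mode) != 1L ||
        !object@mode %in% c("unweighted", "weighted"))
        msg <- c(msg, "mode must be 'unweighted' or 'weighted'")
    a <- object@adj
    if (nrow(a) != length(object@nodes) || ncol(a) != length(object@nodes))
        msg <- c(msg, "adjacency dimensions must match the node set")
    else {
        if (!identical(rownames(a), object@nodes) ||
            !identical(colnames(a), object@nodes))
            msg <- c(msg, "adjacency dimnames must equal the node set")
        if (nrow(a) > 0L) {
            if (!isSymmetric(unname(a)))
                msg <- c(msg, "adjacency must be symmetric")
            if (any(diag(a) != 0))
                msg <- c(msg, "self-pairs are not allowed")
            if (identical(object@mode, "unweighted") && !all(a %in% c(0, 1)))
                msg <- c(msg, "unweighted adjacency entries must be 0 or 1")
        }
    }
    if (length(msg)) msg else TRUE
})

#' ModuleMap: disjoint modules plus significant inter-module links
#'
#' @slot modules named list of character vectors (pairwise disjoint node
#'   sets), names `"M1"`, `"M2"`, ...
#' @slot links data.frame with columns `from`, `to` (1-based module indices,
#'   `from < to`), `p` (combined link p-value) and `weight` (sum of signed
#'   G-weights across the pair).
#' @slot alpha numeric, the link acceptance threshold in force when the map
#'   was finalized.
#'
#' @seealso [finalizeMap()], [globalScore()], [writeMap()]
#' @export
setClass("ModuleMap",
    slots = c(modules = "list", links = "data.frame", alpha = "numeric"))

setValidity("ModuleMap", function(object) {
    msg <- character()
    mods <- object@modules
    all_nodes <- unlist(mods, use.names = FALSE)
    if (anyDuplicated(all_nodes))
        msg <- c(msg, "modules must be pairwise disjoint")
    lk <- object@links
    if (!all(c("from", "to", "p", "weight") %in% names(lk)))
        msg <- c(msg, "links must have columns from, to, p, weight")
    else if (nrow(lk)) {
        if (any(lk$from >= lk$to))
            msg <- c(msg, "links must satisfy from < to")
        if (any(lk$from < 1L) || any(lk$to > length(mods)))
            msg <- c(msg, "link indices out of range")
        if (any(lk$p < 0 | lk$p > 1))
            msg <- c(msg, "link p-values must lie in [0, 1]")
        if (length(object@alpha) == 1L && any(lk$p > object@alpha))
            msg <- c(msg, "stored link p-values must not exceed alpha")
    }
    if (length(msg)) msg else TRUE
})

#' InitialSolution: output of an initiator
#'
#' @slot sets list of pairwise disjoint character vectors (seed node sets).
#' @slot seedLinks two-column integer matrix of set indices proposed as
#'   linked pairs (may have zero rows).
#' @export
setClass("InitialSolution",
    slots = c(sets = "list", seedLinks = "matrix"))

setValidity("InitialSolution", function(object) {
    msg <- character()
    if (anyDuplicated(unlist(object@sets, use.names = FALSE)))
        msg <- c(msg, "seed sets must be pairwise disjoint")
    sl <- object@seedLinks
    if (ncol(sl) != 2L)
        msg <- c(msg, "seedLinks must have two columns")
    else if (nrow(sl)) {
        if (any(sl < 1L) || any(sl > length(object@sets)))
            msg <- c(msg, "seedLinks indices out of range")
        if (any(sl[, 1L] == sl[, 2L]))
            msg <- c(msg, "seedLinks must join two distinct sets")
    }
    if (length(msg)) msg else TRUE
})

#' ImproverState: the working solution after an improvement phase
#'
#' Holds the disjoint node sets (including leftover singletons), the accepted
#' links among sets with their p-values and weights, the sticky anti-link
#' pairs, the total number of link tests performed (for Bonferroni
#' accounting), and the global-score trajectory of the improvement loop.
#'
#' @slot sets list of character vectors, pairwise disjoint.
#' @slot links data.frame (`from`, `to`, `p`, `weight`) over set indices.
#' @slot anti two-column integer matrix of anti-linked set index pairs.
#' @slot nTests numeric count of link p-value evaluations performed.
#' @slot trajectory numeric vector of global scores, one per iteration.
#' @export
setClass("ImproverState",
    slots = c(sets = "list", links = "data.frame", anti = "matrix",
              nTests = "numeric", trajectory = "numeric"))

#' LinkTestResult: per-node and combined p-values for one candidate link
#'
#' @slot perNodeP named numeric vector of per-node p-values.
#' @slot combinedP combined p-value (Fisher or Stouffer).
#' @slot method `"hypergeom_fisher"` or `"wilcoxon_stouffer"`.
#' @slot nTests integer, number of per-node tests combined.
#' @export
setClass("LinkTestResult",
    slots = c(perNodeP = "numeric", combinedP = "numeric",
              method = "character", nTests = "integer"))

#' PlantedTruth: ground truth of a simulated module map
#'
#' @slot modules list of character vectors, the planted modules.
#' @slot treeLinks two-column integer matrix, the spanning-tree link pairs
#'   over module indices.
#' @slot cliqueDecoys list of character vectors, decoy cliques planted in H.
#' @slot bicliqueDecoys list of two-element lists (`sideA`, `sideB`), decoy
#'   bicliques planted in G.
#' @export
setClass("PlantedTruth",
    slots = c(modules = "list", treeLinks = "matrix",
              cliqueDecoys = "list", bicliqueDecoys = "list"))

setMethod("show", "Network", function(object) {
    ne <- if (identical(object@mode, "unweighted"))
        sum(object@adj) / 2
    else sum(object@adj[upper.tri(object@adj)] != 0)
    cat(sprintf("Network (%s): %d nodes, %d %s\n", object@mode,
                length(object@nodes), as.integer(ne),
                if (identical(object@mode, "unweighted")) "edges"
                else "non-zero pair weights"))
    invisible(object)
})

setMethod("show", "ModuleMap", function(object) {
    sizes <- lengths(object@modules)
    cat(sprintf("ModuleMap: %d modules (%d nodes), %d links\n",
                length(object@modules), sum(sizes), nrow(object@links)))
    if (length(sizes))
        cat(sprintf("  module sizes: %s\n",
                    paste(sizes, collapse = " ")))
    invisible(object)
})

setMethod("show", "ImproverState", function(object) {
    cat(sprintf(
        "ImproverState: %d sets (%d of size >= 2), %d links, %d tests\n",
        length(object@sets), sum(lengths(object@sets) >= 2L),
        nrow(object@links), as.integer(object@nTests)))
    invisible(object)
})
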