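## Evaluation of recovered maps: pair-based Jaccard against planted truth,
## held-out link-versus-nonlink testing, and random-set link fold-change.

#' Pair-based Jaccard between two module collections
#'
#' Both collections are reduced to their sets of unordered node pairs
#' co-assigned to a common module; the Jaccard coefficient of the two pair
#' sets is returned.  This variant is insensitive to module labels,
#' ordering and module-count mismatch.  When both pair sets are empty the
#' coefficient is 1.
#'
#' @param found,truth lists of character vectors; sets within each list
#'   must be disjoint.
#' @return numeric in `[0, 1]`.
#' @export
pairJaccard <- function(found, truth) {
    if (anyDuplicated(unlist(found, use.names = FALSE)))
        stop("'found' modules overlap")
    if (anyDuplicated(unlist(truth, use.names = FALSE)))
        stop("'truth' modules overlap")
    nPairs <- function(sets) sum(choose(lengths(sets), 2))
    pf <- nPairs(found); pt <- nPairs(truth)
    if (pf == 0 && pt == 0) return(1)
    inter <- 0
    for (f in found)
        for (t in truth)
            inter <- inter + choose(length(intersect(f, t)), 2)
    inter / (pf + pt - inter)
}

#' Recovery statistics of a map against planted truth
#'
#' @param map a [ModuleMap-class].
#' @param truth a [PlantedTruth-class] or list of character vectors.
#' @return list with `pairJaccard`, `nModulesFound`, `nGenesCovered`,
#'   `maxModuleSize` and `nLinks`.
#' @export
recoveryReport <- function(map, truth) {
    stopifnot(is(map, "ModuleMap"))
    tmods <- if (is(truth, "PlantedTruth")) truth@modules else truth
    mods <- map@modules
    list(pairJaccard = pairJaccard(mods, tmods),
         nModulesFound = length(mods),
         nGenesCovered = sum(lengths(mods)),
         maxModuleSize = if (length(mods)) max(lengths(mods)) else 0L,
         nLinks = nrow(map@links))
}

#' Write a recovery report as a flat key-value TSV
#'
#' @param report output of [recoveryReport()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
    df <- data.frame(key = names(report),
                     value = unlist(report, use.names = FALSE))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Held-out link-versus-nonlink test
#'
#' For every unordered module pair of the map, computes the mean signed
#' cross weight in a held-out network, and compares linked pairs against
#' unlinked pairs with a one-sided rank-sum test (linked heavier).
#'
#' @param map a [ModuleMap-class] with at least two modules, at least one
#'   link and at least one non-link pair.
#' @param Gtest a [Network-class] containing all map nodes.
#' @return the one-sided rank-sum p-value.
#' @export
linkVsNonlinkTest <- function(map, Gtest) {
    stopifnot(is(map, "ModuleMap"), is(Gtest, "Network"))
    mods <- map@modules
    if (length(mods) < 2L) stop("need at least two modules")
    idx <- lapply(mods, .checkNodes, net = Gtest)
    uw <- !isWeighted(Gtest)
    pairs <- combn(length(mods), 2L)
    lkKey <- paste(map@links$from, map@links$to)
    dc <- numeric(ncol(pairs))
    isLink <- logical(ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
        i <- pairs[1L, k]; j <- pairs[2L, k]
        dc[k] <- .linkWIdx(Gtest@adj, uw, idx[[i]], idx[[j]]) /
            (length(idx[[i]]) * length(idx[[j]]))
        isLink[k] <- paste(i, j) %in% lkKey
    }
    if (!any(isLink)) stop("map has no links")
    if (all(isLink)) stop("map has no non-link pair")
    .rankSumP(dc[isLink], dc[!isLink])
}

#' Link fold-change against random same-size set pairs
#'
#' For every link (U, V) of the map, the link statistic (mean positive
#' cross weight, with negative-signed pairs contributing zero, floored at
#' `eps`) is compared with the maximum of the same statistic over
#' `repeats` random disjoint node-set pairs of sizes `(|U|, |V|)` drawn
#' from the network.
#'
#' @param map a [ModuleMap-class].
#' @param G a [Network-class].
#' @param repeats number of random draws (>= 1).
#' @param eps floor for the statistic, guarding division by zero.
#' @return numeric vector of fold changes, one per link.
#' @export
linkFoldChange <- function(map, G, repeats = 200L, eps = 1e-6) {
    stopifnot(is(map, "ModuleMap"), is(G, "Network"), repeats >= 1L)
    mods <- map@modules
    lk <- map@links
    n <- length(G@nodes)
    uw <- !isWeighted(G)
    stat <- function(iU, iV) {
        w <- G@adj[iU, iV, drop = FALSE]
        if (uw) w <- 2 * w - 1
        max(mean(pmax(w, 0)), eps)
    }
    out <- numeric(nrow(lk))
    for (k in seq_len(nrow(lk))) {
        iU <- .checkNodes(G, mods[[lk$from[k]]])
        iV <- .checkNodes(G, mods[[lk$to[k]]])
        if (length(iU) + length(iV) > n)
            stop("network too small for disjoint random sets")
        real <- stat(iU, iV)
        best <- eps
        for (r in seq_len(repeats)) {
            draw <- sample.int(n, length(iU) + length(iV))
            best <- max(best, stat(draw[seq_along(iU)],
                                   draw[-seq_along(iU)]))
        }
        out[k] <- real / best
    }
    out
}
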