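## Maximal non-induced biclique enumeration (wrapper around the compiled
## Close-by-One enumerator) with deterministic canonical ordering.

#' Enumerate maximal bicliques of an unweighted network
#'
#' A biclique is a pair of disjoint node sets with every cross pair an
#' edge; it is maximal when no node can be added to either side.  Weighted
#' networks are thresholded at weight > 0 first.  Enumeration is exhaustive
#' up to the result and work caps; when a cap is hit the returned list is
#' truncated and flagged.
#'
#' @param net a [Network-class].
#' @param minSide minimum size of each side (default 3, which bounds output
#'   on noisy graphs).
#' @param maxResults cap on the number of bicliques returned (default 1e6).
#' @param maxVisits cap on the number of enumeration-tree nodes explored.
#' @return list of bicliques, each a list with character vectors `sideA`
#'   and `sideB` (`sideA` lexicographically smaller); ordered
#'   lexicographically by sorted `sideA` then `sideB`.  Attributes
#'   `truncated` (logical) and `visited` (work count) report enumeration
#'   status; truncation also emits a warning.
#' @export
enumerateMaximalBicliques <- function(net, minSide = 3L,
                                      maxResults = 1e6,
                                      maxVisits = 5e7) {
    stopifnot(is(net, "Network"), minSide >= 1L)
    raw <- .enumBicliquesIdx(net@adj > 0, minSide, maxResults, maxVisits)
    nm <- net@nodes
    out <- lapply(seq_along(raw$sideA), function(i) {
        a <- sort(nm[raw$sideA[[i]]])
        b <- sort(nm[raw$sideB[[i]]])
        if (.lexLess(b, a)) list(sideA = b, sideB = a)
        else list(sideA = a, sideB = b)
    })
    if (length(out)) {
        keyA <- vapply(out, function(x)
            paste(x$sideA, collapse = "\r"), character(1))
        keyB <- vapply(out, function(x)
            paste(x$sideB, collapse = "\r"), character(1))
        out <- out[order(keyA, keyB, method = "radix")]
    }
    attr(out, "truncated") <- raw$truncated
    attr(out, "visited") <- raw$visited
    if (raw$truncated)
        warning("biclique enumeration truncated at the configured cap")
    out
}

## integer-index enumeration on a logical adjacency matrix
.enumBicliquesIdx <- function(A, minSide, maxResults, maxVisits) {
    storage.mode(A) <- "logical"
    .enumerate_bicliques_cpp(A, as.integer(minSide),
                             as.numeric(maxResults),
                             as.numeric(maxVisits))
}

## TRUE if character vector a sorts strictly before b
.lexLess <- function(a, b) {
    k <- min(length(a), length(b))
    for (i in seq_len(k)) {
        if (a[i] < b[i]) return(TRUE)
        if (a[i] > b[i]) return(FALSE)
    }
    length(a) < length(b)
}
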