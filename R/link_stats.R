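## Link significance machinery: per-node tests of a node's connectivity
## towards a candidate partner set, combination of per-node p-values, and
## the link / anti-link classification used by the improvers.

.P_FLOOR <- 1e-300

#' Per-node hypergeometric link test
#'
#' Tests whether node `x` has more edges into `target` (in the unweighted
#' network, or the positively-thresholded version of a weighted one) than
#' expected for its degree.  The population is all nodes except `x` itself
#' (members of `x`'s own set are not excluded), the successes are the
#' neighbours of `x`, and the sample is `target`; the upper tail
#' `P(X >= k)` is returned, so a node with no edge into `target` gets 1.
#'
#' @param Gp an unweighted [Network-class] (weighted networks are
#'   thresholded at weight > 0).
#' @param x a node identifier, member of `own`.
#' @param own the node set `x` belongs to (disjoint from `target`).
#' @param target the candidate partner set.
#' @return the one-sided hypergeometric p-value.
#' @export
nodeLinkPvalueHypergeom <- function(Gp, x, own, target) {
    stopifnot(is(Gp, "Network"))
    if (x %in% target) stop("'x' must not belong to 'target'")
    if (!x %in% own) stop("'x' must belong to 'own'")
    if (length(intersect(own, target)))
        stop("'own' and 'target' must be disjoint")
    ix <- .checkNodes(Gp, x)
    it <- .checkNodes(Gp, target)
    A <- Gp@adj > 0
    k <- sum(A[ix, it])
    K <- sum(A[ix, ])
    N <- length(Gp@nodes) - 1L
    .hgP(k, K, length(it), N)
}

## upper-tail P(X >= k); X ~ Hypergeom(N population, K successes, n draws)
.hgP <- function(k, K, n, N) {
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Per-node Wilcoxon rank-sum link test
#'
#' Compares the weights from `x` into `target` with the weights from `x`
#' into all remaining nodes (one-sided: target weights stochastically
#' greater).  Exact when both sides are small and untied; mid-ranks with a
#' normal approximation otherwise; a completely tied comparison carries no
#' evidence and returns 1.
#'
#' @param G a weighted [Network-class].
#' @param x a node identifier.
#' @param target non-empty node set not containing `x`.
#' @return the one-sided rank-sum p-value.
#' @export
nodeLinkPvalueWilcoxon <- function(G, x, target) {
    stopifnot(is(G, "Network"))
    if (x %in% target) stop("'x' must not belong to 'target'")
    ix <- .checkNodes(G, x)
    it <- .checkNodes(G, target)
    ib <- setdiff(seq_along(G@nodes), c(ix, it))
    if (!length(ib)) stop("background set is empty")
    if (!length(it)) stop("'target' must be non-empty")
    w <- G@adj[ix, ]
    if (!isWeighted(G)) w <- ifelse(w > 0, 1, -1)
    .rankSumP(w[it], w[ib])
}

## one-sided rank-sum p (greater); exact via pwilcox when untied and small
.rankSumP <- function(tgt, bg) {
    m <- length(tgt); n <- length(bg)
    all_v <- c(tgt, bg)
    if (max(all_v) == min(all_v)) return(1)
    r <- rank(all_v)
    U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
    ties <- anyDuplicated(all_v) > 0L
    if (!ties && m < 20L && n < 20L)
        return(pwilcox(U - 1, m, n, lower.tail = FALSE))
    N <- m + n
    tie_tab <- table(all_v)
    tiecor <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- m * n / 12 * ((N + 1) - tiecor)
    if (sigma2 <= 0) return(1)
    z <- (U - m * n / 2 - 0.5) / sqrt(sigma2)
    pnorm(z, lower.tail = FALSE)
}

#' Combine p-values by Fisher's method
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return the upper chi-square tail with `2 * length(pvals)` degrees of
#'   freedom at the statistic `-2 * sum(log(pvals))`.
#' @examples
#' combineFisher(c(0.1, 0.1))  # ~0.0562
#' @export
combineFisher <- function(pvals) {
    if (!length(pvals)) stop("no p-values to combine")
    if (any(pvals <= 0) || any(pvals > 1))
        stop("p-values must lie in (0, 1]")
    pchisq(-2 * sum(log(pvals)), df = 2 * length(pvals),
           lower.tail = FALSE)
}

#' Combine p-values by Stouffer's method
#'
#' @param pvals numeric vector of p-values in (0, 1).
#' @return the normal upper tail at `sum(z_i) / sqrt(k)` where `z_i` is the
#'   standard-normal upper quantile of `pvals[i]`.
#' @examples
#' combineStouffer(c(0.05, 0.05))  # ~0.0100
#' @export
combineStouffer <- function(pvals) {
    if (!length(pvals)) stop("no p-values to combine")
    if (any(pvals <= 0) || any(pvals >= 1))
        stop("p-values must lie in (0, 1)")
    z <- qnorm(pvals, lower.tail = FALSE)
    pnorm(sum(z) / sqrt(length(z)), lower.tail = FALSE)
}

#' Combined link p-value for a candidate module pair
#'
#' Per-node p-values are computed for every node of `U` against `V` and
#' every node of `V` against `U`, then combined: hypergeometric node tests
#' with Fisher's method (the default, computed on the unweighted version of
#' G), or Wilcoxon node tests with Stouffer's method (for weighted G).
#'
#' @param G a [Network-class].
#' @param U,V disjoint non-empty node sets.
#' @param method combination scheme.
#' @param counter optional environment with a numeric field `n`; when
#'   supplied, `n` is incremented by one for every combined link test
#'   evaluated (Bonferroni accounting).
#' @return a [LinkTestResult-class].
#' @export
linkPvalue <- function(G, U, V,
                       method = c("hypergeom_fisher", "wilcoxon_stouffer"),
                       counter = NULL) {
    method <- match.arg(method)
    stopifnot(is(G, "Network"))
    if (!length(U) || !length(V)) stop("'U' and 'V' must be non-empty")
    if (length(intersect(U, V))) stop("'U' and 'V' must be disjoint")
    iU <- .checkNodes(G, U)
    iV <- .checkNodes(G, V)
    if (method == "hypergeom_fisher") {
        A <- G@adj > 0
        pp <- .linkPHypergeomIdx(A, iU, iV)
    } else {
        if (!isWeighted(G))
            warning("Wilcoxon link test on an unweighted network; ",
                    "ranks are degenerate")
        pp <- .linkPWilcoxonIdx(G@adj, !isWeighted(G), iU, iV)
    }
    if (!is.null(counter)) counter$n <- counter$n + 1
    new("LinkTestResult",
        perNodeP = stats::setNames(pp$perNode,
                                   c(G@nodes[iU], G@nodes[iV])),
        combinedP = pp$combined, method = method,
        nTests = length(pp$perNode))
}

## vectorised hypergeometric per-node p-values + Fisher combination,
## operating on a logical adjacency matrix and integer index sets
.linkPHypergeomIdx <- function(A, iU, iV, deg = NULL) {
    if (is.null(deg)) deg <- rowSums(A)
    N <- nrow(A) - 1L
    kU <- if (length(iV) == 1L) A[iU, iV] else rowSums(A[iU, iV, drop = FALSE])
    kV <- if (length(iU) == 1L) A[iV, iU] else rowSums(A[iV, iU, drop = FALSE])
    pU <- .hgP(kU, deg[iU], length(iV), N)
    pV <- .hgP(kV, deg[iV], length(iU), N)
    per <- pmax(c(pU, pV), .P_FLOOR)
    list(perNode = per, combined = combineFisher(per))
}

.linkPWilcoxonIdx <- function(adj, unweighted, iU, iV) {
    n <- nrow(adj)
    per <- numeric(length(iU) + length(iV))
    k <- 1L
    for (x in iU) {
        w <- adj[x, ]
        if (unweighted) w <- ifelse(w > 0, 1, -1)
        bg <- setdiff(seq_len(n), c(x, iV))
        per[k] <- .rankSumP(w[iV], w[bg]); k <- k + 1L
    }
    for (x in iV) {
        w <- adj[x, ]
        if (unweighted) w <- ifelse(w > 0, 1, -1)
        bg <- setdiff(seq_len(n), c(x, iU))
        per[k] <- .rankSumP(w[iU], w[bg]); k <- k + 1L
    }
    per <- pmin(pmax(per, .P_FLOOR), 1 - 1e-16)
    list(perNode = per, combined = combineStouffer(per))
}

#' Classify a link p-value against the acceptance thresholds
#'
#' A pair with `p <= alpha` is linked; a pair with `p >= beta` is
#' anti-linked (and is never re-tested by the improvers); anything between
#' is unknown.
#'
#' @param p combined link p-value.
#' @param alpha link acceptance threshold (default 0.005).
#' @param beta anti-link threshold (default 0.2); must exceed `alpha`.
#' @return list with elements `status` (`"linked"`, `"anti_linked"` or
#'   `"unknown"`) and `p`.
#' @export
classifyLink <- function(p, alpha = 0.005, beta = 0.2) {
    if (!(alpha > 0 && alpha < beta && beta <= 1))
        stop("need 0 < alpha < beta <= 1")
    status <- if (p <= alpha) "linked"
              else if (p >= beta) "anti_linked"
              else "unknown"
    list(status = status, p = p)
}
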