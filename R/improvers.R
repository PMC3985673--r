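## Improvers: the local improver (node addition / link merging) and the
## global improver (greedy merges maximising the global score subject to
## link significance, with sticky anti-link caching and optional batched
## merges), plus map finalization.

.EPS_GAIN <- 1e-9

.newCounter <- function() {
    e <- new.env(parent = emptyenv())
    e$n <- 0
    e
}

## ---- internal improver environment -------------------------------------

.buildImpEnv <- function(H, G, init, alpha, beta, method, widen = FALSE) {
    stopifnot(is(H, "Network"), is(G, "Network"),
              identical(H@nodes, G@nodes), is(init, "InitialSolution"))
    if (!(alpha > 0 && alpha < beta && beta <= 1))
        stop("need 0 < alpha < beta <= 1")
    env <- new.env(parent = emptyenv())
    env$nm <- H@nodes
    env$n <- length(env$nm)
    env$adjH <- H@adj; env$uwH <- !isWeighted(H)
    env$adjG <- G@adj; env$uwG <- !isWeighted(G)
    env$Agp <- G@adj > 0
    env$degGp <- rowSums(env$Agp)
    env$alpha <- alpha; env$beta <- beta; env$method <- method
    env$widen <- widen
    sets0 <- lapply(init@sets, function(s) sort(.checkNodes(H, s)))
    covered <- unlist(sets0, use.names = FALSE)
    if (anyDuplicated(covered)) stop("initial sets are not disjoint")
    singles <- setdiff(seq_len(env$n), covered)
    K <- length(sets0) + length(singles)
    maxIds <- 2L * K + 10L
    env$maxIds <- maxIds
    env$sets <- vector("list", maxIds)
    env$sets[seq_along(sets0)] <- sets0
    for (i in seq_along(singles))
        env$sets[[length(sets0) + i]] <- singles[i]
    env$singleOf <- integer(env$n)
    env$singleOf[singles] <- length(sets0) + seq_along(singles)
    env$live <- c(rep(TRUE, K), rep(FALSE, maxIds - K))
    env$size <- integer(maxIds)
    env$size[seq_len(K)] <- lengths(env$sets[seq_len(K)])
    env$status <- matrix(0L, maxIds, maxIds)
    env$pmat <- matrix(NA_real_, maxIds, maxIds)
    env$lwmat <- matrix(NA_real_, maxIds, maxIds)
    env$parents <- vector("list", maxIds)
    env$nTests <- 0
    env$nextId <- K + 1L
    env$traj <- numeric()
    ## memo of speculative merge tests: sets behind the ids are immutable,
    ## so p((A u B), Z) is deterministic per id triple
    env$memo <- new.env(hash = TRUE, parent = emptyenv())
    env
}

.lpPairIdxEnv <- function(env, iU, iV) {
    env$nTests <- env$nTests + 1
    if (env$method == "hypergeom_fisher")
        .linkPHypergeomIdx(env$Agp, iU, iV, env$degGp)$combined
    else
        .linkPWilcoxonIdx(env$adjG, env$uwG, iU, iV)$combined
}

.lwPairIdxEnv <- function(env, iU, iV)
    .linkWIdx(env$adjG, env$uwG, iU, iV)

.statusOf <- function(env, p) {
    if (p <= env$alpha) 1L else if (p >= env$beta) 2L else 3L
}

## test a live pair once; statuses are sticky and never recomputed
.testLivePair <- function(env, a, b) {
    if (env$status[a, b] != 0L) return(invisible())
    p <- .lpPairIdxEnv(env, env$sets[[a]], env$sets[[b]])
    st <- .statusOf(env, p)
    lw <- .lwPairIdxEnv(env, env$sets[[a]], env$sets[[b]])
    env$status[a, b] <- env$status[b, a] <- st
    env$pmat[a, b] <- env$pmat[b, a] <- p
    env$lwmat[a, b] <- env$lwmat[b, a] <- lw
    invisible()
}

.moduleIds <- function(env) which(env$live & env$size >= 2L)

.scoreEnv <- function(env) {
    mods <- .moduleIds(env)
    s <- 0
    for (m in mods) s <- s + .intScoreIdx(env$adjH, env$uwH, env$sets[[m]])
    if (length(mods) >= 2L) {
        st <- env$status[mods, mods, drop = FALSE]
        lw <- env$lwmat[mods, mods, drop = FALSE]
        linked <- st == 1L & upper.tri(st)
        if (any(linked)) s <- s + sum(lw[linked])
    }
    s
}

## anti-link inheritance through merge ancestry: a merged set is anti-linked
## to Y whenever either parent is
.antiStar <- function(env, i, j) {
    st <- env$status[i, j]
    if (st == 2L) return(TRUE)
    if (st != 0L) return(FALSE)
    pj <- env$parents[[j]]
    if (!is.null(pj))
        for (p in pj) if (.antiStar(env, i, p)) return(TRUE)
    pi <- env$parents[[i]]
    if (!is.null(pi))
        for (p in pi) if (.antiStar(env, p, j)) return(TRUE)
    FALSE
}

## full merge-gain evaluation for a live pair (a, b): the change in global
## score if they merge, with the merged module's links determined by fresh
## tests against every other live module not anti-link-inherited
.mergeGainIdxEnv <- function(env, a, b) {
    A <- env$sets[[a]]; B <- env$sets[[b]]
    Y <- sort(c(A, B))
    whGain <- .linkWIdx(env$adjH, env$uwH, A, B)
    mods <- setdiff(.moduleIds(env), c(a, b))
    k <- length(mods)
    zs <- integer(k); st <- integer(k)
    pv <- rep(NA_real_, k); lw <- rep(NA_real_, k)
    newLinkSum <- 0
    for (i in seq_len(k)) {
        z <- mods[i]; zs[i] <- z
        if (env$status[a, z] == 2L || env$status[b, z] == 2L) {
            st[i] <- 2L
        } else {
            key <- paste(min(a, b), max(a, b), z)
            hit <- env$memo[[key]]
            if (is.null(hit)) {
                p <- .lpPairIdxEnv(env, Y, env$sets[[z]])
                lwi <- .lwPairIdxEnv(env, Y, env$sets[[z]])
                env$memo[[key]] <- c(p, lwi)
            } else {
                p <- hit[1L]; lwi <- hit[2L]
            }
            pv[i] <- p
            st[i] <- .statusOf(env, p)
            lw[i] <- lwi
            if (st[i] == 1L) newLinkSum <- newLinkSum + lw[i]
        }
    }
    cur <- 0
    for (z in mods) {
        if (env$status[a, z] == 1L) cur <- cur + env$lwmat[a, z]
        if (env$status[b, z] == 1L) cur <- cur + env$lwmat[b, z]
    }
    if (env$status[a, b] == 1L) cur <- cur + env$lwmat[a, b]
    list(a = a, b = b, gain = whGain + newLinkSum - cur,
         zs = zs, st = st, p = pv, lw = lw)
}

.executeMerge <- function(env, prop) {
    id <- env$nextId
    if (id > env$maxIds) stop("internal: merge id capacity exceeded")
    env$nextId <- id + 1L
    a <- prop$a; b <- prop$b
    env$sets[[id]] <- sort(c(env$sets[[a]], env$sets[[b]]))
    env$size[id] <- length(env$sets[[id]])
    env$live[id] <- TRUE
    env$live[a] <- env$live[b] <- FALSE
    env$parents[[id]] <- c(a, b)
    for (i in seq_along(prop$zs)) {
        z <- prop$zs[i]
        env$status[id, z] <- env$status[z, id] <- prop$st[i]
        env$pmat[id, z] <- env$pmat[z, id] <- prop$p[i]
        env$lwmat[id, z] <- env$lwmat[z, id] <- prop$lw[i]
    }
    id
}

## resolve untested statuses among live modules (new pairs created by a
## batch of merges): anti-inheritance first, fresh test otherwise
.resolveNewPairs <- function(env) {
    mods <- .moduleIds(env)
    if (length(mods) < 2L) return(invisible())
    for (i in seq_along(mods)[-1L]) {
        for (j in seq_len(i - 1L)) {
            a <- mods[i]; b <- mods[j]
            if (env$status[a, b] != 0L) next
            if (.antiStar(env, a, b)) {
                env$status[a, b] <- env$status[b, a] <- 2L
            } else {
                .testLivePair(env, a, b)
            }
        }
    }
    invisible()
}

## proposal generation: module-module pairs (with at least one positive H
## or G' cross pair unless widened) plus module-singleton pairs surviving
## an exact upper bound on the attainable gain
.collectProposals <- function(env) {
    mods <- .moduleIds(env)
    props <- list()
    if (length(mods) >= 2L) {
        cmb <- combn(mods, 2L)
        for (c1 in seq_len(ncol(cmb))) {
            a <- cmb[1L, c1]; b <- cmb[2L, c1]
            A <- env$sets[[a]]; B <- env$sets[[b]]
            if (!env$widen &&
                !any(env$adjH[A, B] > 0) && !any(env$Agp[A, B]))
                next
            pr <- .mergeGainIdxEnv(env, a, b)
            if (pr$gain > .EPS_GAIN)
                props[[length(props) + 1L]] <- pr
        }
    }
    singleIds <- which(env$live & env$size == 1L)
    if (length(singleIds) && length(mods)) {
        sx <- vapply(env$sets[singleIds], `[`, integer(1), 1L)
        for (a in mods) {
            A <- env$sets[[a]]
            hasH <- if (length(A) == 1L) env$adjH[A, sx] > 0
                    else colSums(env$adjH[A, sx, drop = FALSE] > 0) > 0
            hasG <- if (length(A) == 1L) env$Agp[A, sx]
                    else colSums(env$Agp[A, sx, drop = FALSE]) > 0
            cand <- if (env$widen) rep(TRUE, length(sx)) else (hasH | hasG)
            if (!any(cand)) next
            ub <- .sumToSetIdx(env$adjH, env$uwH, A)[sx]
            for (z in setdiff(mods, a)) {
                if (env$status[a, z] == 2L) next
                lwAZ <- env$lwmat[a, z]
                dV <- .sumToSetIdx(env$adjG, env$uwG, env$sets[[z]])[sx]
                ub <- ub + pmax(lwAZ + dV, 0) -
                    (env$status[a, z] == 1L) * lwAZ
            }
            for (ii in which(cand & ub > .EPS_GAIN)) {
                pr <- .mergeGainIdxEnv(env, a, singleIds[ii])
                if (pr$gain > .EPS_GAIN)
                    props[[length(props) + 1L]] <- pr
            }
        }
    }
    props
}

.envToState <- function(env) {
    liveIds <- which(env$live)
    setsChar <- lapply(env$sets[liveIds], function(ix) env$nm[ix])
    mods <- liveIds[env$size[liveIds] >= 2L]
    from <- integer(); to <- integer(); p <- numeric(); w <- numeric()
    af <- integer(); at <- integer()
    if (length(mods) >= 2L) {
        cmb <- combn(mods, 2L)
        for (c1 in seq_len(ncol(cmb))) {
            a <- cmb[1L, c1]; b <- cmb[2L, c1]
            st <- env$status[a, b]
            ia <- match(a, liveIds); ib <- match(b, liveIds)
            if (st == 1L) {
                from <- c(from, ia); to <- c(to, ib)
                p <- c(p, env$pmat[a, b]); w <- c(w, env$lwmat[a, b])
            } else if (st == 2L) {
                af <- c(af, ia); at <- c(at, ib)
            }
        }
    }
    new("ImproverState", sets = setsChar,
        links = data.frame(from = from, to = to, p = p, weight = w),
        anti = cbind(af, at, deparse.level = 0),
        nTests = env$nTests, trajectory = env$traj)
}

## ---- global improver ----------------------------------------------------

#' Global improver: greedy score-maximising merges with link tests
#'
#' Starting from the initiator's sets plus all uncovered nodes as
#' singletons, repeatedly evaluates merges of two modules or of a module
#' and a single node.  A merge's gain is the exact change in global score:
#' the signed H-weight between the parts plus the link weights of the
#' merged module's significant links minus those of the parts' current
#' links, where the merged module's links are determined by fresh combined
#' p-value tests against every other module.  Pairs whose p-value ever
#' reaches `beta` become anti-linked and are never re-tested; a merged set
#' inherits anti-links from either parent without testing.  With
#' `batch = TRUE` each iteration accepts a maximal set of non-interacting
#' positive-gain merges in descending gain order; otherwise one merge per
#' iteration.  The loop stops when no merge has positive gain.
#'
#' @param H,G [Network-class] objects on the same node universe.
#' @param init an [InitialSolution-class].
#' @param alpha link acceptance threshold (default 0.005).
#' @param beta anti-link threshold (default 0.2).
#' @param minSize minimum module size; enforced at [finalizeMap()], kept
#'   here for pipeline configuration.
#' @param batch accept multiple disjoint merges per iteration.
#' @param method link test, see [linkPvalue()].
#' @param widenCandidates consider all set pairs as merge candidates, not
#'   only pairs joined by a positive H or G' pair (useful for weighted
#'   inputs where negative-signed pairs can still yield positive gains).
#' @return an [ImproverState-class]; its `trajectory` slot records the
#'   global score after every iteration (non-decreasing).
#' @export
globalImprove <- function(H, G, init, alpha = 0.005, beta = 0.2,
                          minSize = 5L, batch = TRUE,
                          method = c("hypergeom_fisher",
                                     "wilcoxon_stouffer"),
                          widenCandidates = FALSE) {
    method <- match.arg(method)
    env <- .buildImpEnv(H, G, init, alpha, beta, method,
                        widen = widenCandidates)
    mods <- .moduleIds(env)
    if (length(mods) >= 2L) {
        cmb <- combn(mods, 2L)
        for (c1 in seq_len(ncol(cmb)))
            .testLivePair(env, cmb[1L, c1], cmb[2L, c1])
    }
    env$traj <- .scoreEnv(env)
    maxIter <- sum(env$live)
    for (iter in seq_len(maxIter)) {
        props <- .collectProposals(env)
        if (!length(props)) break
        gains <- vapply(props, `[[`, numeric(1), "gain")
        keys <- vapply(props, function(p)
            paste(env$nm[sort(c(env$sets[[p$a]], env$sets[[p$b]]))],
                  collapse = "\r"), character(1))
        ord <- order(-gains, keys, method = "radix")
        accMembers <- integer()
        accBlock <- integer()
        deferred <- integer()
        executed <- FALSE
        for (oi in ord) {
            pr <- props[[oi]]
            block <- c(pr$a, pr$b, pr$zs[pr$st == 1L])
            curLinked <- pr$zs[env$status[pr$a, pr$zs] == 1L |
                               env$status[pr$b, pr$zs] == 1L]
            block <- unique(c(block, curLinked))
            if (any(c(pr$a, pr$b) %in% accBlock) ||
                any(block %in% accMembers) ||
                any(c(pr$a, pr$b) %in% deferred)) {
                ## a member whose better-ranked proposal was foreclosed
                ## waits for the next iteration, where gains are fresh
                deferred <- c(deferred, pr$a, pr$b)
                next
            }
            .executeMerge(env, pr)
            executed <- TRUE
            accMembers <- c(accMembers, pr$a, pr$b)
            accBlock <- c(accBlock, block)
            if (!batch) break
        }
        if (!executed) break
        .resolveNewPairs(env)
        env$traj <- c(env$traj, .scoreEnv(env))
    }
    .envToState(env)
}

#' Exact merge gain for one candidate pair
#'
#' Evaluates what [globalImprove()] would gain by merging two sets of an
#' [ImproverState-class]: the signed H-weight between them plus the link
#' weights of the merged module's accepted links minus those of the two
#' parts' current links.  Pairs anti-linked to either part are inherited
#' as anti-linked without testing.
#'
#' @param H,G [Network-class] objects.
#' @param state an [ImproverState-class].
#' @param A,B indices of two live sets in `state`.
#' @param alpha,beta,method as in [globalImprove()].
#' @return list with `gain`, the proposed `links` of the merged module
#'   (data.frame `partner`, `p`, `weight`), and `nTestsPerformed`.
#' @export
mergeGain <- function(H, G, state, A, B, alpha = 0.005, beta = 0.2,
                      method = c("hypergeom_fisher", "wilcoxon_stouffer")) {
    method <- match.arg(method)
    stopifnot(is(state, "ImproverState"))
    ns <- length(state@sets)
    if (!(A %in% seq_len(ns)) || !(B %in% seq_len(ns)) || A == B)
        stop("'A' and 'B' must index distinct sets of the state")
    env <- .stateToEnv(H, G, state, alpha, beta, method)
    n0 <- env$nTests
    pr <- .mergeGainIdxEnv(env, A, B)
    tested <- pr$st != 2L
    list(gain = pr$gain,
         links = data.frame(partner = pr$zs[pr$st == 1L],
                            p = pr$p[pr$st == 1L],
                            weight = pr$lw[pr$st == 1L]),
         nTestsPerformed = env$nTests - n0)
}

## rebuild an improver environment from a frozen state (ids = set positions)
.stateToEnv <- function(H, G, state, alpha, beta, method) {
    init <- .newInitialSolution(state@sets)
    env <- .buildImpEnv(H, G, init, alpha, beta, method)
    lk <- state@links
    for (i in seq_len(nrow(lk))) {
        a <- lk$from[i]; b <- lk$to[i]
        env$status[a, b] <- env$status[b, a] <- 1L
        env$pmat[a, b] <- env$pmat[b, a] <- lk$p[i]
        lw <- .lwPairIdxEnv(env, env$sets[[a]], env$sets[[b]])
        env$lwmat[a, b] <- env$lwmat[b, a] <- lw
    }
    an <- state@anti
    for (i in seq_len(nrow(an))) {
        a <- an[i, 1L]; b <- an[i, 2L]
        env$status[a, b] <- env$status[b, a] <- 2L
    }
    ## remaining module pairs are treated as tested-unknown so that gain
    ## evaluation does not silently link them from stale information
    mods <- .moduleIds(env)
    if (length(mods) >= 2L) {
        cmb <- combn(mods, 2L)
        for (c1 in seq_len(ncol(cmb))) {
            a <- cmb[1L, c1]; b <- cmb[2L, c1]
            if (env$status[a, b] == 0L) .testLivePair(env, a, b)
        }
    }
    env$nTests <- state@nTests + (env$nTests)
    env
}

## ---- local improver -----------------------------------------------------

#' Local improver: extend links by node additions and link merging
#'
#' Operates link by link on the initiator's seed links: (a) adds to either
#' side the single unassigned node with the largest positive summed
#' contribution (signed H-weight to its side plus signed G-weight to the
#' opposite side); (b) merges the two non-shared sets of two links sharing
#' a module when the combined pair score (internal H score of the union
#' plus its link weight to the shared module) improves on the two
#' separate pairs.  Alternates to a fixpoint.  By construction this
#' improver cannot create modules absent from the initial solution.
#'
#' @param H,G [Network-class] objects.
#' @param init an [InitialSolution-class] with seed links.
#' @param method link test used to annotate the surviving links with
#'   p-values at the end.
#' @param maxPasses safety cap on alternation rounds.
#' @return an [ImproverState-class] (uncovered nodes become singletons).
#' @export
localImprove <- function(H, G, init,
                         method = c("hypergeom_fisher",
                                    "wilcoxon_stouffer"),
                         maxPasses = 100L) {
    method <- match.arg(method)
    stopifnot(is(H, "Network"), is(G, "Network"),
              identical(H@nodes, G@nodes), is(init, "InitialSolution"))
    nm <- H@nodes
    n <- length(nm)
    uwH <- !isWeighted(H); uwG <- !isWeighted(G)
    sets <- lapply(init@sets, function(s) sort(.checkNodes(H, s)))
    links <- init@seedLinks
    if (!nrow(links)) {
        warning("initial solution has no seed links; nothing to improve")
        return(.localState(H, G, sets, links, method))
    }
    pool <- setdiff(seq_len(n), unlist(sets, use.names = FALSE))
    for (pass in seq_len(maxPasses)) {
        changed <- FALSE
        ## (a) single-node additions, best-first per link
        for (li in seq_len(nrow(links))) {
            repeat {
                if (!length(pool)) break
                a <- links[li, 1L]; b <- links[li, 2L]
                A <- sets[[a]]; B <- sets[[b]]
                gA <- .sumToSetIdx(H@adj, uwH, A)[pool] +
                      .sumToSetIdx(G@adj, uwG, B)[pool]
                gB <- .sumToSetIdx(H@adj, uwH, B)[pool] +
                      .sumToSetIdx(G@adj, uwG, A)[pool]
                bestA <- max(gA); bestB <- max(gB)
                if (max(bestA, bestB) <= .EPS_GAIN) break
                if (bestA >= bestB) {
                    k <- which(gA == bestA)
                    k <- k[order(nm[pool[k]])[1L]]
                    sets[[a]] <- sort(c(sets[[a]], pool[k]))
                } else {
                    k <- which(gB == bestB)
                    k <- k[order(nm[pool[k]])[1L]]
                    sets[[b]] <- sort(c(sets[[b]], pool[k]))
                }
                pool <- pool[-k]
                changed <- TRUE
            }
        }
        ## (b) merge two links sharing a set
        merged <- TRUE
        while (merged && nrow(links) >= 2L) {
            merged <- FALSE
            for (i in seq_len(nrow(links) - 1L)) {
                for (j in seq(i + 1L, nrow(links))) {
                    sh <- intersect(links[i, ], links[j, ])
                    if (length(sh) != 1L) next
                    s <- sh
                    o1 <- setdiff(links[i, ], s)
                    o2 <- setdiff(links[j, ], s)
                    if (o1 == o2) next
                    un <- sort(c(sets[[o1]], sets[[o2]]))
                    d <- .intScoreIdx(H@adj, uwH, un) +
                        .linkWIdx(G@adj, uwG, sets[[s]], un) -
                        .intScoreIdx(H@adj, uwH, sets[[o1]]) -
                        .intScoreIdx(H@adj, uwH, sets[[o2]]) -
                        .linkWIdx(G@adj, uwG, sets[[s]], sets[[o1]]) -
                        .linkWIdx(G@adj, uwG, sets[[s]], sets[[o2]])
                    if (d <= .EPS_GAIN) next
                    sets[[o1]] <- un
                    sets[[o2]] <- integer()
                    links[links == o2] <- o1
                    links <- links[links[, 1L] != links[, 2L], ,
                                   drop = FALSE]
                    key <- paste(pmin(links[, 1L], links[, 2L]),
                                 pmax(links[, 1L], links[, 2L]))
                    links <- links[!duplicated(key), , drop = FALSE]
                    merged <- TRUE
                    changed <- TRUE
                    break
                }
                if (merged) break
            }
        }
        if (!changed) break
    }
    ## drop emptied sets, remap link indices
    keep <- which(lengths(sets) > 0L)
    remap <- match(seq_along(sets), keep)
    links <- cbind(remap[links[, 1L]], remap[links[, 2L]],
                   deparse.level = 0)
    sets <- sets[keep]
    .localState(H, G, sets, links, method)
}

.localState <- function(H, G, sets, links, method) {
    nm <- H@nodes
    pool <- setdiff(seq_along(nm), unlist(sets, use.names = FALSE))
    allSets <- c(sets, as.list(pool))
    counter <- .newCounter()
    from <- integer(); to <- integer(); p <- numeric(); w <- numeric()
    for (i in seq_len(nrow(links))) {
        a <- links[i, 1L]; b <- links[i, 2L]
        res <- linkPvalue(G, nm[allSets[[a]]], nm[allSets[[b]]],
                          method = method, counter = counter)
        from <- c(from, min(a, b)); to <- c(to, max(a, b))
        p <- c(p, res@combinedP)
        w <- c(w, .linkWIdx(G@adj, !isWeighted(G),
                            allSets[[a]], allSets[[b]]))
    }
    new("ImproverState",
        sets = lapply(allSets, function(ix) nm[ix]),
        links = data.frame(from = from, to = to, p = p, weight = w),
        anti = matrix(integer(), 0L, 2L),
        nTests = counter$n, trajectory = numeric())
}

## state for improver = "none": seed links are tested, nothing else moves
.initToState <- function(H, G, init, method = "hypergeom_fisher") {
    sets <- lapply(init@sets, function(s) sort(.checkNodes(H, s)))
    .localState(H, G, sets, init@seedLinks, method)
}

## ---- finalization -------------------------------------------------------

#' Finalize an improver state into a module map
#'
#' Drops sets smaller than `minSize`, accepts links among the survivors at
#' `p <= alpha` (or `p <= 0.05 / nTests` under Bonferroni correction over
#' all link tests performed during improvement), and then drops modules
#' left without any link, repeating until stable, so that every module of
#' the returned map participates in at least one link.
#'
#' @param state an [ImproverState-class].
#' @param H,G [Network-class] objects (used to recompute link weights).
#' @param minSize minimum module size.
#' @param alpha link acceptance threshold when `correction = "none"`.
#' @param correction `"none"` or `"bonferroni"`.
#' @return a [ModuleMap-class]; empty (with a warning) when nothing
#'   survives.
#' @export
finalizeMap <- function(state, H, G, minSize = 5L, alpha = 0.005,
                        correction = c("none", "bonferroni")) {
    correction <- match.arg(correction)
    stopifnot(is(state, "ImproverState"))
    thr <- if (correction == "bonferroni")
        0.05 / max(state@nTests, 1) else alpha
    sizes <- lengths(state@sets)
    keep <- which(sizes >= minSize)
    lk <- state@links
    lk <- lk[lk$from %in% keep & lk$to %in% keep & lk$p <= thr, ,
             drop = FALSE]
    repeat {
        linked <- keep %in% c(lk$from, lk$to)
        if (all(linked)) break
        keep <- keep[linked]
        lk <- lk[lk$from %in% keep & lk$to %in% keep, , drop = FALSE]
        if (!length(keep)) break
    }
    if (!length(keep)) {
        warning("no module survived finalization; returning an empty map")
        return(moduleMap(list(), alpha = thr))
    }
    mods <- state@sets[keep]
    ord <- order(vapply(mods, `[`, character(1), 1L))
    mods <- mods[ord]
    remap <- match(keep[ord], keep)           # position of old in new
    newIdx <- integer(max(keep))
    newIdx[keep[ord]] <- seq_along(keep)
    from <- newIdx[lk$from]; to <- newIdx[lk$to]
    links <- data.frame(from = pmin(from, to), to = pmax(from, to),
                        p = lk$p, weight = lk$weight)
    links <- links[order(links$from, links$to), , drop = FALSE]
    rownames(links) <- NULL
    names(mods) <- paste0("M", seq_along(mods))
    new("ModuleMap", modules = mods, links = links, alpha = thr)
}
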