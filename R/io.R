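## File formats, run configuration and the build pipeline entry point.

#' Read a network from a tab-separated edge list
#'
#' Columns are `node_a`, `node_b` and, in weighted mode, `weight`.  A
#' header row is detected when the first row's fields match those column
#' names (case-insensitively).  Duplicate pair rows collapse to one (last
#' weight wins, with a warning) and self-loops are dropped with a warning.
#'
#' @param path input file.
#' @param mode `"unweighted"` or `"weighted"`.
#' @param nodes optional fixed node universe.
#' @return a [Network-class].
#' @export
readEdgeList <- function(path, mode = c("unweighted", "weighted"),
                         nodes = NULL) {
    mode <- match.arg(mode)
    first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    hasHeader <- length(first) >= 2L &&
        all(tolower(first[1:2]) == c("node_a", "node_b"))
    df <- tryCatch(
        read.table(path, sep = "\t", header = hasHeader,
                   stringsAsFactors = FALSE, quote = "",
                   comment.char = ""),
        error = function(e)
            stop("malformed edge list '", path, "': ",
                 conditionMessage(e)))
    if (ncol(df) < 2L)
        stop("edge list must have at least two columns")
    names(df)[1:2] <- c("node_a", "node_b")
    if (mode == "weighted") {
        if (ncol(df) < 3L)
            stop("weighted mode requires a third (weight) column")
        names(df)[3L] <- "weight"
        if (!is.numeric(df$weight))
            stop("weight column is not numeric in '", path, "'")
    }
    Network(df, nodes = nodes, mode = mode)
}

#' Write a network as a tab-separated edge list
#'
#' Unweighted networks list their edges; weighted networks list every
#' pair with a non-zero weight together with the weight.
#'
#' @param net a [Network-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path) {
    A <- net@adj
    nm <- net@nodes
    sel <- upper.tri(A) & (A != 0)
    idx <- which(sel, arr.ind = TRUE)
    lo <- pmin(nm[idx[, 1L]], nm[idx[, 2L]])
    hi <- pmax(nm[idx[, 1L]], nm[idx[, 2L]])
    ord <- order(lo, hi, method = "radix")
    if (isWeighted(net)) {
        df <- data.frame(node_a = lo, node_b = hi, weight = A[idx])
        df <- df[ord, , drop = FALSE]
    } else {
        df <- data.frame(node_a = lo, node_b = hi)[ord, , drop = FALSE]
    }
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Export a module map for downstream analysis and Cytoscape
#'
#' Writes `modules.tsv` (node, module id), `links.tsv` (module pair,
#' p-value, link weight), `map.sif` (module-level simple-interaction
#' format) and `map.graphml` (module-level GraphML with size attributes).
#' The TSVs round-trip losslessly through [readMap()].
#'
#' @param map a [ModuleMap-class].
#' @param outDir output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
writeMap <- function(map, outDir) {
    stopifnot(is(map, "ModuleMap"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    mods <- map@modules
    nodeDf <- data.frame(
        node = unlist(mods, use.names = FALSE),
        module_id = rep(seq_along(mods), lengths(mods)))
    if (nrow(nodeDf))
        nodeDf <- nodeDf[order(nodeDf$module_id, nodeDf$node), ,
                         drop = FALSE]
    write.table(nodeDf, file.path(outDir, "modules.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    lk <- map@links
    linkDf <- data.frame(module_i = lk$from, module_j = lk$to,
                         p_value = lk$p, link_weight = lk$weight)
    write.table(linkDf, file.path(outDir, "links.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sif <- if (nrow(lk))
        sprintf("M%d\tlink\tM%d", lk$from, lk$to) else character()
    unlinked <- setdiff(seq_along(mods), c(lk$from, lk$to))
    sif <- c(sif, sprintf("M%d", unlinked))
    writeLines(sif, file.path(outDir, "map.sif"))
    .writeGraphml(map, file.path(outDir, "map.graphml"))
    invisible(outDir)
}

.writeGraphml <- function(map, path) {
    doc <- xml2::xml_new_root(
        "graphml",
        xmlns = "http://graphml.graphdrawing.org/xmlns")
    key1 <- xml2::xml_add_child(doc, "key", id = "d0", `for` = "node",
                                attr.name = "size", attr.type = "int")
    key2 <- xml2::xml_add_child(doc, "key", id = "d1", `for` = "node",
                                attr.name = "members",
                                attr.type = "string")
    key3 <- xml2::xml_add_child(doc, "key", id = "d2", `for` = "edge",
                                attr.name = "p_value",
                                attr.type = "double")
    g <- xml2::xml_add_child(doc, "graph", id = "modulemap",
                             edgedefault = "undirected")
    mods <- map@modules
    for (i in seq_along(mods)) {
        nd <- xml2::xml_add_child(g, "node", id = sprintf("M%d", i))
        d <- xml2::xml_add_child(nd, "data", key = "d0")
        xml2::xml_text(d) <- as.character(length(mods[[i]]))
        d2 <- xml2::xml_add_child(nd, "data", key = "d1")
        xml2::xml_text(d2) <- paste(mods[[i]], collapse = ",")
    }
    lk <- map@links
    for (k in seq_len(nrow(lk))) {
        ed <- xml2::xml_add_child(g, "edge",
                                  source = sprintf("M%d", lk$from[k]),
                                  target = sprintf("M%d", lk$to[k]))
        d <- xml2::xml_add_child(ed, "data", key = "d2")
        xml2::xml_text(d) <- format(lk$p[k], digits = 15)
    }
    xml2::write_xml(doc, path)
    invisible(path)
}

#' Read a module map written by [writeMap()]
#'
#' @param dir directory holding `modules.tsv` and `links.tsv`.
#' @param alpha threshold to record on the object (defaults to the
#'   largest stored link p-value, or 1).
#' @return a [ModuleMap-class].
#' @export
readMap <- function(dir, alpha = NULL) {
    nodeDf <- read.table(file.path(dir, "modules.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE)
    linkDf <- read.table(file.path(dir, "links.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE)
    mods <- if (nrow(nodeDf))
        lapply(split(nodeDf$node, nodeDf$module_id), sort) else list()
    mods <- unname(mods)
    if (is.null(alpha))
        alpha <- if (nrow(linkDf)) max(linkDf$p_value) else 1
    moduleMap(mods,
              data.frame(from = linkDf$module_i, to = linkDf$module_j,
                         p = linkDf$p_value, weight = linkDf$link_weight),
              alpha = alpha)
}

#' Build-run configuration
#'
#' Defaults follow the package's standard profile (called "modmap"): the
#' maximal-biclique initiator with cleaning, the global improver with the
#' hypergeometric/Fisher link test at `alpha = 0.005`, `beta = 0.2`, and
#' batched merges.
#'
#' @param initiator one of `"mbc-dicer"`, `"dicer-k"`, `"hclust"`,
#'   `"greedy"`.
#' @param improver one of `"global"`, `"local"`, `"none"`.
#' @param alpha,beta link and anti-link thresholds (`alpha < beta`).
#' @param minModuleSize minimum final module size (also the initiator
#'   seed size, and `k` for `"dicer-k"`).
#' @param correction `"none"` or `"bonferroni"` link correction at
#'   finalization.
#' @param batchMerges accept multiple disjoint merges per global-improver
#'   iteration.
#' @param method link test; `NULL` selects hypergeometric/Fisher (the
#'   fast default for both modes).
#' @param maxBicliques,maxVisits enumeration caps for `"mbc-dicer"`.
#' @param seed integer seed for any randomised step.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(initiator = c("mbc-dicer", "dicer-k", "hclust",
                                    "greedy"),
                      improver = c("global", "local", "none"),
                      alpha = 0.005, beta = 0.2, minModuleSize = 5L,
                      correction = c("none", "bonferroni"),
                      batchMerges = TRUE, method = NULL,
                      maxBicliques = 1e6, maxVisits = 5e7, seed = 1L) {
    initiator <- match.arg(initiator)
    improver <- match.arg(improver)
    correction <- match.arg(correction)
    if (!(alpha > 0 && alpha < beta && beta <= 1))
        stop("need 0 < alpha < beta <= 1")
    if (minModuleSize < 2L) stop("minModuleSize must be >= 2")
    if (is.null(method)) method <- "hypergeom_fisher"
    structure(list(initiator = initiator, improver = improver,
                   alpha = alpha, beta = beta,
                   minModuleSize = as.integer(minModuleSize),
                   correction = correction, batchMerges = batchMerges,
                   method = method, maxBicliques = maxBicliques,
                   maxVisits = maxVisits, seed = as.integer(seed)),
              class = "RunConfig")
}

#' Run the full module-map pipeline
#'
#' Restricts H and G to their shared node universe, runs the configured
#' initiator and improver, finalizes the map, and reports solution
#' statistics and the improvement log.  Deterministic given the
#' configuration seed.
#'
#' @param H,G [Network-class] objects (or paths to edge lists, read in
#'   the configured mode).
#' @param cfg a [runConfig()].
#' @param weighted when `H`/`G` are paths: read them as weighted.
#' @return list with `map` ([ModuleMap-class]), `state`
#'   ([ImproverState-class]), `stats` (module/link counts) and `log`
#'   (score trajectory, iteration and test counts).
#' @export
runBuild <- function(H, G, cfg = runConfig(), weighted = FALSE) {
    stopifnot(inherits(cfg, "RunConfig"))
    mode <- if (weighted) "weighted" else "unweighted"
    if (is.character(H)) H <- readEdgeList(H, mode)
    if (is.character(G)) G <- readEdgeList(G, mode)
    nets <- intersectNetworks(H, G)
    H <- nets$H; G <- nets$G
    set.seed(cfg$seed)
    init <- switch(cfg$initiator,
        "mbc-dicer" = mbcDicerInit(H, G, minSize = cfg$minModuleSize,
                                   maxResults = cfg$maxBicliques,
                                   maxVisits = cfg$maxVisits),
        "dicer-k" = dicerKInit(H, G, k = cfg$minModuleSize),
        "hclust" = hclustInit(H, minSize = cfg$minModuleSize),
        "greedy" = greedyInit(H, minSize = cfg$minModuleSize))
    state <- switch(cfg$improver,
        "global" = globalImprove(H, G, init, alpha = cfg$alpha,
                                 beta = cfg$beta,
                                 minSize = cfg$minModuleSize,
                                 batch = cfg$batchMerges,
                                 method = cfg$method),
        "local" = localImprove(H, G, init, method = cfg$method),
        "none" = .initToState(H, G, init, method = cfg$method))
    map <- finalizeMap(state, H, G, minSize = cfg$minModuleSize,
                       alpha = cfg$alpha, correction = cfg$correction)
    mods <- map@modules
    list(map = map, state = state,
         stats = list(nModules = length(mods),
                      nGenesCovered = sum(lengths(mods)),
                      maxModuleSize = if (length(mods))
                          max(lengths(mods)) else 0L,
                      nLinks = nrow(map@links)),
         log = list(scoreTrajectory = state@trajectory,
                    nIterations = max(length(state@trajectory) - 1L, 0L),
                    nTests = state@nTests))
}
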