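## Classification of genetic interactions from paired untreated/treated
## screens into treatment-specific positive and stable positive classes.

#' Classify differential genetic interactions
#'
#' A gene pair is a damage-specific positive interaction when its S-score
#' is negative untreated, exceeds 0.5 under treatment, and the p-value for
#' differential interaction is below 0.01; it is a stable positive
#' interaction when the S-score exceeds 1.5 in both conditions.  All
#' comparisons are strict, so boundary values fall to `"other"`.  The two
#' classes are mutually exclusive (an S-score cannot be both negative and
#' above 1.5 untreated).  Records whose damage-specific call would hinge
#' on a missing differential p-value are classified `"other"` with a
#' warning.
#'
#' @param gi data.frame with columns `gene_a`, `gene_b`, `s_untreated`,
#'   `s_treated`, `p_diff` (`p_diff` may be `NA`).
#' @return factor with levels `damage_specific_positive`,
#'   `stable_positive`, `other`, one per row.
#' @export
classifyDifferentialGi <- function(gi) {
    req <- c("gene_a", "gene_b", "s_untreated", "s_treated", "p_diff")
    if (!all(req %in% names(gi)))
        stop("need columns: ", paste(req, collapse = ", "))
    if (any(gi$gene_a == gi$gene_b))
        stop("self-pairs are not valid genetic interactions")
    su <- gi$s_untreated; st <- gi$s_treated; pd <- gi$p_diff
    sCond <- su < 0 & st > 0.5
    damage <- sCond & !is.na(pd) & pd < 0.01
    undecid <- sCond & is.na(pd)
    if (any(undecid))
        warning(sprintf(
            "%d record(s) meet the S-score conditions but lack the %s",
            sum(undecid),
            "differential p-value; classified as 'other'"))
    stable <- su > 1.5 & st > 1.5
    cls <- rep("other", nrow(gi))
    cls[stable] <- "stable_positive"
    cls[damage] <- "damage_specific_positive"
    factor(cls, levels = c("damage_specific_positive",
                           "stable_positive", "other"))
}

#' Read a genetic-interaction screen table
#'
#' Expects a 5-column TSV (`gene_a`, `gene_b`, `s_untreated`, `s_treated`,
#' `p_diff`); `p_diff` may be the string `NA`.
#'
#' @param path input file.
#' @return data.frame.
#' @export
readGiTable <- function(path) {
    gi <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE, na.strings = "NA")
    gi$gene_a <- as.character(gi$gene_a)
    gi$gene_b <- as.character(gi$gene_b)
    gi
}

#' Write classified GI edge lists
#'
#' Splits a classified table into `damage_specific.tsv` and
#' `stable_positive.tsv` edge lists directly loadable as a G network.
#' Identical unordered pairs are deduplicated within each class.
#'
#' @param gi data.frame as accepted by [classifyDifferentialGi()].
#' @param dir output directory (created if needed).
#' @return named list of the written paths, invisibly.
#' @export
writeGiNetworks <- function(gi, dir) {
    cls <- classifyDifferentialGi(gi)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    emit <- function(mask, fname) {
        sub <- gi[mask, c("gene_a", "gene_b"), drop = FALSE]
        lo <- pmin(sub$gene_a, sub$gene_b)
        hi <- pmax(sub$gene_a, sub$gene_b)
        df <- unique(data.frame(node_a = lo, node_b = hi))
        df <- df[order(df$node_a, df$node_b), , drop = FALSE]
        path <- file.path(dir, fname)
        write.table(df, path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        path
    }
    invisible(list(
        damage_specific = emit(cls == "damage_specific_positive",
                               "damage_specific.tsv"),
        stable_positive = emit(cls == "stable_positive",
                               "stable_positive.tsv")))
}
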