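# Per-locus filters: the initial coverage/length screen and threshold-based
# selection on diagnostic metrics.

#' Filter loci by taxon coverage and alignment length
#'
#' A locus is kept when the fraction of the study's taxa with at least one
#' non-gap character reaches `min_coverage` *and* its alignment length meets
#' the category minimum (`min_len_cds` for CDS, `min_len_igs` for IGS and
#' OTHER loci).
#'
#' @param loci Non-empty list of [locus_alignment()] objects.
#' @param n_taxa_total Total number of taxa in the study.
#' @param min_coverage Minimum taxon coverage fraction (default 0.55).
#' @param min_len_cds Minimum CDS alignment length in bp (default 100).
#' @param min_len_igs Minimum IGS alignment length in bp (default 50).
#' @return List with `kept` (locus list) and `report` (one row per input
#'   locus: coverage, length, kept flag, rejection reason).
#' @export
filter_loci <- function(loci, n_taxa_total, min_coverage = 0.55,
                        min_len_cds = 100L, min_len_igs = 50L) {
  if (length(loci) == 0L) stop("empty locus list")
  n_present <- vapply(loci, function(l) sum(rowSums(l$mat != "-") > 0L), 0L)
  if (n_taxa_total < max(n_present))
    stop("n_taxa_total smaller than the number of taxa present in a locus")
  coverage <- n_present / n_taxa_total
  len <- vapply(loci, locus_length, 0L)
  category <- vapply(loci, function(l) l$category, "")
  min_len <- ifelse(category == "CDS", min_len_cds, min_len_igs)
  cov_ok <- coverage >= min_coverage
  len_ok <- len >= min_len
  keep <- cov_ok & len_ok
  reason <- rep("", length(loci))
  reason[!cov_ok] <- "coverage"
  reason[cov_ok & !len_ok] <- "length"
  reason[!cov_ok & !len_ok] <- "coverage+length"
  report <- data.frame(
    locus_id = vapply(loci, function(l) l$locus_id, ""),
    category = category, n_taxa = n_present, coverage = coverage,
    length = len, kept = keep, reason = reason, stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(kept = loci[keep], report = report)
}

#' Select loci by a diagnostic threshold
#'
#' The long-branch filter removes loci whose LB heterogeneity exceeds the
#' threshold; the slope, R-squared and support filters remove loci whose
#' value falls below it.  Values exactly at the threshold are always kept.
#'
#' @param records Data frame with column `locus_id` and the metric columns
#'   `lb_heterogeneity`, `slope`, `r2`, `mean_support` (as available).
#' @param metric One of `"lb"`, `"slope"`, `"r2"`, `"support"`.
#' @param threshold Numeric cutoff.
#' @param direction `"remove_above"` or `"remove_below"`; defaults to the
#'   metric's conventional direction.
#' @return List with `kept` and `removed` locus_id vectors.
#' @export
select_loci_by_threshold <- function(records, metric = c("lb", "slope", "r2", "support"),
                                     threshold,
                                     direction = NULL) {
  metric <- match.arg(metric)
  col <- switch(metric, lb = "lb_heterogeneity", slope = "slope",
                r2 = "r2", support = "mean_support")
  if (!col %in% names(records))
    stop("records lack metric column '", col, "'")
  x <- records[[col]]
  if (anyNA(x)) stop("metric '", metric, "' missing for some loci")
  if (is.null(direction))
    direction <- if (metric == "lb") "remove_above" else "remove_below"
  direction <- match.arg(direction, c("remove_above", "remove_below"))
  rm <- if (direction == "remove_above") x > threshold else x < threshold
  list(kept = records$locus_id[!rm], removed = records$locus_id[rm])
}
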