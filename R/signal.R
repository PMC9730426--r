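# Gene-wise phylogenetic signal among candidate topologies: GLS (gene-wise
# sums of site log-likelihoods), delta-GLS between topologies, supported-
# topology proportions, and 3-sigma outlier bounds on the mean delta-GLS.

GLS_TIE_TOL <- 1e-9

#' Gene-wise log-likelihood signal records
#'
#' Sums each topology's per-site log-likelihoods (SLS) over every
#' partition, yielding the gene-wise score GLS and the pairwise differences
#' delta-GLS.  Each locus supports the topology with the highest GLS; exact
#' ties (within 1e-9) are recorded as `"ambiguous"`.  `mean_delta` is the
#' mean of the pairwise differences oriented in label order
#' (T1-T2, T1-T3, T2-T3 for three topologies).
#'
#' @param tables Named list of `site_lik_table` objects (one per topology),
#'   all computed on the same matrix.
#' @param partitions Partition data frame (`locus_id`, `start`, `end`) of
#'   that matrix.
#' @return Data frame of class `signal_table`: `locus_id`, one `gls_<T>`
#'   column per topology, one `delta_<Ta>_<Tb>` column per ordered pair,
#'   `supported`, `mean_delta`.
#' @export
gene_wise_gls <- function(tables, partitions) {
  stopifnot(is.list(tables), length(tables) >= 2L)
  labels <- names(tables)
  if (is.null(labels)) labels <- vapply(tables, function(t) t$topology_id, "")
  names(tables) <- labels
  L <- length(tables[[1]]$sls)
  for (t in tables)
    if (length(t$sls) != L)
      stop("site-likelihood tables have differing lengths")
  if (max(partitions$end) != L)
    stop("partition map does not match table length (", max(partitions$end),
         " vs ", L, ")")
  np <- nrow(partitions)
  gls <- matrix(NA_real_, nrow = np, ncol = length(labels),
                dimnames = list(partitions$locus_id, labels))
  for (k in seq_along(labels)) {
    sls <- tables[[k]]$sls
    for (i in seq_len(np))
      gls[i, k] <- sum(sls[(partitions$start[i] + 1L):partitions$end[i]])
  }
  out <- data.frame(locus_id = partitions$locus_id, stringsAsFactors = FALSE)
  for (k in seq_along(labels)) out[[paste0("gls_", labels[k])]] <- gls[, k]
  pair_cols <- list()
  nlab <- length(labels)
  for (i in seq_len(nlab - 1)) for (j in (i + 1):nlab) {
    nm <- paste0("delta_", labels[i], "_", labels[j])
    out[[nm]] <- gls[, i] - gls[, j]
    pair_cols[[nm]] <- TRUE
  }
  supported <- character(np)
  for (r in seq_len(np)) {
    g <- gls[r, ]
    best <- max(g)
    winners <- labels[g >= best - GLS_TIE_TOL]
    supported[r] <- if (length(winners) == 1L) winners else "ambiguous"
  }
  out$supported <- supported
  out$mean_delta <- rowMeans(out[, names(pair_cols), drop = FALSE])
  class(out) <- c("signal_table", "data.frame")
  out
}

#' Proportion of loci supporting each topology
#'
#' @param records A `signal_table` (or data frame with a `supported`
#'   column).
#' @param labels Topology labels; default: all non-ambiguous values seen.
#' @return Named numeric vector of percentages (one entry per topology plus
#'   `"ambiguous"`), summing to 100 up to rounding.
#' @export
support_proportions <- function(records, labels = NULL) {
  if (nrow(records) == 0L) stop("empty signal table")
  sup <- records$supported
  if (is.null(labels))
    labels <- sort(setdiff(unique(sup), "ambiguous"))
  out <- vapply(c(labels, "ambiguous"),
                function(l) 100 * mean(sup == l), 0)
  out
}

#' Three-sigma outlier bounds
#'
#' Bounds in the style of a Gaussian outer fence: `upper = min(max(x),
#' mu + 3 sigma)`, `lower = max(min(x), mu - 3 sigma)` with the sample mean
#' and standard deviation.  A value is flagged when it exceeds `mu + 3
#' sigma` or falls below `mu - 3 sigma`; the min/max capping affects only
#' the reported bounds.
#'
#' @param values Numeric vector (n >= 3), e.g. per-locus mean delta-GLS.
#' @return Object of class `outlier_bounds`: `mean`, `sd`, `lower`,
#'   `upper`, logical `flags`.
#' @export
outlier_bounds <- function(values) {
  if (length(values) < 3L) stop("need at least 3 values")
  if (any(!is.finite(values))) stop("values must be finite")
  mu <- mean(values)
  sigma <- stats::sd(values)
  if (sigma == 0) {
    warning("zero standard deviation; no outliers flagged")
    flags <- rep(FALSE, length(values))
  } else {
    flags <- values > mu + 3 * sigma | values < mu - 3 * sigma
  }
  structure(list(mean = mu, sd = sigma,
                 lower = max(min(values), mu - 3 * sigma),
                 upper = min(max(values), mu + 3 * sigma),
                 flags = flags),
            class = "outlier_bounds")
}

#' @export
print.outlier_bounds <- function(x, ...) {
  cat("<outlier_bounds> mean", format(x$mean), "sd", format(x$sd),
      "bounds [", format(x$lower), ",", format(x$upper), "]",
      sum(x$flags), "flagged\n")
  invisible(x)
}

#' Outlier flags for a signal table
#'
#' With `on = "any_pair"` (default) every pairwise delta-GLS column gets its
#' own three-sigma bounds and a locus is flagged when any of its pairwise
#' values falls outside; this keeps conflict loci visible whichever pair of
#' topologies they separate.  (The signed mean of the three oriented
#' pairwise deltas telescopes to `(2/3)(GLS_T1 - GLS_T3)` and is blind to
#' the middle topology, so it is offered only as the explicit
#' `on = "mean_delta"` variant.)
#'
#' Flagging is sequential: after a pass flags loci, the bounds are
#' recomputed on the remaining loci and the pass repeats until no new locus
#' is flagged.  A cluster of similar outliers inflates the first-pass
#' standard deviation enough to mask all but the most extreme member (three
#' equal outliers among thirty can never exceed three sigma in one pass);
#' peeling recovers the rest one pass at a time.
#'
#' @param records A `signal_table`.
#' @param on `"any_pair"` or `"mean_delta"`.
#' @return Logical flag vector (one per record); per-axis final-pass
#'   [outlier_bounds()] objects in attribute `bounds`.
#' @export
signal_outlier_flags <- function(records, on = c("any_pair", "mean_delta")) {
  on <- match.arg(on)
  cols <- if (on == "mean_delta") "mean_delta"
          else grep("^delta_", names(records), value = TRUE)
  if (length(cols) == 0L) stop("no delta columns in signal table")
  n <- nrow(records)
  flags <- rep(FALSE, n)
  bounds <- NULL
  repeat {
    active <- which(!flags)
    if (length(active) < 3L) break
    bounds <- lapply(cols, function(cl)
      suppressWarnings(outlier_bounds(records[[cl]][active])))
    names(bounds) <- cols
    new <- Reduce(`|`, lapply(bounds, function(b) b$flags))
    if (!any(new)) break
    flags[active[new]] <- TRUE
  }
  attr(flags, "bounds") <- bounds
  flags
}

#' Remove outlier loci flagged on the delta-GLS distributions
#'
#' @param loci List of [locus_alignment()] objects.
#' @param records `signal_table` covering those loci.
#' @param on Flagging axis passed to [signal_outlier_flags()].
#' @return List with `loci` (retained), `removed` (locus ids) and
#'   `bounds` (per-axis [outlier_bounds()]).
#' @export
remove_outliers <- function(loci, records, on = "any_pair") {
  ids <- vapply(loci, function(l) l$locus_id, "")
  m <- match(ids, records$locus_id)
  if (anyNA(m)) stop("signal records missing for: ",
                     paste(ids[is.na(m)], collapse = ", "))
  flags <- signal_outlier_flags(records[m, , drop = FALSE], on = on)
  list(loci = loci[!flags], removed = ids[flags],
       bounds = attr(flags, "bounds"))
}
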