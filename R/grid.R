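# The strategy grid: from the CDS and IGS locus sets plus per-locus
# diagnostics and signal, emit the 30 named supermatrices (11 CDS-family,
# 9 IGS-family, 10 All-family) that the conflict meta-analysis compares.

#' Strategy grid configuration
#'
#' Thresholds follow the study defaults: long-branch heterogeneity shoulders
#' at 0.45 (CDS) / 0.90 (IGS), saturation R-squared shoulders at 0.50 /
#' 0.344, slope shoulders at 0.104 / 0.30, and a 75\% mean bootstrap-support
#' cutoff.  Loci failing a threshold are removed; ties are kept.
#'
#' @param gap_modes Gap modes for the conserved-block trimmer.
#' @param lb_threshold,slope_threshold,r2_threshold Named per-category
#'   (`CDS`, `IGS`) thresholds.
#' @param bs_threshold Mean bootstrap support cutoff in percent.
#' @param include_codon_datasets Emit `CDS-codon-align` and
#'   `CDS-codon-align-rm3`.
#' @param include_block_dataset Emit `All-Homblock` (strict whole-matrix
#'   block trimming).
#' @param trim_is_frac,trim_fs_frac,trim_max_nonconserved,trim_min_block
#'   Parameters forwarded to [trim_conserved_blocks()].
#' @return Object of class `strategy_config`.
#' @export
strategy_config <- function(gap_modes = c("all", "half", "none"),
                            lb_threshold = c(CDS = 0.45, IGS = 0.90),
                            slope_threshold = c(CDS = 0.104, IGS = 0.30),
                            r2_threshold = c(CDS = 0.50, IGS = 0.344),
                            bs_threshold = 75,
                            include_codon_datasets = TRUE,
                            include_block_dataset = TRUE,
                            trim_is_frac = 0.5, trim_fs_frac = 0.85,
                            trim_max_nonconserved = 8L, trim_min_block = 10L) {
  gap_modes <- match.arg(gap_modes, several.ok = TRUE)
  stopifnot(all(lb_threshold > 0), all(slope_threshold > 0),
            all(r2_threshold > 0), bs_threshold > 0, bs_threshold <= 100)
  structure(list(gap_modes = gap_modes, lb_threshold = lb_threshold,
                 slope_threshold = slope_threshold,
                 r2_threshold = r2_threshold, bs_threshold = bs_threshold,
                 include_codon_datasets = include_codon_datasets,
                 include_block_dataset = include_block_dataset,
                 trim_is_frac = trim_is_frac, trim_fs_frac = trim_fs_frac,
                 trim_max_nonconserved = as.integer(trim_max_nonconserved),
                 trim_min_block = as.integer(trim_min_block)),
            class = "strategy_config")
}

threshold_for <- function(thr, category) {
  if (length(thr) == 1L && is.null(names(thr))) return(unname(thr))
  out <- thr[category]
  out[is.na(out)] <- thr[["IGS"]]
  unname(out)
}

# remove loci failing a per-category threshold; errors if nothing survives
filter_family <- function(loci, diag, metric, thr, label, family) {
  ids <- vapply(loci, function(l) l$locus_id, "")
  d <- diag[match(ids, diag$locus_id), , drop = FALSE]
  if (anyNA(d$locus_id))
    stop("diagnostics missing for loci: ",
         paste(ids[is.na(d$locus_id)], collapse = ", "))
  tvec <- threshold_for(thr, d$category)
  col <- switch(metric, lb = "lb_heterogeneity", slope = "slope",
                r2 = "r2", support = "mean_support")
  x <- d[[col]]
  if (anyNA(x)) stop("diagnostic '", col, "' missing for some loci")
  rm <- if (metric == "lb") x > tvec else x < tvec
  if (all(rm))
    stop("filter '", label, "' removed every locus of family ", family)
  loci[!rm]
}

#' Build the full strategy grid of supermatrices
#'
#' Emits, with default configuration, exactly 30 matrices: the CDS family
#' (base, three gap-mode trims, BS75, LB, Slope, R2, no-outlier,
#' codon-align, codon-align-rm3), the IGS family (base, three trims, BS75,
#' LB, Slope, R2, no-outlier) and the All family (base, three trims, BS75,
#' LB, Slope, R2, no-outlier, Homblock).  Filter strategies remove whole
#' loci; trimming strategies remove columns.  `All-Homblock` applies the
#' strict (`none`) block trimmer to the whole concatenation.
#'
#' @param cds_loci,igs_loci Lists of [locus_alignment()] objects.
#' @param diagnostics Data frame from [diagnose_loci()] covering all loci
#'   (columns `locus_id`, `category`, `lb_heterogeneity`, `slope`, `r2`,
#'   `mean_support`).
#' @param signal A `signal_table` (with `locus_id` and the pairwise
#'   `delta_*` columns) covering all loci, or a named list of such tables
#'   (`CDS`, `IGS`, `All`) when the signal was quantified per dataset
#'   family; outlier flags are recomputed per family via
#'   [signal_outlier_flags()].
#' @param config A [strategy_config()].
#' @return Named list of `concat_matrix` objects.
#' @export
build_strategy_grid <- function(cds_loci, igs_loci, diagnostics, signal,
                                config = strategy_config()) {
  stopifnot(length(cds_loci) > 0L, length(igs_loci) > 0L)
  all_loci <- c(cds_loci, igs_loci)
  out <- list()
  add <- function(label, cm) {
    cm$provenance <- unique(c(cm$provenance, label))
    out[[label]] <<- cm
  }
  trim <- function(cm, mode)
    trim_conserved_blocks(cm, gap_mode = mode,
                          is_frac = config$trim_is_frac,
                          fs_frac = config$trim_fs_frac,
                          max_nonconserved = config$trim_max_nonconserved,
                          min_block = config$trim_min_block)

  family <- function(loci, prefix) {
    base <- concatenate(loci)
    add(prefix, base)
    for (mode in config$gap_modes)
      add(paste0(prefix, "-GB-", mode), trim(base, mode))
    add(paste0(prefix, "-BS75"),
        concatenate(filter_family(loci, diagnostics, "support",
                                  config$bs_threshold, "BS75", prefix)))
    add(paste0(prefix, "-LB"),
        concatenate(filter_family(loci, diagnostics, "lb",
                                  config$lb_threshold, "LB", prefix)))
    add(paste0(prefix, "-Slope"),
        concatenate(filter_family(loci, diagnostics, "slope",
                                  config$slope_threshold, "Slope", prefix)))
    add(paste0(prefix, "-R2"),
        concatenate(filter_family(loci, diagnostics, "r2",
                                  config$r2_threshold, "R2", prefix)))
    ids <- vapply(loci, function(l) l$locus_id, "")
    sig <- if (is.data.frame(signal)) signal else signal[[prefix]]
    if (is.null(sig)) stop("no signal table for family ", prefix)
    s <- sig[match(ids, sig$locus_id), , drop = FALSE]
    if (anyNA(s$locus_id))
      stop("signal records missing for loci: ",
           paste(ids[is.na(s$locus_id)], collapse = ", "))
    flags <- signal_outlier_flags(s)
    if (all(flags))
      stop("outlier filter removed every locus of family ", prefix)
    add(paste0(prefix, "-no-outlier"), concatenate(loci[!flags]))
    invisible(NULL)
  }

  family(cds_loci, "CDS")
  if (config$include_codon_datasets) {
    codon <- concatenate(cds_loci, provenance = "codon-align")
    add("CDS-codon-align", codon)
    add("CDS-codon-align-rm3", remove_third_codon(codon))
  }
  family(igs_loci, "IGS")
  family(all_loci, "All")
  if (config$include_block_dataset)
    add("All-Homblock", trim(concatenate(all_loci), "none"))
  out
}

#' Count grid matrices per dataset family
#'
#' @param grid Named list from [build_strategy_grid()].
#' @return Named integer vector with `CDS`, `IGS`, `All` and `total`.
#' @export
grid_family_counts <- function(grid) {
  labs <- names(grid)
  cds <- sum(startsWith(labs, "CDS"))
  igs <- sum(startsWith(labs, "IGS"))
  all_ <- sum(startsWith(labs, "All"))
  c(CDS = cds, IGS = igs, All = all_, total = length(grid))
}
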