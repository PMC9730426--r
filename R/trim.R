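# Conserved-block trimming of aligned matrices, in the style of Gblocks:
# columns are classified by the frequency of their majority residue and a
# gap rule; long runs of non-conserved columns are excised, remaining blocks
# are trimmed back to highly conserved flanks and short blocks are dropped.
# Only the gap rule ("all"/"half"/"none") is meant to vary between runs.

#' Trim a matrix to conserved blocks
#'
#' A column is *conserved* when its majority residue occurs in at least
#' `is_frac` of its non-gap rows and *highly conserved* at `fs_frac`; the
#' gap mode
#' removes columns violating its gap rule (`none`: any gap; `half`: more
#' than 50\% gaps; `all`: gaps ignored).  Runs of more than
#' `max_nonconserved` consecutive non-conserved columns are cut, surviving
#' segments are trimmed to highly conserved flank columns, and blocks
#' shorter than `min_block` are dropped.
#'
#' @param cm A `concat_matrix`.
#' @param gap_mode `"all"`, `"half"` or `"none"` (most relaxed to strictest).
#' @param is_frac Minimum majority-residue fraction for a conserved column.
#' @param fs_frac Majority-residue fraction for a highly conserved (flank)
#'   column.
#' @param max_nonconserved Longest tolerated run of non-conserved columns
#'   inside a block.
#' @param min_block Minimum surviving block length.
#' @return The trimmed `concat_matrix`; attribute `kept_columns` maps its
#'   columns back to 1-based input columns.  An empty result (all columns
#'   removed) is returned with a warning.
#' @export
trim_conserved_blocks <- function(cm, gap_mode = c("all", "half", "none"),
                                  is_frac = 0.5, fs_frac = 0.85,
                                  max_nonconserved = 8L, min_block = 10L) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(inherits(cm, "concat_matrix"), matrix_length(cm) > 0L)
  n <- length(cm$taxa)
  L <- matrix_length(cm)

  gap_frac <- colMeans(cm$mat == "-")
  # majority residue frequency among the non-gap rows of the column; gaps
  # enter only through the gap rule below
  maj <- apply(cm$mat, 2L, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0L) return(0)
    max(tabulate(factor(col))) / length(col)
  })

  status <- ifelse(maj >= fs_frac, 2L, ifelse(maj >= is_frac, 1L, 0L))
  gap_bad <- switch(gap_mode,
                    all = rep(FALSE, L),
                    half = gap_frac > 0.5,
                    none = gap_frac > 0)
  status[gap_bad] <- 0L

  keep <- rep(TRUE, L)
  # gap-rule violations are removed outright, as in the original block
  # trimmer; other non-conserved columns fall only with long runs
  keep[gap_bad] <- FALSE
  r <- rle(status == 0L)
  ends <- cumsum(r$lengths)
  for (i in seq_along(r$lengths))
    if (r$values[i] && r$lengths[i] > max_nonconserved)
      keep[(ends[i] - r$lengths[i] + 1L):ends[i]] <- FALSE

  # segment-wise flank trimming and minimum block length
  final <- rep(FALSE, L)
  seg <- rle(keep)
  seg_ends <- cumsum(seg$lengths)
  for (i in seq_along(seg$lengths)) {
    if (!seg$values[i]) next
    a <- seg_ends[i] - seg$lengths[i] + 1L
    b <- seg_ends[i]
    hi <- which(status[a:b] == 2L)
    if (length(hi) == 0L) next
    a2 <- a + hi[1] - 1L
    b2 <- a + hi[length(hi)] - 1L
    if (b2 - a2 + 1L >= min_block) final[a2:b2] <- TRUE
  }

  if (!any(final)) {
    warning("trimming removed all columns (gap_mode = ", gap_mode, ")")
    out <- new_concat_matrix(cm$taxa, cm$mat[, 0, drop = FALSE],
                             cm$partitions[0, ], cm$alphabet,
                             c(cm$provenance, paste0("GB-", gap_mode)))
    attr(out, "kept_columns") <- integer()
    return(out)
  }
  subset_columns(cm, final, provenance_add = paste0("GB-", gap_mode))
}
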