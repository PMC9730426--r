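# Per-locus diagnostics feeding the locus filters: long-branch (LB) scores,
# substitution-saturation regressions, and mean gene-tree bootstrap support.

#' Long-branch scores of a tree's taxa
#'
#' The LB score of taxon i is the percentage deviation of its mean patristic
#' distance to all other taxa from the tree-wide mean pairwise distance:
#' `LB_i = 100 * (mean_j PD(i,j) / mean_all PD - 1)`.  The per-tree summary
#' (LB heterogeneity) is the sample standard deviation of the taxon scores
#' expressed on the fractional (0-1) scale, i.e. `sd(LB_i) / 100` -- the
#' scale on which the filter's shoulder thresholds (0.45 for CDS, 0.90 for
#' IGS) are quoted.  Loci whose trees have heterogeneous LB scores are
#' long-branch prone.
#'
#' @param tree `phylo` with branch lengths, at least 3 taxa.
#' @return List with `lb` (named per-taxon percent scores) and
#'   `heterogeneity` (fractional scale).
#' @export
lb_scores <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 3L) stop("LB scores require at least 3 taxa")
  pd <- patristic_distances(tree)
  mean_i <- rowSums(pd) / (n - 1)
  overall <- sum(pd) / (n * (n - 1))
  lb <- 100 * (mean_i / overall - 1)
  list(lb = lb, heterogeneity = stats::sd(lb) / 100)
}

#' Uncorrected pairwise distances of one locus
#'
#' Mismatch proportion over columns where both sequences carry an
#' unambiguous state (gaps, `N`/`X` excluded).  Pairs with no comparable
#' site get `NA`.
#'
#' @param locus A [locus_alignment()].
#' @return Symmetric taxon-by-taxon matrix of p-distances.
#' @export
p_distances <- function(locus) {
  stopifnot(inherits(locus, "locus_alignment"))
  mat <- locus$mat
  n <- nrow(mat)
  if (n < 2L) stop("p-distances require at least 2 taxa")
  unamb <- if (locus$alphabet == "NT") c("A", "C", "G", "T")
           else setdiff(AA_CHARS, c("X", "-"))
  ok <- matrix(mat %in% unamb, nrow = n)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- ok[i, ] & ok[j, ]
    nc <- sum(comp)
    d[i, j] <- d[j, i] <-
      if (nc == 0L) NA_real_ else sum(mat[i, comp] != mat[j, comp]) / nc
  }
  d
}

#' Saturation regression of observed on patristic distance
#'
#' Ordinary least squares of the uncorrected p-distance on the patristic
#' distance with the intercept forced through zero (zero evolutionary
#' distance implies zero observed distance).  Shallow slopes and low
#' R-squared indicate substitutional saturation.
#'
#' @param pdist Symmetric p-distance matrix (e.g. from [p_distances()]).
#' @param patristic Symmetric patristic matrix over the same taxa.
#' @return List with `slope` and `r2` (R-squared of the zero-intercept fit).
#' @export
saturation_regression <- function(pdist, patristic) {
  taxa <- intersect(rownames(pdist), rownames(patristic))
  if (length(taxa) < 3L) stop("need at least 3 shared taxa")
  p <- pdist[taxa, taxa]; x <- patristic[taxa, taxa]
  lo <- lower.tri(p)
  y <- p[lo]; xx <- x[lo]
  keep <- is.finite(y) & is.finite(xx)
  y <- y[keep]; xx <- xx[keep]
  if (length(y) < 3L) stop("fewer than 3 valid taxon pairs")
  if (all(xx == 0)) stop("all patristic distances are zero")
  fit <- stats::lm(y ~ 0 + xx)
  list(slope = unname(coef(fit)[1]),
       r2 = summary(fit)$r.squared)
}

#' Mean bootstrap support of a tree's internal edges
#'
#' @param tree `phylo` with numeric supports in `node.label`.
#' @return Arithmetic mean of the internal-edge supports (percent).
#' @export
mean_support <- function(tree) {
  sup <- node_supports(tree)
  sup <- sup[!is.na(sup)]
  if (length(sup) == 0L) stop("no internal supports on tree")
  mean(sup)
}

# Quick per-locus gene tree: NJ topology on ML (JC) distances with
# branch lengths (and optionally the topology) re-optimised by likelihood.
gene_tree <- function(locus, model, settings = opt_settings(),
                      method = c("nj", "nni"), restarts = 1L, seed = NULL) {
  method <- match.arg(method)
  cm <- concatenate(list(locus))
  n <- nrow(locus$mat)
  if (n < 3L) stop("gene tree requires at least 3 taxa")
  dm <- tryCatch(phangorn::dist.ml(as_phydat(cm)), error = function(e) NULL)
  if (is.null(dm) || any(!is.finite(as.matrix(dm)))) {
    pd <- p_distances(locus)
    pd[!is.finite(pd)] <- max(pd[is.finite(pd)], 0.75)
    dm <- stats::as.dist(pd)
  }
  start <- if (n == 3L) {
    tr <- ape::rtree(3, tip.label = rownames(locus$mat), rooted = FALSE)
    tr$edge.length <- rep(0.05, nrow(tr$edge)); tr
  } else ape::nj(dm)
  start$edge.length <- pmax(start$edge.length, settings$min_edge)
  if (method == "nni" && n >= 4L)
    nni_search(cm, start, model, settings, restarts = restarts, seed = seed)
  else
    optimize_branch_lengths(cm, start, model, settings)
}

#' Compute the full diagnostics table for a list of loci
#'
#' For each locus a gene tree is estimated (NJ topology with ML branch
#' lengths by default, or a likelihood NNI search), from which LB scores,
#' the saturation regression and (optionally) mean nonparametric bootstrap
#' support are derived.
#'
#' @param loci List of [locus_alignment()] objects.
#' @param model A [subst_model()] used for gene-tree estimation.
#' @param settings An [opt_settings()].
#' @param tree_method `"nj"` (fast default) or `"nni"`.
#' @param bootstrap_B Bootstrap replicates for mean support; 0 skips the
#'   support column (NA).
#' @param seed Integer seed for the bootstrap and any tree-search restarts.
#' @return Data frame with columns `locus_id`, `category`,
#'   `lb_heterogeneity`, `slope`, `r2`, `mean_support`; per-taxon LB scores
#'   in attribute `taxon_lb`, gene trees in attribute `gene_trees`.
#' @export
diagnose_loci <- function(loci, model = jc_model(k = 4, shape = 1),
                          settings = opt_settings(), tree_method = "nj",
                          bootstrap_B = 0L, seed = 1L) {
  n <- length(loci)
  out <- data.frame(locus_id = vapply(loci, function(l) l$locus_id, ""),
                    category = vapply(loci, function(l) l$category, ""),
                    lb_heterogeneity = NA_real_, slope = NA_real_,
                    r2 = NA_real_, mean_support = NA_real_,
                    stringsAsFactors = FALSE)
  taxon_lb <- vector("list", n)
  trees <- vector("list", n)
  for (i in seq_len(n)) {
    locus <- loci[[i]]
    gt <- gene_tree(locus, model, settings, method = tree_method,
                    seed = seed + i)
    trees[[i]] <- gt$tree
    lb <- lb_scores(gt$tree)
    taxon_lb[[i]] <- lb$lb
    out$lb_heterogeneity[i] <- lb$heterogeneity
    sat <- tryCatch(
      saturation_regression(p_distances(locus), patristic_distances(gt$tree)),
      error = function(e) list(slope = NA_real_, r2 = NA_real_))
    out$slope[i] <- sat$slope
    out$r2[i] <- sat$r2
    if (bootstrap_B > 0L && length(gt$tree$tip.label) >= 4L) {
      cm <- concatenate(list(locus))
      bt <- bootstrap_support(cm, gt$tree, model, B = bootstrap_B,
                              seed = seed + 1000L + i, settings = settings)
      out$mean_support[i] <- mean_support(bt)
      trees[[i]] <- bt
    }
  }
  names(taxon_lb) <- out$locus_id
  names(trees) <- out$locus_id
  attr(out, "taxon_lb") <- taxon_lb
  attr(out, "gene_trees") <- trees
  out
}
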