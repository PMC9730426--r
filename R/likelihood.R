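# Likelihood engine: fixed-topology evaluation with per-site log-likelihoods,
# branch-length and model optimisation, NNI gene-tree search, and
# nonparametric bootstrap support.  Evaluation and optimisation are delegated
# to phangorn (Felsenstein pruning over a discrete-gamma(+I) mixture with
# ambiguous states as all-ones partials); this module owns the contracts:
# taxon checks, site-table expansion, two-taxon handling and seeding.

as_phydat <- function(cm) {
  stopifnot(inherits(cm, "concat_matrix"))
  type <- if (cm$alphabet == "NT") "DNA" else "AA"
  phangorn::phyDat(cm$mat, type = type)
}

check_tree_vs_matrix <- function(tree, cm) {
  if (!setequal(tree$tip.label, cm$taxa))
    stop("tree leaves and matrix taxa differ: tree-only {",
         paste(setdiff(tree$tip.label, cm$taxa), collapse = ","),
         "}, matrix-only {",
         paste(setdiff(cm$taxa, tree$tip.label), collapse = ","), "}")
  invisible(TRUE)
}

build_pml <- function(cm, tree, model, data = NULL) {
  check_tree_vs_matrix(tree, cm)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (is.null(data)) data <- as_phydat(cm)
  if (model$alphabet != cm$alphabet)
    stop("model alphabet does not match matrix alphabet")
  if (model$alphabet == "NT") {
    if (is.null(model$bf)) {
      phangorn::pml(tree, data, Q = model$Q, k = model$k,
                    shape = model$shape, inv = model$inv)
    } else {
      phangorn::pml(tree, data, Q = model$Q, bf = model$bf, k = model$k,
                    shape = model$shape, inv = model$inv)
    }
  } else {
    phangorn::pml(tree, data, model = model$aa_model, k = model$k,
                  shape = model$shape, inv = model$inv)
  }
}

model_from_pml <- function(fit, template) {
  out <- template
  out$Q <- fit$Q
  out$bf <- fit$bf
  out$shape <- fit$shape
  out$k <- fit$k
  out$inv <- fit$inv
  out
}

#' Per-site log-likelihoods of a matrix under a fixed tree and model
#'
#' @param cm A `concat_matrix`.
#' @param tree `phylo` with branch lengths; its leaf set must equal the
#'   matrix taxa.
#' @param model A [subst_model()].
#' @param topology_id Label stored with the table (e.g. `"T1"`).
#' @return Object of class `site_lik_table`: `topology_id`, `sls` (length-L
#'   vector of per-column ln likelihoods), `logLik`, `tree`, `model`.
#' @export
site_loglik <- function(cm, tree, model, topology_id = "T1") {
  fit <- build_pml(cm, tree, model)
  idx <- attr(fit$data, "index")
  sls <- fit$siteLik[idx]
  if (any(!is.finite(sls))) stop("non-finite site log-likelihood")
  if (any(sls > 1e-8)) stop("positive site log-likelihood; corrupt model?")
  structure(list(topology_id = topology_id, sls = as.numeric(sls),
                 logLik = as.numeric(fit$logLik), tree = fit$tree,
                 model = model_from_pml(fit, model)),
            class = "site_lik_table")
}

#' @export
print.site_lik_table <- function(x, ...) {
  cat("<site_lik_table>", x$topology_id, "L =", length(x$sls),
      "lnL =", format(x$logLik), "\n")
  invisible(x)
}

#' Optimise branch lengths on a fixed topology
#'
#' Round-robin single-branch optimisation (via \pkg{phangorn}) until the
#' log-likelihood improves by less than `settings$tol`.  For two-taxon trees
#' the single path length is optimised by bounded 1-D search.
#'
#' @param cm A `concat_matrix`.
#' @param tree Starting tree (topology fixed).
#' @param model A [subst_model()].
#' @param settings An [opt_settings()].
#' @return List with `tree` (optimised branch lengths) and `logLik`.
#' @export
optimize_branch_lengths <- function(cm, tree, model, settings = opt_settings()) {
  check_tree_vs_matrix(tree, cm)
  data <- as_phydat(cm)
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  tree$edge.length <- pmin(pmax(tree$edge.length, settings$min_edge),
                           settings$max_edge)
  if (length(tree$tip.label) == 2L) {
    f <- function(t) {
      tr <- tree
      tr$edge.length <- rep(t / nrow(tree$edge), nrow(tree$edge))
      build_pml(cm, tr, model, data = data)$logLik
    }
    opt <- stats::optimize(f, c(settings$min_edge, settings$max_edge),
                           maximum = TRUE, tol = 1e-10)
    tr <- tree
    tr$edge.length <- rep(opt$maximum / nrow(tree$edge), nrow(tree$edge))
    return(list(tree = tr, logLik = opt$objective))
  }
  fit <- build_pml(cm, tree, model, data = data)
  fit <- phangorn::optim.pml(
    fit, optEdge = TRUE,
    control = phangorn::pml.control(epsilon = settings$tol,
                                    maxit = settings$maxit, trace = 0))
  list(tree = fit$tree, logLik = as.numeric(fit$logLik))
}

#' Fit substitution-model parameters by coordinate ascent
#'
#' Nucleotide matrices: exchangeabilities free, stationary frequencies from
#' empirical counts; amino-acid matrices: fixed empirical exchangeability
#' matrix.  Gamma shape and the invariant proportion are optimised when the
#' template enables them (`k > 1`, `inv > 0`), interleaved with
#' branch-length optimisation.  If the data are too degenerate to identify
#' the shape, it is fixed at 1 with a warning.
#'
#' @param cm A `concat_matrix`.
#' @param tree Starting tree.
#' @param model Template [subst_model()].
#' @param settings An [opt_settings()].
#' @param est_inv Optimise the invariant proportion (default: template
#'   `inv > 0`).
#' @return List with `model` (fitted snapshot), `tree`, `logLik`.
#' @export
fit_model <- function(cm, tree, model, settings = opt_settings(),
                      est_inv = model$inv > 0) {
  check_tree_vs_matrix(tree, cm)
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  template <- model
  template$bf <- NULL  # empirical frequencies from the data
  fit <- build_pml(cm, tree, template, data = as_phydat(cm))
  ctrl <- phangorn::pml.control(epsilon = settings$tol,
                                maxit = settings$maxit, trace = 0)
  opt_gamma <- model$k > 1L
  # variable columns are needed to identify the gamma shape
  n_states <- apply(cm$mat, 2L, function(col) {
    col <- col[!col %in% c("-", "N", "X")]
    length(unique(col))
  })
  if (all(n_states < 2L) && opt_gamma) {
    warning("degenerate data (no variable columns): gamma shape fixed at 1")
    template$shape <- 1
    opt_gamma <- FALSE
    fit <- build_pml(cm, tree, template)
  }
  res <- tryCatch(
    phangorn::optim.pml(fit, optEdge = TRUE,
                        optQ = model$alphabet == "NT",
                        optBf = FALSE,
                        optGamma = opt_gamma, optInv = est_inv,
                        control = ctrl),
    error = function(e) NULL)
  if (is.null(res)) {
    warning("model optimisation failed (degenerate data?); fixing shape at 1")
    template$shape <- 1
    fit <- build_pml(cm, tree, template)
    res <- phangorn::optim.pml(fit, optEdge = TRUE, control = ctrl)
  }
  list(model = model_from_pml(res, model), tree = res$tree,
       logLik = as.numeric(res$logLik))
}

random_start_tree <- function(taxa) {
  tr <- ape::rtopology(length(taxa), rooted = FALSE, tip.label = sample(taxa))
  tr$edge.length <- rep(0.1, nrow(tr$edge))
  tr
}

#' NNI hill-climbing tree search with random restarts
#'
#' Accepts improving nearest-neighbour-interchange moves until a local
#' optimum, then repeats from seeded random starting topologies and returns
#' the best tree found.
#'
#' @param cm A `concat_matrix`.
#' @param start Binary unrooted starting tree.
#' @param model A [subst_model()].
#' @param settings An [opt_settings()].
#' @param restarts Number of additional random-start searches (default 5).
#' @param seed Optional integer seed for the restarts.
#' @return List with `tree` and `logLik`.
#' @export
nni_search <- function(cm, start, model, settings = opt_settings(),
                       restarts = 5L, seed = NULL) {
  check_tree_vs_matrix(start, cm)
  if (length(start$tip.label) < 4L) {
    opt <- optimize_branch_lengths(cm, start, model, settings)
    return(opt)
  }
  if (!is.null(seed)) set.seed(seed)
  data <- as_phydat(cm)
  ctrl <- phangorn::pml.control(epsilon = settings$tol,
                                maxit = settings$maxit, trace = 0)
  climb <- function(tree) {
    if (is.null(tree$edge.length))
      tree$edge.length <- rep(0.1, nrow(tree$edge))
    fit <- build_pml(cm, tree, model, data = data)
    fit <- phangorn::optim.pml(fit, optNni = TRUE, optEdge = TRUE,
                               control = ctrl)
    list(tree = fit$tree, logLik = as.numeric(fit$logLik))
  }
  best <- climb(start)
  for (r in seq_len(restarts)) {
    cand <- climb(random_start_tree(cm$taxa))
    if (cand$logLik > best$logLik + 1e-9) best <- cand
  }
  best
}

#' Nonparametric bootstrap support for a tree
#'
#' Columns are resampled with replacement `B` times; each replicate is
#' re-searched by NNI hill-climbing from the input tree, and each internal
#' edge's support is the percentage of replicate trees containing its
#' bipartition.  Support is stored in `node.label`.
#'
#' @param cm A `concat_matrix`.
#' @param tree Tree to annotate (binary, unrooted, with branch lengths).
#' @param model A [subst_model()].
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param settings An [opt_settings()].
#' @return The input tree with percentage supports in `node.label`.
#' @export
bootstrap_support <- function(cm, tree, model, B = 100L, seed = 1L,
                              settings = opt_settings()) {
  stopifnot(B >= 1L)
  set.seed(seed)
  L <- matrix_length(cm)
  ctrl <- phangorn::pml.control(epsilon = settings$tol,
                                maxit = settings$maxit, trace = 0)
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(L, L, replace = TRUE)
    cmb <- cm
    cmb$mat <- cm$mat[, cols, drop = FALSE]
    if (length(tree$tip.label) < 4L) {
      reps[[b]] <- tree
      next
    }
    fit <- build_pml(cmb, tree, model, data = as_phydat(cmb))
    fit <- phangorn::optim.pml(fit, optNni = TRUE, optEdge = TRUE,
                               control = ctrl)
    reps[[b]] <- fit$tree
  }
  ref <- ape::unroot(tree)
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  ref$node.label <- as.character(round(100 * counts / B, 6))
  ref$node.label[1] <- ""  # root pseudo-node carries no bipartition
  ref
}
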