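# Substitution model and optimisation-settings containers.

#' Time-reversible substitution model
#'
#' Nucleotide models are parameterised by six exchangeabilities (order
#' AC, AG, AT, CG, CT, GT) and four stationary frequencies; amino-acid
#' models use a named empirical exchangeability matrix (default `"LG"`).
#' Among-site rate variation uses a discrete gamma with `k` equal-weight
#' categories of shape `shape`, plus an invariant-site proportion `inv`.
#'
#' @param alphabet `"NT"` or `"AA"`.
#' @param Q Six exchangeabilities (NT only).
#' @param bf Stationary frequencies (length 4 for NT); `NULL` means
#'   empirical frequencies computed from the data at fit time.
#' @param shape Gamma shape alpha (> 0).
#' @param k Number of gamma categories (1 disables rate variation).
#' @param inv Proportion of invariant sites in `[0, 1)`.
#' @param aa_model Empirical amino-acid model name (passed to phangorn),
#'   default `"LG"`.
#' @return Object of class `subst_model`.
#' @export
subst_model <- function(alphabet = c("NT", "AA"), Q = rep(1, 6), bf = NULL,
                        shape = 1, k = 4L, inv = 0, aa_model = "LG") {
  alphabet <- match.arg(alphabet)
  if (alphabet == "NT") {
    stopifnot(length(Q) == 6L, all(Q > 0))
    if (!is.null(bf)) {
      stopifnot(length(bf) == 4L, all(bf > 0))
      bf <- bf / sum(bf)
    }
  }
  stopifnot(shape > 0, k >= 1L, inv >= 0, inv < 1)
  structure(list(alphabet = alphabet, Q = Q, bf = bf, shape = shape,
                 k = as.integer(k), inv = inv, aa_model = aa_model),
            class = "subst_model")
}

#' Jukes-Cantor model (equal rates and frequencies, no rate variation)
#' @param k Gamma categories (default 1: no rate heterogeneity).
#' @param shape Gamma shape when `k > 1`.
#' @return A `subst_model`.
#' @export
jc_model <- function(k = 1L, shape = 1)
  subst_model("NT", Q = rep(1, 6), bf = rep(0.25, 4), shape = shape, k = k)

#' Optimisation settings for likelihood fits
#'
#' @param tol Convergence tolerance on the log-likelihood (default 1e-4).
#' @param maxit Maximum outer iterations (default 50).
#' @param min_edge,max_edge Branch-length bounds in substitutions/site.
#' @return Object of class `opt_settings`.
#' @export
opt_settings <- function(tol = 1e-4, maxit = 50L, min_edge = 1e-8,
                         max_edge = 10) {
  stopifnot(tol > 0, maxit >= 1L, min_edge > 0, max_edge > min_edge)
  structure(list(tol = tol, maxit = as.integer(maxit),
                 min_edge = min_edge, max_edge = max_edge),
            class = "opt_settings")
}
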