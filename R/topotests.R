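# RELL-based topology hypothesis tests.  All tests resample per-site log-
# likelihoods (no re-optimisation): KH/SH and their weighted variants at
# scale 1, and the approximately unbiased (AU) test across a multiscale
# bootstrap with a probit-scale weighted least-squares fit of
# BP(r) = 1 - Phi(d sqrt(r) + c / sqrt(r)).

as_sls_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x) && all(vapply(x, inherits, TRUE, "site_lik_table"))) {
    labels <- names(x)
    if (is.null(labels)) labels <- vapply(x, function(t) t$topology_id, "")
    m <- do.call(rbind, lapply(x, function(t) t$sls))
    rownames(m) <- labels
    return(m)
  }
  stop("expected a topology x site matrix or a list of site_lik_table")
}

#' RELL bootstrap of per-site log-likelihoods
#'
#' Each replicate draws `ceiling(scale * L)` site indices with replacement
#' and sums every topology's site log-likelihoods over them (equivalently:
#' weights the columns by one multinomial draw).
#'
#' @param sls Topology-by-site matrix of per-site log-likelihoods, or a
#'   named list of `site_lik_table` objects.
#' @param B Number of replicates.
#' @param scale Resampling scale factor (fraction of L drawn; default 1).
#' @param seed Optional integer seed.
#' @return Topology-by-replicate matrix of resampled totals.
#' @export
rell_resample <- function(sls, B, scale = 1, seed = NULL) {
  sls <- as_sls_matrix(sls)
  if (ncol(sls) == 0L || nrow(sls) < 2L)
    stop("need >= 2 topologies and >= 1 site")
  stopifnot(B >= 1L, scale > 0)
  if (!is.null(seed)) set.seed(seed)
  L <- ncol(sls)
  m <- as.integer(ceiling(scale * L))
  totals <- matrix(0, nrow = nrow(sls), ncol = B,
                   dimnames = list(rownames(sls), NULL))
  # multinomial site weights per replicate, built by tabulating uniform
  # site draws (runif indexing: same law, much cheaper than sample.int at
  # tens of millions of draws); chunked so the count matrix stays small
  chunk <- max(1L, min(B, as.integer(4e7 / L)))
  done <- 0L
  while (done < B) {
    nb <- min(chunk, B - done)
    idx <- as.integer(ceiling(stats::runif(m * nb) * L))
    off <- idx + rep.int((seq_len(nb) - 1L) * L, rep.int(m, nb))
    W <- tabulate(off, nbins = L * nb)
    dim(W) <- c(L, nb)
    totals[, (done + 1L):(done + nb)] <- sls %*% W
    done <- done + nb
  }
  totals
}

#' KH and SH topology tests (plus weighted variants) by RELL
#'
#' Replicate totals are centred by their own replicate mean.  The KH test
#' of topology i compares the observed log-likelihood deficit relative to
#' the maximum-likelihood topology against the centred replicate
#' differences (one-sided); the SH test uses the maximum over all
#' topologies.  The weighted variants standardise every pairwise difference
#' by its replicate standard deviation.
#'
#' @param sls Topology-by-site log-likelihood matrix or list of
#'   `site_lik_table` objects.
#' @param B Replicates (default 10000; fewer than 100 warns).
#' @param seed Integer seed.
#' @return Data frame: `topology`, `logLik`, `p_kh`, `p_sh`, `p_wkh`,
#'   `p_wsh`.
#' @export
kh_sh_tests <- function(sls, B = 10000L, seed = 1L) {
  sls <- as_sls_matrix(sls)
  if (B < 100L) warning("B < 100 gives unstable p-values")
  obs <- rowSums(sls)
  R <- rell_resample(sls, B, scale = 1, seed = seed)
  C <- R - rowMeans(R)
  ml <- which.max(obs)
  nt <- nrow(sls)
  maxC <- apply(C, 2L, max)
  obs_max <- max(obs)
  p_kh <- p_sh <- p_wkh <- p_wsh <- numeric(nt)
  # pairwise replicate standard deviations for the weighted tests
  sdm <- matrix(0, nt, nt)
  for (i in seq_len(nt)) for (j in seq_len(nt))
    if (i != j) sdm[i, j] <- stats::sd(R[j, ] - R[i, ])
  for (i in seq_len(nt)) {
    d_obs <- obs[ml] - obs[i]
    d_rep <- C[ml, ] - C[i, ]
    p_kh[i] <- mean(d_rep >= d_obs)
    p_sh[i] <- mean((maxC - C[i, ]) >= (obs_max - obs[i]))
    s <- sdm[i, ml]
    if (s == 0) {
      p_wkh[i] <- 1
    } else {
      p_wkh[i] <- mean(d_rep / s >= d_obs / s)
    }
    # WSH: max over comparators of standardised differences
    z_obs <- z_rep <- 0
    z_rep <- rep(0, ncol(C))
    for (j in seq_len(nt)) {
      if (j == i || sdm[i, j] == 0) next
      z_obs <- max(z_obs, (obs[j] - obs[i]) / sdm[i, j])
      z_rep <- pmax(z_rep, (C[j, ] - C[i, ]) / sdm[i, j])
    }
    p_wsh[i] <- mean(z_rep >= z_obs)
  }
  data.frame(topology = rownames(sls), logLik = obs, p_kh = p_kh,
             p_sh = p_sh, p_wkh = p_wkh, p_wsh = p_wsh,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Approximately unbiased (AU) test by multiscale RELL bootstrap
#'
#' For each scale r the bootstrap proportion BP(r) is the fraction of
#' replicates in which a topology attains the maximum total.  The curve
#' `BP(r) = 1 - Phi(d sqrt(r) + c / sqrt(r))` is fitted by weighted least
#' squares on the probit scale with binomial weights (continuity correction
#' `1/(2B)` for degenerate proportions), and `p_au = 1 - Phi(d - c)`.
#'
#' @param sls Topology-by-site log-likelihood matrix or list of
#'   `site_lik_table` objects.
#' @param scales Resampling scales (default 0.5 to 1.4 by 0.1).
#' @param B Replicates per scale.
#' @param seed Integer seed.
#' @return Data frame: `topology`, `p_au`, `d`, `c`; the per-scale
#'   bootstrap proportions in attribute `bp` (topology x scale).
#' @export
au_test <- function(sls, scales = seq(0.5, 1.4, by = 0.1), B = 10000L,
                    seed = 1L) {
  sls <- as_sls_matrix(sls)
  if (length(scales) < 2L || any(scales <= 0))
    stop("need >= 2 positive scales")
  nt <- nrow(sls)
  bp <- matrix(0, nt, length(scales),
               dimnames = list(rownames(sls), paste0("r", scales)))
  for (s in seq_along(scales)) {
    tot <- rell_resample(sls, B, scale = scales[s], seed = seed + s)
    cmax <- apply(tot, 2L, max)
    # count every topology attaining the maximum, so identical site
    # log-likelihood vectors receive identical proportions
    bp[, s] <- rowMeans(tot >= matrix(cmax, nt, B, byrow = TRUE) - 1e-10)
  }
  p_au <- d_hat <- c_hat <- numeric(nt)
  for (i in seq_len(nt)) {
    b <- bp[i, ]
    if (all(b == 0)) { p_au[i] <- 0; d_hat[i] <- Inf; c_hat[i] <- 0
      warning("topology ", rownames(sls)[i],
              " never attains the maximum; p_au set to 0"); next }
    if (all(b == 1)) { p_au[i] <- 1; d_hat[i] <- -Inf; c_hat[i] <- 0
      warning("topology ", rownames(sls)[i],
              " always attains the maximum; p_au set to 1"); next }
    fit <- au_fit(b, scales, B)
    d_hat[i] <- fit$d
    c_hat[i] <- fit$c
    p_au[i] <- fit$p_au
  }
  out <- data.frame(topology = rownames(sls), p_au = p_au, d = d_hat,
                    c = c_hat, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "bp") <- bp
  out
}

# probit-scale weighted least-squares fit of BP(r) = 1 - Phi(d sqrt(r) +
# c / sqrt(r)) with binomial weights; continuity correction 1/(2B) keeps
# degenerate proportions finite on the probit scale
au_fit <- function(bp, scales, B) {
  bc <- pmin(pmax(bp, 1 / (2 * B)), 1 - 1 / (2 * B))
  z <- stats::qnorm(1 - bc)
  w <- B * stats::dnorm(z)^2 / (bc * (1 - bc))
  X <- cbind(sqrt(scales), 1 / sqrt(scales))
  fit <- stats::lm.wfit(X, z, w)
  d <- unname(fit$coefficients[1])
  cc <- unname(fit$coefficients[2])
  list(d = d, c = cc, p_au = 1 - stats::pnorm(d - cc))
}

#' All five topology tests in one table
#'
#' Runs [kh_sh_tests()] at scale 1 and [au_test()] across the multiscale
#' grid, on the same per-site log-likelihoods.
#'
#' @inheritParams au_test
#' @param B Replicates (per scale for the AU part).
#' @return Data frame: `topology`, `logLik`, `p_au`, `p_kh`, `p_sh`,
#'   `p_wkh`, `p_wsh`.
#' @export
topology_tests <- function(sls, B = 10000L, scales = seq(0.5, 1.4, by = 0.1),
                           seed = 1L) {
  sls <- as_sls_matrix(sls)
  kh <- kh_sh_tests(sls, B = B, seed = seed)
  au <- au_test(sls, scales = scales, B = B, seed = seed + 1000L)
  out <- merge(kh, au[, c("topology", "p_au")], by = "topology", sort = FALSE)
  out[, c("topology", "logLik", "p_au", "p_kh", "p_sh", "p_wkh", "p_wsh")]
}
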