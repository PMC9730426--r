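# Gene-wise signal quantification and outlier handling.

mk_table <- function(id, sls) structure(
  list(topology_id = id, sls = sls, logLik = sum(sls), tree = NULL,
       model = NULL), class = "site_lik_table")

mk_parts <- function(lens, ids = sprintf("g%d", seq_along(lens))) {
  end <- cumsum(lens)
  data.frame(locus_id = ids, start = end - lens, end = end,
             category = "IGS", stringsAsFactors = FALSE)
}

test_that("gene-wise sums, deltas and the argmax rule behave as defined", {
  sls1 <- c(-1, -2, -3, -4)
  sls2 <- c(-2, -2, -3, -5)
  tabs <- list(T1 = mk_table("T1", sls1), T2 = mk_table("T2", sls2))
  # single-locus matrix: gls equals the total
  sig1 <- gene_wise_gls(tabs, mk_parts(4))
  expect_equal(sig1$gls_T1, sum(sls1))
  expect_equal(sig1$gls_T2, sum(sls2))
  expect_equal(sig1$delta_T1_T2, sum(sls1) - sum(sls2))
  expect_equal(sig1$supported, "T1")
  # two loci: partition sums and per-locus argmax
  sig2 <- gene_wise_gls(tabs, mk_parts(c(2, 2)))
  expect_equal(sig2$gls_T1, c(-3, -7))
  expect_equal(sig2$gls_T2, c(-4, -8))
  expect_equal(sig2$supported, c("T1", "T1"))
  # identical tables are ambiguous everywhere
  sig3 <- gene_wise_gls(list(T1 = mk_table("T1", sls1),
                             T2 = mk_table("T2", sls1)), mk_parts(c(2, 2)))
  expect_equal(sig3$supported, c("ambiguous", "ambiguous"))
  expect_equal(sig3$delta_T1_T2, c(0, 0))
  expect_error(gene_wise_gls(tabs, mk_parts(c(2, 3))), "partition map")
})

test_that("three-topology records support the argmax and antisymmetric deltas", {
  tabs <- list(T1 = mk_table("T1", c(-50, -50)),
               T2 = mk_table("T2", c(-52.5, -52.5)),
               T3 = mk_table("T3", c(-55, -55)))
  sig <- gene_wise_gls(tabs, mk_parts(2))
  expect_equal(sig$supported, "T1")
  expect_equal(sig$delta_T1_T2, 5)
  expect_equal(sig$delta_T1_T3, 10)
  expect_equal(sig$delta_T2_T3, 5)
  expect_equal(sig$mean_delta, mean(c(5, 10, 5)))
  # antisymmetry: swapping labels negates the delta exactly
  rev <- gene_wise_gls(list(T2 = mk_table("T2", c(-52.5, -52.5)),
                            T1 = mk_table("T1", c(-50, -50))), mk_parts(2))
  expect_identical(rev$delta_T2_T1, -sig$delta_T1_T2)
})

test_that("partition-sum identity holds on simulated data", {
  st <- shared_study()
  cm <- concatenate(st$loci[1:6])
  m <- st$model
  tabs <- list()
  for (nm in names(st$topologies)) {
    tr <- glsignal:::prune_to_taxa(st$topologies[[nm]], cm$taxa)
    opt <- optimize_branch_lengths(cm, tr, m)
    tabs[[nm]] <- site_loglik(cm, opt$tree, m, nm)
  }
  sig <- gene_wise_gls(tabs, cm$partitions)
  for (nm in names(tabs))
    expect_equal(sum(sig[[paste0("gls_", nm)]]), tabs[[nm]]$logLik,
                 tolerance = 1e-6)
})

test_that("support proportions sum to 100 with an ambiguous share", {
  rec <- data.frame(supported = c(rep("T1", 5), rep("T2", 3), rep("T3", 2)))
  p <- support_proportions(rec)
  expect_equal(unname(p[c("T1", "T2", "T3")]), c(50, 30, 20))
  expect_equal(unname(p["ambiguous"]), 0)
  rec2 <- data.frame(supported = rep("ambiguous", 4))
  p2 <- support_proportions(rec2, labels = c("T1", "T2", "T3"))
  expect_equal(unname(p2), c(0, 0, 0, 100))
  expect_equal(sum(p), 100)
  expect_error(support_proportions(rec[0, , drop = FALSE]), "empty")
})

test_that("outlier bounds follow the 3-sigma rule with min/max capping", {
  b <- outlier_bounds(c(-1, 0, 1))
  expect_equal(b$mean, 0)
  expect_equal(b$sd, 1)
  expect_equal(b$lower, -1)  # capped at min(x) since mu - 3 sd = -3 < -1
  expect_equal(b$upper, 1)
  expect_false(any(b$flags))
  # hand-computed: twelve zeros and one 50
  x <- c(rep(0, 12), 50)
  mu <- mean(x); s <- sd(x)
  expect_gt(50, mu + 3 * s)
  b2 <- outlier_bounds(x)
  expect_identical(which(b2$flags), 13L)
  expect_equal(b2$upper, min(max(x), mu + 3 * s))
  expect_equal(b2$lower, max(min(x), mu - 3 * s))
  expect_warning(b3 <- outlier_bounds(rep(2, 5)), "zero standard deviation")
  expect_false(any(b3$flags))
  expect_error(outlier_bounds(c(1, 2)), "at least 3")
})

test_that("outlier removal drops flagged loci and nothing else", {
  lens <- rep(2, 15)
  sls_t1 <- rep(-1, 30)
  sls_t2 <- rep(-1, 30)
  sls_t2[29:30] <- -6  # fifteenth locus strongly prefers T1 over T2
  tabs <- list(T1 = mk_table("T1", sls_t1), T2 = mk_table("T2", sls_t2))
  sig <- gene_wise_gls(tabs, mk_parts(lens))
  loci <- lapply(sig$locus_id, function(id)
    random_locus(id, c("a", "b", "c"), 2, seed = 1))
  out <- remove_outliers(loci, sig)
  expect_equal(out$removed, "g15")
  expect_length(out$loci, 14L)
  # no flags: identity
  sig0 <- gene_wise_gls(list(T1 = mk_table("T1", sls_t1),
                             T2 = mk_table("T2", sls_t1 * 1.0001)),
                        mk_parts(lens))
  out0 <- suppressWarnings(remove_outliers(loci, sig0))
  expect_length(out0$loci, 15L)
})

test_that("removing loci that favour a rival only strengthens the leader", {
  set.seed(33)
  L <- 40
  sls_t1 <- rnorm(L, -2, 0.2)
  sls_t2 <- sls_t1
  sls_t2[37:40] <- sls_t1[37:40] + 2  # last locus favours T2
  tabs <- list(T1 = mk_table("T1", sls_t1), T2 = mk_table("T2", sls_t2))
  parts <- mk_parts(rep(4, 10))
  sig <- gene_wise_gls(tabs, parts)
  drop <- sig$supported == "T2"
  before <- sum(sls_t1) - sum(sls_t2)
  keep_cols <- unlist(lapply(which(!drop), function(i)
    (parts$start[i] + 1):parts$end[i]))
  after <- sum(sls_t1[keep_cols]) - sum(sls_t2[keep_cols])
  expect_gt(after, before)
})
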