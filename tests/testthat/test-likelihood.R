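# Likelihood engine contracts: limits, oracle equivalence, optimisation,
# tree search, bootstrap and tree utilities.

two_taxon_cm <- function(sa, sb) concatenate(list(mk_locus(
  "g", c(A = sa, B = sb))))

test_that("two-taxon limits match the analytic values", {
  tr <- ape::read.tree(text = "(A:0.0000001,B:0.0000001);")
  cm <- two_taxon_cm("A", "A")
  tab <- site_loglik(cm, tr, jc_model(), "T1")
  expect_equal(tab$logLik, log(0.25), tolerance = 1e-5)
  # saturation: distinct states, long path -> joint prob 1/16
  tr2 <- ape::read.tree(text = "(A:5,B:5);")
  cm2 <- two_taxon_cm("A", "C")
  tab2 <- site_loglik(cm2, tr2, jc_model(), "T1")
  expect_equal(tab2$logLik, log(1 / 16), tolerance = 1e-4)
})

test_that("pruning likelihood equals exhaustive-enumeration oracle", {
  set.seed(31)
  for (rep in 1:4) {
    ntaxa <- sample(4:5, 1)
    tr <- ape::unroot(ape::rtree(ntaxa, br = function(n) runif(n, 0.02, 0.6)))
    loc <- random_locus("g", tr$tip.label, 8, gap_prob = if (rep > 2) 0.1 else 0)
    cm <- concatenate(list(loc))
    # JC and an asymmetric GTR
    for (mdl in list(jc_model(),
                     subst_model("NT", Q = c(1, 3, 0.5, 0.8, 2.5, 1.2),
                                 bf = c(0.4, 0.3, 0.2, 0.1), k = 1))) {
      got <- site_loglik(cm, tr, mdl, "T1")$logLik
      bf <- if (is.null(mdl$bf)) rep(0.25, 4) else mdl$bf
      want <- oracle_loglik(loc$mat, tr, ex = mdl$Q, bf = bf)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("log-likelihood is invariant under re-rooting", {
  set.seed(5)
  tr <- ape::rtree(6, br = function(n) runif(n, 0.05, 0.4))
  loc <- random_locus("g", tr$tip.label, 50, seed = 6)
  cm <- concatenate(list(loc))
  m <- jc_model(k = 4, shape = 0.7)
  u <- ape::unroot(tr)
  l0 <- site_loglik(cm, u, m)$logLik
  for (og in u$tip.label[1:3]) {
    r <- ape::root(u, outgroup = og, resolve.root = TRUE)
    expect_equal(site_loglik(cm, r, m)$logLik, l0, tolerance = 1e-8)
  }
})

test_that("site table sums to the total log-likelihood", {
  set.seed(8)
  tr <- ape::unroot(ape::rtree(6, br = function(n) runif(n, 0.05, 0.4)))
  loc <- random_locus("g", tr$tip.label, 120, gap_prob = 0.05, seed = 9)
  cm <- concatenate(list(loc))
  m <- subst_model("NT", Q = c(1, 2, 1, 1, 2, 1), bf = c(0.3, 0.2, 0.3, 0.2),
                   k = 4, shape = 0.5)
  tab <- site_loglik(cm, tr, m)
  expect_length(tab$sls, 120L)
  expect_true(all(tab$sls <= 0))
  expect_equal(sum(tab$sls), tab$logLik, tolerance = 1e-8)
  opt <- optimize_branch_lengths(cm, tr, m)
  tab2 <- site_loglik(cm, opt$tree, m)
  expect_equal(sum(tab2$sls), opt$logLik, tolerance = 1e-8)
})

test_that("two-taxon JC branch length MLE matches the closed form", {
  sa <- paste(rep("A", 100), collapse = "")
  sb <- paste(c(rep("A", 90), rep("C", 10)), collapse = "")
  cm <- two_taxon_cm(sa, sb)
  tr <- ape::read.tree(text = "(A:0.05,B:0.05);")
  opt <- optimize_branch_lengths(cm, tr, jc_model())
  t_hat <- sum(opt$tree$edge.length)
  expect_equal(t_hat, -0.75 * log(1 - 4 * 0.10 / 3), tolerance = 1e-6)
  # identical sequences drive branches to the lower bound
  cm0 <- two_taxon_cm(sa, sa)
  opt0 <- optimize_branch_lengths(cm0, tr, jc_model())
  expect_lt(sum(opt0$tree$edge.length), 1e-6)
})

test_that("huge gamma shape reduces to the single-rate likelihood", {
  set.seed(12)
  tr <- ape::unroot(ape::rtree(5, br = function(n) runif(n, 0.05, 0.3)))
  loc <- random_locus("g", tr$tip.label, 200, seed = 13)
  cm <- concatenate(list(loc))
  l1 <- site_loglik(cm, tr, jc_model(k = 1))$logLik
  l4 <- site_loglik(cm, tr, jc_model(k = 4, shape = 1e6))$logLik
  expect_equal(l4, l1, tolerance = 1e-6)
})

test_that("branch-length optimisation never decreases the likelihood", {
  set.seed(14)
  tr <- ape::unroot(ape::rtree(6, br = function(n) runif(n, 0.02, 0.5)))
  m <- jc_model(k = 4, shape = 1)
  loc <- simulate_locus(tr, m, 400, seed = 15)
  cm <- concatenate(list(loc))
  start <- tr
  start$edge.length <- rep(0.2, nrow(tr$edge))
  l_start <- site_loglik(cm, start, m)$logLik
  opt <- optimize_branch_lengths(cm, start, m)
  expect_gte(opt$logLik, l_start)
  # restarting from the optimum barely moves
  opt2 <- optimize_branch_lengths(cm, opt$tree, m)
  expect_lt(abs(opt2$logLik - opt$logLik), 1e-2)
})

test_that("model fitting recovers simulation parameters approximately", {
  set.seed(16)
  tr <- ape::unroot(ape::rtree(8, br = function(n) runif(n, 0.05, 0.3)))
  m <- jc_model(k = 4, shape = 0.5)
  loc <- simulate_locus(tr, m, 5000, seed = 17)
  cm <- concatenate(list(loc))
  fit <- fit_model(cm, tr, subst_model("NT", k = 4, shape = 1),
                   est_inv = FALSE)
  # JC truth: exchangeabilities near equal (phangorn normalises to GT = 1)
  q <- fit$model$Q / mean(fit$model$Q)
  expect_true(all(q > 0.6 & q < 1.4))
  expect_gt(fit$model$shape, 0.3)
  expect_lt(fit$model$shape, 0.8)
})

test_that("degenerate all-invariant data falls back with a warning", {
  m <- matrix("A", nrow = 4, ncol = 60,
              dimnames = list(paste0("t", 1:4), NULL))
  cm <- concatenate(list(locus_alignment("g", "IGS", m, "NT")))
  tr <- ape::unroot(ape::rtree(4))
  tr$edge.length <- rep(0.1, nrow(tr$edge))
  expect_warning(fit_model(cm, tr, subst_model("NT", k = 4, shape = 1)),
                 "degenerate|failed")
})

test_that("NNI search finds the quartet split the data support", {
  m <- jc_model()
  true <- ape::read.tree(text = "((A:0.05,B:0.05):0.3,(C:0.05,D:0.05):0.3);")
  loc <- simulate_locus(ape::unroot(true), m, 800, seed = 18)
  cm <- concatenate(list(loc))
  wrong <- ape::unroot(ape::read.tree(
    text = "((A:0.1,C:0.1):0.1,(B:0.1,D:0.1):0.1);"))
  found <- nni_search(cm, wrong, m, restarts = 0L, seed = 1)
  expect_identical(glsignal:::tree_bipartitions(found$tree),
                   glsignal:::tree_bipartitions(true))
  # oracle: exhaustive scoring of the three quartet topologies
  quartets <- c("((A,B),(C,D));", "((A,C),(B,D));", "((A,D),(B,C));")
  scores <- vapply(quartets, function(q) {
    tq <- ape::unroot(ape::read.tree(text = q))
    tq$edge.length <- rep(0.1, nrow(tq$edge))
    optimize_branch_lengths(cm, tq, m)$logLik
  }, 0)
  expect_equal(which.max(scores), 1L, ignore_attr = TRUE)
  expect_equal(found$logLik, max(scores), tolerance = 1e-4)
  # searching from the optimum is a fixed point
  again <- nni_search(cm, found$tree, m, restarts = 0L)
  expect_identical(glsignal:::tree_bipartitions(again$tree),
                   glsignal:::tree_bipartitions(found$tree))
})

test_that("bootstrap supports are percentages, deterministic under a seed", {
  m <- jc_model()
  true <- ape::unroot(ape::read.tree(
    text = "((A:0.05,B:0.05):0.2,(C:0.05,D:0.05):0.2,(E:0.05,F:0.05):0.2);"))
  loc <- simulate_locus(true, m, 1500, seed = 20)
  cm <- concatenate(list(loc))
  b1 <- bootstrap_support(cm, true, m, B = 1L, seed = 3)
  sup1 <- glsignal:::node_supports(b1)
  expect_true(all(sup1[!is.na(sup1)] %in% c(0, 100)))
  b20a <- bootstrap_support(cm, true, m, B = 20L, seed = 4)
  b20b <- bootstrap_support(cm, true, m, B = 20L, seed = 4)
  expect_identical(b20a$node.label, b20b$node.label)
  # strong signal: internal edges well supported
  sup <- glsignal:::node_supports(b20a)
  expect_true(all(sup[!is.na(sup)] >= 80))
})

test_that("low-support edges collapse into polytomies", {
  tr <- ape::read.tree(text = "((A:1,B:1)90:0.5,(C:1,D:1)5:0.5,E:1);")
  out <- collapse_low_support(tr, threshold = 10)
  expect_equal(out$Nnode, tr$Nnode - 1L)
  splits <- glsignal:::tree_bipartitions(out)
  expect_true(any(grepl("^A,B$|^C,D,E$", splits)))
  expect_length(splits, 1L)
  # all supports above threshold: unchanged
  tr2 <- ape::read.tree(text = "((A:1,B:1)90:0.5,(C:1,D:1)80:0.5,E:1);")
  expect_equal(collapse_low_support(tr2, 10)$Nnode, tr2$Nnode)
  # threshold above 100 gives a star tree
  star <- collapse_low_support(tr2, 101)
  expect_length(glsignal:::tree_bipartitions(star), 0L)
  expect_error(collapse_low_support(ape::rtree(4), 10), "support")
})

test_that("patristic distances match an explicit path-walk oracle", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  pd <- patristic_distances(tr)
  expect_equal(pd["A", "B"], 2)
  expect_equal(pd["A", "C"], 4)
  expect_true(isSymmetric(pd))
  expect_true(all(diag(pd) == 0))
  set.seed(21)
  tr6 <- ape::rtree(6)
  expect_equal(patristic_distances(tr6)[tr6$tip.label, tr6$tip.label],
               oracle_patristic(tr6), tolerance = 1e-12)
})
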