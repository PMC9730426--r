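# Synthetic-data generator: topology sets, single-locus simulation, and the
# structured multi-locus study.

test_that("topology sets are distinct single-NNI rearrangements", {
  ts <- make_topology_set(12, seed = 1)
  expect_named(ts, c("T1", "T2", "T3"))
  leaves <- lapply(ts, function(t) sort(t$tip.label))
  expect_identical(leaves$T1, leaves$T2)
  expect_identical(leaves$T1, leaves$T3)
  # one NNI = Robinson-Foulds distance 2, by independent split comparison
  expect_equal(oracle_rf(ts$T1, ts$T2), 2)
  expect_equal(oracle_rf(ts$T1, ts$T3), 2)
  expect_gt(oracle_rf(ts$T2, ts$T3), 0)
  # determinism
  ts2 <- make_topology_set(12, seed = 1)
  expect_identical(ape::write.tree(ts$T1), ape::write.tree(ts2$T1))
  expect_identical(ape::write.tree(ts$T3), ape::write.tree(ts2$T3))
  expect_error(make_topology_set(5, seed = 1), "at least 6")
})

test_that("zero rate freezes the locus at the root draw", {
  tr <- ape::unroot(ape::rtree(6, br = function(n) runif(n, 0.1, 0.3)))
  loc <- simulate_locus(tr, jc_model(), 50, rate_multiplier = 0, seed = 3)
  expect_equal(nrow(unique(loc$mat)), 1L)
})

test_that("simulated base composition follows the stationary frequencies", {
  tr <- ape::unroot(ape::rtree(4, br = function(n) runif(n, 0.05, 0.3)))
  bf <- c(0.1, 0.2, 0.3, 0.4)
  m <- subst_model("NT", bf = bf, k = 1)
  loc <- simulate_locus(tr, m, 50000, seed = 4)
  freq <- table(factor(loc$mat, levels = c("A", "C", "G", "T"))) / length(loc$mat)
  expect_true(all(abs(as.numeric(freq) - bf) < 0.01))
})

test_that("the same seed reproduces the same alignment byte for byte", {
  tr <- ape::unroot(ape::rtree(5, br = function(n) runif(n, 0.05, 0.3)))
  a <- simulate_locus(tr, jc_model(k = 4, shape = 0.5), 100, seed = 5)
  b <- simulate_locus(tr, jc_model(k = 4, shape = 0.5), 100, seed = 5)
  expect_identical(a$mat, b$mat)
})

test_that("study bookkeeping matches the configured counts and classes", {
  cfg <- simulation_config(n_taxa = 8, n_clean = 30, n_conflict = 6,
                           n_saturated = 6, n_outlier = 3, seed = 21)
  st <- simulate_study(cfg)
  expect_length(st$loci, 45L)
  expect_equal(nrow(st$truth), 45L)
  expect_equal(sum(st$truth$class == "clean"), 30L)
  expect_equal(sum(st$truth$class == "conflict"), 6L)
  expect_equal(sum(st$truth$class == "saturated"), 6L)
  expect_equal(sum(st$truth$class == "outlier"), 3L)
  expect_true(all(st$truth$topology[st$truth$class == "clean"] == "T1"))
  expect_true(all(st$truth$topology[st$truth$class == "outlier"] == "T2"))
  expect_setequal(unique(st$truth$topology[st$truth$class == "conflict"]),
                  c("T2", "T3"))
  # truth table and emitted loci agree in id, category and length
  for (i in seq_along(st$loci)) {
    expect_equal(st$loci[[i]]$locus_id, st$truth$locus_id[i])
    expect_equal(st$loci[[i]]$category, st$truth$category[i])
    expect_equal(ncol(st$loci[[i]]$mat), st$truth$length[i])
    expect_equal(nrow(st$loci[[i]]$mat), st$truth$n_taxa[i])
  }
  # CDS-like loci are in frame
  cds_len <- st$truth$length[st$truth$category == "CDS"]
  expect_true(all(cds_len %% 3 == 0))
  expect_true(all(st$truth$n_taxa >= ceiling(0.6 * 8)))
})

test_that("missing probability zero keeps every taxon everywhere", {
  cfg <- simulation_config(n_taxa = 8, n_clean = 4, n_conflict = 0,
                           n_saturated = 0, n_outlier = 0,
                           missing_prob = 0, seed = 22)
  st <- simulate_study(cfg)
  expect_true(all(st$truth$n_taxa == 8L))
  expect_error(simulation_config(n_taxa = 8, n_clean = 0, n_conflict = 0,
                                 n_saturated = 0, n_outlier = 0, seed = 1),
               "zero")
  expect_error(simulation_config(n_taxa = 8), "seed")
})

test_that("saturated loci are measurably more divergent than clean loci", {
  st <- shared_study()
  mean_p <- function(cls) {
    idx <- which(st$truth$class == cls)
    mean(vapply(idx, function(i) {
      p <- p_distances(st$loci[[i]])
      mean(p[upper.tri(p)], na.rm = TRUE)
    }, 0))
  }
  expect_gt(mean_p("saturated"), mean_p("clean"))
})

test_that("study writing is deterministic and complete", {
  cfg <- simulation_config(n_taxa = 8, n_clean = 2, n_conflict = 1,
                           n_saturated = 0, n_outlier = 0,
                           cds_len_range = c(300L, 450L),
                           igs_len_range = c(150L, 250L), seed = 23)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(simulate_study(cfg), d1)
  write_study(simulate_study(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(all(c("manifest.tsv", "truth.tsv", "T1.nwk", "T2.nwk",
                    "T3.nwk") %in% f1))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})
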