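# The strategy grid: cardinalities, labels, filter semantics, invariants.

# fabricated inputs that exercise the grid mechanics quickly
grid_fixture <- function(n_cds = 4, n_igs = 4, seed = 50) {
  set.seed(seed)
  taxa <- paste0("t", 1:6)
  cds <- lapply(seq_len(n_cds), function(i)
    random_locus(sprintf("cds%02d", i), taxa, 30 + 3 * i, category = "CDS"))
  igs <- lapply(seq_len(n_igs), function(i)
    random_locus(sprintf("igs%02d", i), taxa, 40 + i, category = "IGS"))
  ids <- c(vapply(cds, function(l) l$locus_id, ""),
           vapply(igs, function(l) l$locus_id, ""))
  diag <- data.frame(locus_id = ids,
                     category = rep(c("CDS", "IGS"), c(n_cds, n_igs)),
                     lb_heterogeneity = 0.2, slope = 0.8, r2 = 0.9,
                     mean_support = 90, stringsAsFactors = FALSE)
  sig <- data.frame(locus_id = ids,
                    delta_T1_T2 = rnorm(length(ids), 5, 1),
                    delta_T1_T3 = rnorm(length(ids), 5, 1),
                    delta_T2_T3 = rnorm(length(ids), 0, 1),
                    mean_delta = rnorm(length(ids), 3, 0.5),
                    stringsAsFactors = FALSE)
  list(cds = cds, igs = igs, diag = diag, sig = sig)
}

test_that("the default grid emits 30 matrices: 11 CDS, 9 IGS, 10 All", {
  fx <- grid_fixture()
  # ensure codon datasets are constructible: CDS lengths multiples of 3
  fx$cds <- lapply(fx$cds, function(l) {
    L <- ncol(l$mat); l$mat <- l$mat[, seq_len(L - L %% 3), drop = FALSE]; l
  })
  grid <- suppressWarnings(
    build_strategy_grid(fx$cds, fx$igs, fx$diag, fx$sig))
  counts <- grid_family_counts(grid)
  expect_equal(unname(counts["CDS"]), 11L)
  expect_equal(unname(counts["IGS"]), 9L)
  expect_equal(unname(counts["All"]), 10L)
  expect_equal(unname(counts["total"]), 30L)
  expect_setequal(
    grep("^CDS", names(grid), value = TRUE),
    c("CDS", "CDS-GB-all", "CDS-GB-half", "CDS-GB-none", "CDS-BS75",
      "CDS-LB", "CDS-Slope", "CDS-R2", "CDS-no-outlier", "CDS-codon-align",
      "CDS-codon-align-rm3"))
  # every non-empty matrix keeps valid partition tiling
  for (label in names(grid)) {
    cm <- grid[[label]]
    if (ncol(cm$mat) == 0L) next
    expect_silent(glsignal:::validate_concat_matrix(cm))
    expect_true(label %in% cm$provenance)
  }
  # third-codon removal dropped exactly one third of the columns
  expect_equal(ncol(grid[["CDS-codon-align-rm3"]]$mat),
               2L * ncol(grid[["CDS"]]$mat) / 3L)
})

test_that("dropping optional strategies shrinks the grid accordingly", {
  fx <- grid_fixture(seed = 51)
  cfg <- strategy_config(include_codon_datasets = FALSE)
  g28 <- suppressWarnings(
    build_strategy_grid(fx$cds, fx$igs, fx$diag, fx$sig, cfg))
  expect_equal(unname(grid_family_counts(g28)["total"]), 28L)
  cfg2 <- strategy_config(include_codon_datasets = FALSE,
                          include_block_dataset = FALSE)
  g27 <- suppressWarnings(
    build_strategy_grid(fx$cds, fx$igs, fx$diag, fx$sig, cfg2))
  expect_equal(unname(grid_family_counts(g27)["total"]), 27L)
})

test_that("no-op filters reproduce the base matrix content", {
  fx <- grid_fixture(seed = 52)
  grid <- suppressWarnings(
    build_strategy_grid(fx$cds, fx$igs, fx$diag, fx$sig))
  expect_identical(grid[["CDS-LB"]]$mat, grid[["CDS"]]$mat)
  expect_identical(grid[["IGS-BS75"]]$mat, grid[["IGS"]]$mat)
  expect_identical(grid[["All-Slope"]]$mat, grid[["All"]]$mat)
  expect_identical(grid[["CDS-codon-align"]]$mat, grid[["CDS"]]$mat)
})

test_that("per-category thresholds remove the right loci", {
  fx <- grid_fixture(seed = 53)
  # one CDS locus saturated (slope below CDS shoulder), one IGS locus weak
  fx$diag$slope[fx$diag$locus_id == "cds01"] <- 0.05
  fx$diag$mean_support[fx$diag$locus_id == "igs02"] <- 60
  grid <- suppressWarnings(
    build_strategy_grid(fx$cds, fx$igs, fx$diag, fx$sig))
  expect_false("cds01" %in% grid[["CDS-Slope"]]$partitions$locus_id)
  expect_false("cds01" %in% grid[["All-Slope"]]$partitions$locus_id)
  expect_true("cds01" %in% grid[["CDS"]]$partitions$locus_id)
  expect_false("igs02" %in% grid[["IGS-BS75"]]$partitions$locus_id)
  # a slope of 0.2 passes the CDS shoulder (0.104); the same value would
  # fail the IGS shoulder (0.30)
  fx2 <- grid_fixture(seed = 54)
  fx2$diag$slope[fx2$diag$category == "CDS"] <- 0.2
  grid2 <- suppressWarnings(
    build_strategy_grid(fx2$cds, fx2$igs, fx2$diag, fx2$sig))
  expect_equal(nrow(grid2[["CDS-Slope"]]$partitions), 4L)
  suppressWarnings(expect_error(
    build_strategy_grid(fx2$cds, fx2$igs,
                        within(fx2$diag, slope <- 0.01), fx2$sig),
    "removed every locus"))
})

test_that("outlier flags from the signal table drive the no-outlier sets", {
  # a single extreme value can only exceed 3 sigma when the family is
  # large enough (max |z| is (n-1)/sqrt(n)); use 15 IGS loci
  fx <- grid_fixture(n_igs = 15, seed = 55)
  fx$sig$delta_T1_T2[fx$sig$locus_id == "igs03"] <- -60
  grid <- suppressWarnings(
    build_strategy_grid(fx$cds, fx$igs, fx$diag, fx$sig))
  expect_false("igs03" %in% grid[["IGS-no-outlier"]]$partitions$locus_id)
  expect_true("igs03" %in% grid[["IGS"]]$partitions$locus_id)
})
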