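# End-to-end orchestration: locus filtering, per-locus diagnostics, the
# strategy grid, per-matrix site log-likelihoods under each candidate
# topology, delta-GLS signal, outlier handling and topology tests, with a
# summary table mirroring the per-dataset meta-analysis.

#' Pipeline run configuration
#'
#' @param min_coverage,min_len_cds,min_len_igs Locus-screen thresholds
#'   (defaults 0.55, 100 bp, 50 bp).
#' @param strategy A [strategy_config()].
#' @param model Template [subst_model()] (nucleotide GTR+G by default).
#' @param fit_model Re-fit model parameters on each family's base matrix
#'   (default TRUE); otherwise the template is used as-is.
#' @param settings An [opt_settings()].
#' @param gene_tree_method `"nj"` or `"nni"` gene trees for diagnostics.
#' @param gene_bootstrap_B Bootstrap replicates behind the mean-support
#'   diagnostic (default 25 at desk scale).
#' @param collapse_threshold Support percentage below which gene-tree edges
#'   are collapsed in the emitted gene trees (default 10).
#' @param test_B RELL replicates per topology-test scale (default 10000).
#' @param scales AU-test resampling scales.
#' @param seed Master seed; every random stage derives its seed from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(min_coverage = 0.55, min_len_cds = 100L,
                       min_len_igs = 50L, strategy = strategy_config(),
                       model = subst_model("NT", k = 4L, shape = 1),
                       fit_model = TRUE, settings = opt_settings(),
                       gene_tree_method = "nj", gene_bootstrap_B = 25L,
                       collapse_threshold = 10, test_B = 10000L,
                       scales = seq(0.5, 1.4, by = 0.1), seed = 1L) {
  stopifnot(min_coverage > 0, min_coverage <= 1, test_B >= 1L,
            collapse_threshold >= 0, collapse_threshold <= 100)
  structure(list(min_coverage = min_coverage,
                 min_len_cds = as.integer(min_len_cds),
                 min_len_igs = as.integer(min_len_igs),
                 strategy = strategy, model = model, fit_model = fit_model,
                 settings = settings, gene_tree_method = gene_tree_method,
                 gene_bootstrap_B = as.integer(gene_bootstrap_B),
                 collapse_threshold = collapse_threshold,
                 test_B = as.integer(test_B), scales = scales,
                 seed = as.integer(seed)),
            class = "run_config")
}

prune_to_taxa <- function(tree, taxa) {
  drop <- setdiff(tree$tip.label, taxa)
  if (length(drop)) tree <- ape::drop.tip(tree, drop)
  tree
}

# site-likelihood tables of one matrix under each candidate topology,
# optimising branch lengths per topology under a fixed model
matrix_site_tables <- function(cm, topologies, model, settings) {
  out <- list()
  for (nm in names(topologies)) {
    tr <- prune_to_taxa(topologies[[nm]], cm$taxa)
    opt <- optimize_branch_lengths(cm, tr, model, settings)
    out[[nm]] <- site_loglik(cm, opt$tree, model, topology_id = nm)
  }
  out
}

# Within one run, matrices built from the same loci by pure locus filters
# have identical content; a partition signature lets their site tables be
# computed once and shared.
matrix_signature <- function(cm) {
  p <- cm$partitions
  paste(cm$alphabet, ncol(cm$mat), nrow(cm$mat),
        paste(p$locus_id, p$start, p$end, collapse = ";"),
        paste(grep("rm3|GB-|translate", cm$provenance, value = TRUE),
              collapse = "+"),
        sep = "|")
}

#' Run the full conflict-diagnosis pipeline
#'
#' Stages: coverage/length locus screen, per-locus diagnostics (gene trees,
#' LB scores, saturation regression, bootstrap support), per-family
#' delta-GLS signal, the strategy grid, and per-matrix site
#' log-likelihoods, signal proportions and the five topology tests.
#'
#' @param loci List of [locus_alignment()] objects (CDS and IGS).
#' @param topologies A [topology_set()] of candidate topologies.
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, matrices, tables
#'   and logs are written beneath it.
#' @return List of class `gls_run`: `summary` (one row per matrix and
#'   topology), `proportions`, `grid`, `signal` (per-matrix signal
#'   tables), `diagnostics`, `filter_report`, `gene_trees`, `models`,
#'   `log`.
#' @export
run_pipeline <- function(loci, topologies, config = run_config(),
                         out_dir = NULL) {
  stopifnot(inherits(topologies, "topology_set"))
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))
  n_taxa_total <- length(topologies[[1]]$tip.label)

  flt <- filter_loci(loci, n_taxa_total, config$min_coverage,
                     config$min_len_cds, config$min_len_igs)
  for (i in which(!flt$report$kept))
    note("screen: removed ", flt$report$locus_id[i], " (",
         flt$report$reason[i], ")")
  kept <- flt$kept
  if (length(kept) == 0L) stop("locus screen removed every locus")
  cat_of <- vapply(kept, function(l) l$category, "")
  cds <- kept[cat_of == "CDS"]
  igs <- kept[cat_of != "CDS"]
  if (length(cds) == 0L || length(igs) == 0L)
    stop("need at least one CDS and one IGS locus after screening")
  note("screen: kept ", length(cds), " CDS + ", length(igs), " IGS loci")

  diag <- diagnose_loci(kept, model = config$model,
                        settings = config$settings,
                        tree_method = config$gene_tree_method,
                        bootstrap_B = config$gene_bootstrap_B,
                        seed = config$seed + 10L)
  gene_trees <- attr(diag, "gene_trees")
  if (config$gene_bootstrap_B > 0L)
    gene_trees <- lapply(gene_trees, function(t)
      tryCatch(collapse_low_support(t, config$collapse_threshold),
               error = function(e) t))

  # family base matrices, fitted models, and per-family signal; site tables
  # are cached by content signature so pure locus filters that change
  # nothing (or duplicate a base matrix) are not recomputed
  tab_cache <- new.env(parent = emptyenv())
  cached_tables <- function(cm, fam, mdl) {
    key <- paste(fam, matrix_signature(cm), sep = "||")
    if (!is.null(tab_cache[[key]])) return(tab_cache[[key]])
    tabs <- matrix_site_tables(cm, topologies, mdl, config$settings)
    tab_cache[[key]] <- tabs
    tabs
  }
  fam_loci <- list(CDS = cds, IGS = igs, All = c(cds, igs))
  models <- list()
  fam_signal <- list()
  for (fam in names(fam_loci)) {
    cm <- concatenate(fam_loci[[fam]])
    mdl <- config$model
    if (config$fit_model) {
      tr <- prune_to_taxa(topologies[[1]], cm$taxa)
      fit <- fit_model(cm, tr, config$model, config$settings)
      mdl <- fit$model
      note("model[", fam, "]: lnL ", format(fit$logLik))
    }
    models[[fam]] <- mdl
    tabs <- cached_tables(cm, fam, mdl)
    sig <- gene_wise_gls(tabs, cm$partitions)
    attr(sig, "total_loglik") <- vapply(tabs, function(t) t$logLik, 0)
    fam_signal[[fam]] <- sig
  }

  grid <- build_strategy_grid(cds, igs, diag, fam_signal,
                              config = config$strategy)
  note("grid: ", length(grid), " matrices (",
       paste(names(grid_family_counts(grid))[1:3],
             grid_family_counts(grid)[1:3], sep = "=", collapse = ", "), ")")

  summary_rows <- list()
  prop_rows <- list()
  signal_tables <- list()
  seed_i <- config$seed + 100L
  for (label in names(grid)) {
    cm <- grid[[label]]
    if (matrix_length(cm) == 0L) {
      note("skip ", label, ": empty matrix")
      next
    }
    fam <- sub("-.*$", "", label)
    mdl <- models[[fam]]
    if (cm$alphabet != mdl$alphabet) mdl <- config$model
    tabs <- cached_tables(cm, fam, mdl)
    sig <- gene_wise_gls(tabs, cm$partitions)
    attr(sig, "total_loglik") <- vapply(tabs, function(t) t$logLik, 0)
    signal_tables[[label]] <- sig
    props <- support_proportions(sig, labels = names(topologies))
    prop_rows[[label]] <- data.frame(matrix = label, t(props),
                                     stringsAsFactors = FALSE)
    test_key <- paste("tests", fam, matrix_signature(cm), sep = "||")
    tt <- tab_cache[[test_key]]
    if (is.null(tt)) {
      tt <- topology_tests(tabs, B = config$test_B, scales = config$scales,
                           seed = seed_i)
      tab_cache[[test_key]] <- tt
    }
    seed_i <- seed_i + 10L
    best <- tt$topology[which.max(tt$logLik)]
    summary_rows[[label]] <- data.frame(
      matrix = label, n_loci = nrow(cm$partitions),
      n_sites = matrix_length(cm), supported = best, tt,
      stringsAsFactors = FALSE)
    note("tested ", label, ": best ", best)
  }
  summary <- do.call(rbind, summary_rows)
  proportions <- do.call(rbind, prop_rows)
  rownames(summary) <- rownames(proportions) <- NULL

  res <- structure(list(summary = summary, proportions = proportions,
                        grid = grid, signal = signal_tables,
                        diagnostics = diag, filter_report = flt$report,
                        gene_trees = gene_trees, models = models,
                        log = log, config = config),
                   class = "gls_run")
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

#' @export
print.gls_run <- function(x, ...) {
  cat("<gls_run>", length(x$grid), "matrices;",
      nrow(x$diagnostics), "loci\n")
  tab <- table(x$summary$supported[!duplicated(x$summary$matrix)])
  cat("best topology per matrix:",
      paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  invisible(x)
}

write_tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Write pipeline outputs to a run directory
#'
#' Creates `matrices/`, `trees/` and `tables/` with the grid FASTAs plus
#' partition files, the collapsed gene trees, and all tabular outputs
#' (summary, proportions, diagnostics, per-matrix signal, screen report,
#' log).
#'
#' @param run A `gls_run` from [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  for (d in c("matrices", "trees", "tables"))
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  for (label in names(run$grid)) {
    cm <- run$grid[[label]]
    if (matrix_length(cm) == 0L) next
    write_matrix_fasta(cm, file.path(dir, "matrices", paste0(label, ".fasta")))
  }
  if (length(run$gene_trees)) {
    txt <- vapply(run$gene_trees, write_newick, "")
    writeLines(txt, file.path(dir, "trees", "gene_trees.nwk"))
  }
  write_tsv(run$summary, file.path(dir, "tables", "summary.tsv"))
  write_tsv(run$proportions, file.path(dir, "tables", "proportions.tsv"))
  write_tsv(run$diagnostics, file.path(dir, "tables", "diagnostics.tsv"))
  taxon_lb <- attr(run$diagnostics, "taxon_lb")
  if (!is.null(taxon_lb)) {
    lb_long <- do.call(rbind, lapply(names(taxon_lb), function(id)
      data.frame(locus_id = id, taxon = names(taxon_lb[[id]]),
                 lb = unname(taxon_lb[[id]]), stringsAsFactors = FALSE)))
    write_tsv(lb_long, file.path(dir, "tables", "taxon_lb.tsv"))
  }
  write_tsv(run$filter_report, file.path(dir, "tables", "screen_report.tsv"))
  for (label in names(run$signal))
    write_tsv(run$signal[[label]],
              file.path(dir, "tables", paste0("signal-", label, ".tsv")))
  writeLines(run$log, file.path(dir, "run.log"))
  invisible(dir)
}
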