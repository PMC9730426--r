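# Seeded simulator producing multi-locus datasets with the structure the
# conflict analysis assumes: a dominant history (T1), a minority of loci
# following single-NNI alternative topologies, a saturated subset, planted
# strong-conflict outliers, two locus categories with different rates and
# lengths, and incomplete taxon coverage.

#' Simulation configuration
#'
#' Defaults emulate a desk-scale plastome-like study: 12 taxa, a roughly
#' even mixture of slower in-frame CDS-like loci (300-1500 bp, multiples of
#' 3) and faster IGS-like loci (100-800 bp), lognormal per-locus rate
#' multipliers (median 1), 20\% chance of each taxon missing per locus, a
#' 10-fold rate multiplier for saturated loci, and doubled length for
#' planted outlier loci.
#'
#' @param n_taxa Number of taxa (>= 6).
#' @param n_clean,n_conflict,n_saturated,n_outlier Locus counts per class.
#' @param cds_len_range,igs_len_range Alignment length ranges (bp).
#' @param prop_cds Fraction of loci drawn as CDS-like (default 0.5).
#' @param igs_rate_factor Rate multiplier applied to IGS-like loci
#'   (default 1.5; plastome spacers evolve faster than coding regions).
#' @param rate_sdlog Lognormal sd (log scale) of per-locus rate multipliers.
#' @param saturation_factor Extra rate multiplier of saturated loci
#'   (default 10).
#' @param outlier_rate_factor Extra rate multiplier of planted outlier loci
#'   (default 2): outliers are high-rate, doubled-length conflict loci, so
#'   their gene-wise signal is strong as well as opposed.
#' @param alpha Gamma shape of among-site rate variation (default 1).
#' @param k Gamma categories (default 4).
#' @param missing_prob Per-locus probability that a taxon is dropped
#'   (default 0.2); at least 60\% of taxa (and never fewer than 4) are
#'   always retained.
#' @param seed Mandatory integer seed.
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(n_taxa = 12L, n_clean = 30L, n_conflict = 6L,
                              n_saturated = 6L, n_outlier = 3L,
                              cds_len_range = c(300L, 1500L),
                              igs_len_range = c(100L, 800L),
                              prop_cds = 0.5, igs_rate_factor = 1.5,
                              rate_sdlog = 0.4, saturation_factor = 10,
                              outlier_rate_factor = 2,
                              alpha = 1, k = 4L, missing_prob = 0.2,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_taxa >= 6L, n_clean >= 0L, n_conflict >= 0L,
            n_saturated >= 0L, n_outlier >= 0L,
            all(cds_len_range > 0L), all(igs_len_range > 0L),
            missing_prob >= 0, missing_prob < 1, alpha > 0,
            saturation_factor >= 1)
  if (n_clean + n_conflict + n_saturated + n_outlier == 0L)
    stop("all locus counts are zero")
  structure(list(n_taxa = as.integer(n_taxa), n_clean = as.integer(n_clean),
                 n_conflict = as.integer(n_conflict),
                 n_saturated = as.integer(n_saturated),
                 n_outlier = as.integer(n_outlier),
                 cds_len_range = as.integer(cds_len_range),
                 igs_len_range = as.integer(igs_len_range),
                 prop_cds = prop_cds, igs_rate_factor = igs_rate_factor,
                 rate_sdlog = rate_sdlog,
                 saturation_factor = saturation_factor,
                 outlier_rate_factor = outlier_rate_factor, alpha = alpha,
                 k = as.integer(k), missing_prob = missing_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# the two nearest-neighbour interchanges of one internal edge (u, v),
# done by edge surgery: each child subtree of v is swapped in turn with
# u's other child subtree.  Branch lengths travel with their subtrees, so
# the rearranged trees differ from the input only across the focal edge.
nni_pair <- function(tree, edge_idx) {
  u <- tree$edge[edge_idx, 1]
  v <- tree$edge[edge_idx, 2]
  kids_v <- which(tree$edge[, 1] == v)
  e3 <- setdiff(which(tree$edge[, 1] == u), edge_idx)[1]
  lapply(kids_v[1:2], function(e1) {
    t2 <- tree
    t2$edge[e1, 1] <- u
    t2$edge[e3, 1] <- v
    attr(t2, "order") <- NULL  # force a true reorder after the surgery
    ape::reorder.phylo(t2, "cladewise")
  })
}

#' Generate a base topology and two single-NNI alternatives
#'
#' T1 is a random unrooted binary tree with exponential(10) branch lengths;
#' T2 and T3 are the two nearest-neighbour-interchange rearrangements of
#' one internal edge of T1, keeping all of T1's branch lengths, so that
#' alternative-history loci differ from the dominant history only across
#' the contested split.  Focal edges whose four surrounding subtrees each
#' hold at least two taxa are preferred: the contested split then separates
#' clades, and randomly dropping one taxon from a locus cannot erase the
#' conflict.  All three topologies are pairwise distinct.
#'
#' @param n_taxa Number of taxa (>= 6).
#' @param seed Integer seed.
#' @return A [topology_set()] named `T1`, `T2`, `T3`.
#' @export
make_topology_set <- function(n_taxa, seed) {
  if (n_taxa < 6L) stop("need at least 6 taxa")
  set.seed(seed)
  t1 <- ape::unroot(ape::rtree(n_taxa, br = stats::rexp, rate = 10))
  desc <- phangorn::Descendants(t1, type = "tips")
  internal <- which(t1$edge[, 2] > n_taxa)
  sizes4 <- function(e) {
    u <- t1$edge[e, 1]; v <- t1$edge[e, 2]
    s12 <- lengths(desc[t1$edge[t1$edge[, 1] == v, 2]])
    k3 <- setdiff(t1$edge[t1$edge[, 1] == u, 2], v)[1]
    s3 <- length(desc[[k3]])
    c(s12, s3, n_taxa - sum(s12) - s3)
  }
  balanced <- vapply(internal, function(e) min(sizes4(e)) >= 2L, TRUE)
  # prefer a typical-length focal edge (closest to the exponential mean of
  # 0.1): a near-zero contested edge would carry no signal to conflict
  # over.  Balanced edges of workable length come first; if none exists,
  # any internal edge of typical length beats a degenerate balanced one.
  by_typical <- function(idx)
    idx[order(abs(t1$edge.length[idx] - 0.1))]
  workable <- t1$edge.length[internal] >= 0.03
  cand <- c(by_typical(internal[balanced & workable]),
            by_typical(internal[workable & !balanced]),
            by_typical(internal[!workable]))
  for (e in cand) {
    pair <- nni_pair(t1, e)
    t2 <- pair[[1]]; t3 <- pair[[2]]
    ok <- rf_distance(t1, t2) > 0 && rf_distance(t1, t3) > 0 &&
      rf_distance(t2, t3) > 0
    if (ok) return(topology_set(list(T1 = t1, T2 = t2, T3 = t3)))
  }
  stop("could not find a focal edge with distinct NNI rearrangements")
}

#' Simulate one locus along a tree
#'
#' Ancestral states are drawn from the stationary frequencies and evolved
#' along each branch with transition probabilities under the model's Q;
#' among-site rate variation uses the model's discrete gamma (sites are
#' assigned to categories at random and simulated per category).
#'
#' @param tree `phylo` with branch lengths.
#' @param model A [subst_model()] (`bf = NULL` means uniform frequencies).
#' @param length Number of sites (> 0).
#' @param rate_multiplier Per-locus rate scaling (0 freezes all branches).
#' @param seed Optional integer seed.
#' @param locus_id,category Metadata for the returned alignment.
#' @return A [locus_alignment()].
#' @export
simulate_locus <- function(tree, model, length, rate_multiplier = 1,
                           seed = NULL, locus_id = "locus", category = "OTHER") {
  stopifnot(length > 0L, rate_multiplier >= 0)
  if (!is.null(seed)) set.seed(seed)
  bf <- if (is.null(model$bf)) rep(0.25, 4) else model$bf
  if (rate_multiplier == 0) {
    tree$edge.length[] <- 0
    rate_multiplier <- 1
  }
  n_sites <- as.integer(length)
  rates <- if (model$k > 1L)
    phangorn::discrete.gamma(model$shape, model$k) else 1
  cat_of_site <- sample.int(base::length(rates), n_sites, replace = TRUE)
  mat <- matrix(NA_character_, nrow = base::length(tree$tip.label),
                ncol = n_sites)
  for (g in seq_along(rates)) {
    idx <- which(cat_of_site == g)
    if (base::length(idx) == 0L) next
    sim <- phangorn::simSeq(tree, l = base::length(idx), Q = model$Q, bf = bf,
                            rate = rates[g] * rate_multiplier, type = "DNA")
    sm <- toupper(as.character(sim))  # as.character.phyDat -> char matrix
    if (is.null(rownames(mat))) {
      rownames(mat) <- rownames(sm)
    }
    mat[, idx] <- sm[rownames(mat), , drop = FALSE]
  }
  locus_alignment(locus_id, category, mat, "NT")
}

#' Simulate a full multi-locus study
#'
#' Emits `n_clean` loci evolved on T1, `n_conflict` loci alternating
#' between T2 and T3, `n_saturated` loci on T1 at `saturation_factor` times
#' the rate, and `n_outlier` strong-conflict loci on T2 at doubled length.
#' Locus categories (CDS-like / IGS-like) are assigned at random with
#' probability `prop_cds`; each locus independently drops taxa with
#' probability `missing_prob` (at least 60\% of taxa retained).
#'
#' @param config A [simulation_config()].
#' @return List of class `sim_study`: `loci`, `truth` (data frame:
#'   `locus_id`, `category`, `class`, `topology`, `length`,
#'   `rate_multiplier`, `n_taxa`), `topologies` (a [topology_set()]),
#'   `model`, `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  topo <- make_topology_set(config$n_taxa, config$seed)
  set.seed(config$seed + 1L)
  classes <- c(rep("clean", config$n_clean),
               rep("conflict", config$n_conflict),
               rep("saturated", config$n_saturated),
               rep("outlier", config$n_outlier))
  n <- length(classes)
  conflict_alt <- rep(c("T2", "T3"), length.out = max(config$n_conflict, 1L))
  topo_of <- character(n)
  topo_of[classes == "clean"] <- "T1"
  topo_of[classes == "conflict"] <- conflict_alt[seq_len(config$n_conflict)]
  topo_of[classes == "saturated"] <- "T1"
  topo_of[classes == "outlier"] <- "T2"
  model <- subst_model("NT", Q = rep(1, 6), bf = rep(0.25, 4),
                       shape = config$alpha, k = config$k)
  loci <- vector("list", n)
  truth <- data.frame(locus_id = sprintf("L%03d", seq_len(n)),
                      category = NA_character_, class = classes,
                      topology = topo_of, length = NA_integer_,
                      rate_multiplier = NA_real_, n_taxa = NA_integer_,
                      stringsAsFactors = FALSE)
  min_keep <- max(4L, ceiling(0.6 * config$n_taxa))
  for (i in seq_len(n)) {
    is_cds <- stats::runif(1) < config$prop_cds
    truth$category[i] <- if (is_cds) "CDS" else "IGS"
    rng <- if (is_cds) config$cds_len_range else config$igs_len_range
    len <- sample(rng[1]:rng[2], 1L)
    if (is_cds) len <- max(3L, len - len %% 3L)
    if (classes[i] == "outlier") len <- if (is_cds) 2L * len else 2L * len
    mult <- stats::rlnorm(1, meanlog = 0, sdlog = config$rate_sdlog)
    if (!is_cds) mult <- mult * config$igs_rate_factor
    if (classes[i] == "saturated") mult <- mult * config$saturation_factor
    if (classes[i] == "outlier") mult <- mult * config$outlier_rate_factor
    tr <- topo[[topo_of[i]]]
    loc <- simulate_locus(tr, model, len, rate_multiplier = mult,
                          locus_id = truth$locus_id[i],
                          category = truth$category[i])
    # incomplete taxon coverage: drop taxa whole-locus
    keep <- rep(TRUE, config$n_taxa)
    if (config$missing_prob > 0) {
      repeat {
        keep <- stats::runif(config$n_taxa) >= config$missing_prob
        if (sum(keep) >= min_keep) break
      }
    }
    loc$mat <- loc$mat[sort(rownames(loc$mat))[keep], , drop = FALSE]
    loci[[i]] <- loc
    truth$length[i] <- len
    truth$rate_multiplier[i] <- mult
    truth$n_taxa[i] <- sum(keep)
  }
  structure(list(loci = loci, truth = truth, topologies = topo,
                 model = model, config = config),
            class = "sim_study")
}

#' Write a simulated study to disk
#'
#' Emits one FASTA per locus, a manifest TSV (`locus_id`, `category`,
#' `path`), the truth table TSV and the three topologies as Newick files.
#'
#' @param study A `sim_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(file.path(dir, "loci"), recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(study$loci))
  for (i in seq_along(study$loci)) {
    l <- study$loci[[i]]
    paths[i] <- file.path(dir, "loci", paste0(l$locus_id, ".fasta"))
    cm <- concatenate(list(l))
    write_matrix_fasta(cm, paths[i], partition_path = NULL)
  }
  manifest <- data.frame(locus_id = study$truth$locus_id,
                         category = study$truth$category,
                         path = file.path("loci", basename(paths)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(study$topologies))
    write_newick(study$topologies[[nm]], file.path(dir, paste0(nm, ".nwk")))
  invisible(dir)
}
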