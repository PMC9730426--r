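# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own computation paths (and
# phangorn's likelihood code): transition probabilities come from
# ape::matexpo, likelihoods from explicit enumeration of internal states,
# distances from explicit path walks on the edge table.

# reversible rate matrix from exchangeabilities (AC,AG,AT,CG,CT,GT) and
# frequencies, scaled to one expected substitution per unit time
oracle_Q <- function(ex = rep(1, 6), bf = rep(0.25, 4)) {
  Q <- matrix(0, 4, 4)
  Q[lower.tri(Q)] <- ex
  Q <- Q + t(Q)
  Q <- Q %*% diag(bf)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(bf * diag(Q))
  Q / scale
}

oracle_P <- function(Q, t) ape::matexpo(Q * t)

# Exhaustive-enumeration ln likelihood of a character matrix (rows = taxa,
# entries in A,C,G,T,N,-) on a phylo tree: sums over all internal-state
# assignments.  Single rate class.
oracle_loglik <- function(mat, tree, ex = rep(1, 6), bf = rep(0.25, 4)) {
  states <- c("A", "C", "G", "T")
  Q <- oracle_Q(ex, bf)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)),
              function(e) oracle_P(Q, tree$edge.length[e]))
  root <- ntip + 1L
  internal <- root:(ntip + nnode)
  grid <- as.matrix(expand.grid(rep(list(1:4), nnode)))
  tipstate <- function(ch) if (ch %in% states) match(ch, states) else NA
  total <- 0
  for (site in seq_len(ncol(mat))) {
    obs <- vapply(tree$tip.label, function(tx) tipstate(mat[tx, site]), 0L)
    sitelik <- 0
    for (g in seq_len(nrow(grid))) {
      assign_of <- function(node) {
        if (node <= ntip) obs[node] else grid[g, node - ntip]
      }
      lik <- bf[grid[g, 1]]  # root = first internal node
      ok <- TRUE
      for (e in seq_len(nrow(tree$edge))) {
        par <- tree$edge[e, 1]; kid <- tree$edge[e, 2]
        sp <- assign_of(par); sk <- assign_of(kid)
        if (is.na(sk)) next  # ambiguous tip: sums to 1 over states
        lik <- lik * P[[e]][sp, sk]
      }
      sitelik <- sitelik + lik
    }
    total <- total + log(sitelik)
  }
  total
}

# leaf-to-leaf path distances by explicit walks over the edge table
oracle_patristic <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  dist_from <- function(src) {
    d <- rep(NA_real_, nn); d[src] <- 0
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][k, 1]
        if (is.na(d[u])) { d[u] <- d[v] + adj[[v]][k, 2]; queue <- c(queue, u) }
      }
    }
    d
  }
  out <- matrix(0, ntip, ntip,
                dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) out[i, ] <- dist_from(i)[seq_len(ntip)]
  out
}

# non-trivial splits of an unrooted tree, found by deleting each internal
# edge of the edge table and collecting the tip set below it
oracle_splits <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  keys <- character()
  for (e in seq_len(nrow(tree$edge))) {
    kid <- tree$edge[e, 2]
    if (kid <= ntip) next
    a <- sort(below(kid))
    b <- sort(setdiff(tree$tip.label, a))
    if (length(a) < 2 || length(b) < 2) next
    key <- paste(if (paste(a, collapse = ",") < paste(b, collapse = ","))
      a else b, collapse = ",")
    keys <- c(keys, key)
  }
  sort(unique(keys))
}

oracle_rf <- function(t1, t2) {
  s1 <- oracle_splits(t1); s2 <- oracle_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# small fixture builders ----------------------------------------------------

mk_locus <- function(id, seqs, category = "IGS", alphabet = "NT")
  locus_alignment(id, category, seqs, alphabet)

random_locus <- function(id, taxa, L, category = "IGS", gap_prob = 0,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chars <- c("A", "C", "G", "T")
  m <- matrix(sample(chars, length(taxa) * L, replace = TRUE),
              nrow = length(taxa), dimnames = list(taxa, NULL))
  if (gap_prob > 0)
    m[matrix(runif(length(m)) < gap_prob, nrow = nrow(m))] <- "-"
  locus_alignment(id, category, m, "NT")
}

# a shared small simulated study + pipeline run, computed once per session
shared_cache <- new.env(parent = emptyenv())

shared_study <- function() {
  if (is.null(shared_cache$study)) {
    cfg <- simulation_config(n_taxa = 10, n_clean = 10, n_conflict = 3,
                             n_saturated = 3, n_outlier = 2,
                             cds_len_range = c(300L, 600L),
                             igs_len_range = c(150L, 400L), seed = 7)
    shared_cache$study <- simulate_study(cfg)
  }
  shared_cache$study
}

shared_run <- function() {
  if (is.null(shared_cache$run)) {
    st <- shared_study()
    cfg <- run_config(test_B = 500L, gene_bootstrap_B = 8L, seed = 7)
    shared_cache$run <- suppressWarnings(
      run_pipeline(st$loci, st$topologies, cfg))
  }
  shared_cache$run
}
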