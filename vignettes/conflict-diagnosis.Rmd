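---
title: "Diagnosing topological conflict in multi-locus plastome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing topological conflict in multi-locus plastome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Plastome-scale phylogenies are usually built by concatenating dozens to
hundreds of loci — protein-coding genes (CDS) and faster, gap-rich
intergenic spacers (IGS) — into a supermatrix. When different data
treatments of the same plastomes return different topologies for a
contested node, the question becomes *which loci carry which signal, and
why*. `glsignal` implements the standard diagnosis toolkit for this
situation: per-site and per-gene log-likelihood signal among a small set of
candidate topologies, per-locus saturation and long-branch diagnostics, a
grid of filtered supermatrices, and RELL-based topology tests.

## Signal quantification

For each candidate topology $T$ the package computes, on a fixed matrix,
the per-column log-likelihood (the site-wise score, SLS) under a
time-reversible model with discrete-gamma rate variation, with branch
lengths re-optimised on the whole concatenation under each topology.
Summing SLS over the columns of locus $g$ gives the gene-wise score
$\mathrm{GLS}_g(T)$, and

$$\Delta\mathrm{GLS}_g(T_a, T_b) = \mathrm{GLS}_g(T_a) - \mathrm{GLS}_g(T_b)$$

measures how much locus $g$ prefers $T_a$ over $T_b$. A locus *supports*
the topology with the highest GLS; exact ties (within $10^{-9}$) are
recorded as ambiguous rather than resolved by ordering. Likelihood
evaluation and optimisation are delegated to `phangorn` (Felsenstein
pruning over the discrete-gamma mixture; gaps and `N`/`X` enter as
fully ambiguous states); the identity
$\sum_g \mathrm{GLS}_g(T) = \ln L(T)$ is asserted against `phangorn`'s own
total in the test suite at $10^{-6}$.

Two properties of this statistic shaped design choices:

* **The three-pair mean telescopes.** With three topologies, the mean of
  the oriented differences collapses algebraically:
  $\tfrac13(\Delta_{12} + \Delta_{13} + \Delta_{23}) =
  \tfrac23(\mathrm{GLS}_{T_1} - \mathrm{GLS}_{T_3})$ — the middle topology
  cancels entirely, so a locus that strongly prefers $T_2$ sits near zero
  on that axis. The mean is still reported (`mean_delta`), but outlier
  flagging defaults to the per-pair axes (below).
* **Branch lengths are shared across loci.** Because branch lengths are
  optimised on the concatenation, a topology contradicted by most loci
  gets a near-zero length for its contested edge, which *shrinks* the
  apparent conflict of minority loci. This mirrors how the statistic is
  computed in practice and is worth remembering when interpreting
  $\Delta$GLS magnitudes.

## Outlier loci

Following the three-sigma convention, `outlier_bounds()` reports

$$\mathrm{upper} = \min(\max(x),\ \mu + 3\sigma), \qquad
  \mathrm{lower} = \max(\min(x),\ \mu - 3\sigma)$$

with the sample mean and standard deviation; the min/max capping affects
only the reported bounds, not flags. `signal_outlier_flags()` applies these
bounds to every pairwise $\Delta$GLS axis and flags a locus that escapes
any of them, *sequentially*: after each pass the bounds are recomputed on
the surviving loci and the procedure repeats to a fixed point. The peeling
matters at small locus counts — three outliers of similar magnitude among
thirty loci inflate the first-pass $\sigma$ so much that their maximal
possible z-score is 2.62, below any three-sigma fence; removing the most
extreme first restores the detector. At a few hundred loci the one-pass and
sequential versions rarely differ.

## Per-locus diagnostics and the filter grid

For each locus a gene tree is estimated — by default a neighbour-joining
topology with maximum-likelihood branch lengths, with a likelihood NNI
search available (`tree_method = "nni"`) when gene-tree topology itself is
of interest. From the gene tree and alignment come:

* **LB scores**: taxon $i$'s percentage deviation of its mean patristic
  distance from the tree-wide mean. The per-locus summary
  (`lb_heterogeneity`) is the standard deviation of taxon scores expressed
  on the fractional (0–1) scale, the scale on which the filter's default
  shoulders (0.45 for CDS, 0.90 for IGS) are quoted — a percent-scale
  standard deviation is in the tens for any realistic tree and would make
  those cutoffs degenerate.
* **Saturation regression**: ordinary least squares of uncorrected
  p-distance on patristic distance, intercept forced through zero (zero
  evolutionary distance implies zero observed distance); the uncentred
  $R^2$ convention of zero-intercept fits applies. Shallow slopes and low
  $R^2$ indicate multiple hits have erased signal.
* **Mean bootstrap support** of internal edges, from a standard
  nonparametric bootstrap (column resampling, NNI re-search per replicate).

`build_strategy_grid()` turns these diagnostics into the 30-matrix family
grid: per base family (CDS, IGS, All) the unfiltered concatenation, three
conserved-block trims (gap modes *all*/*half*/*none*), and the BS75, LB,
slope, $R^2$ and no-outlier locus filters; the CDS family adds the
codon-aligned matrix and its third-codon-removed derivative, and the All
family adds a strict whole-matrix block trim (`All-Homblock`). Filter
thresholds are deliberately *configuration inputs*: shoulder positions in
the diagnostic distributions are dataset properties chosen by inspection,
and the defaults are sensible only for data resembling the distributions
they came from. For the synthetic studies below, the slope shoulders sit at
0.25 (CDS) and 0.19 (IGS), between the clean hump (5th percentiles 0.35 and
0.26) and the saturated hump (95th percentiles 0.17 and 0.12) of the
generator's slope distribution. Values exactly at a threshold are kept,
and filters remove whole loci only.

The block trimmer is a re-implementation of the classic conserved-block
algorithm: columns are classified by majority-residue frequency among
non-gap rows (conserved at 0.5, highly conserved at 0.85), the gap mode
removes gap-violating columns outright, runs of more than 8 non-conserved
columns are excised, blocks are trimmed back to highly conserved flanks,
and blocks under 10 columns are dropped. Only the gap mode varies across
the grid. Stricter gap modes always keep a subset of looser modes'
columns; the suite asserts this on random fixtures.

## Topology tests

All tests resample per-site log-likelihoods (RELL; no re-optimisation).
KH compares a topology's observed deficit against its centred replicate
differences from the maximum-likelihood topology (one-sided, so the ML
topology gets $p = 1$); SH uses the maximum over all topologies; the
weighted variants standardise each pairwise difference by its replicate
standard deviation. The AU test runs the bootstrap at ten scales
$r \in \{0.5, \dots, 1.4\}$ and fits
$\mathrm{BP}(r) = 1 - \Phi(d\sqrt{r} + c/\sqrt{r})$ by weighted least
squares on the probit scale with binomial weights (continuity correction
$1/(2B)$ for degenerate proportions), giving $p_{AU} = 1 - \Phi(d - c)$.
The probit-scale WLS fit is simpler to verify than full maximum likelihood
and adequate at the default $B = 10{,}000$; the suite recovers $(d, c)$
exactly from proportions generated by the model. Replicate weights are
multinomial counts built by tabulating uniform site draws, so runs are
bit-reproducible under a seed. Topologies with identical site vectors
receive identical p-values by construction (ties count for every topology
attaining the maximum).

## The synthetic-data generator

`simulate_study()` emits the structure the analysis assumes, so the whole
pipeline runs and is testable with no external data:

* a base topology T1 (random, branch lengths exponential with mean 0.1
  substitutions/site) and two single-NNI rearrangements T2/T3 of one focal
  internal edge, built by edge surgery so T2/T3 inherit *all* of T1's
  branch lengths — alternative-history loci differ from the dominant
  history only across the contested split, as gene-tree conflict does;
* the focal edge is chosen among internal edges whose four surrounding
  subtrees each hold at least two taxa (dropping one taxon can then never
  erase the conflict from a locus) and, among those, the edge closest to
  typical length (0.1) — a near-zero contested edge would carry no signal
  for loci to disagree over;
* locus classes: clean (T1), conflict (alternating T2/T3), saturated (T1
  at 10-fold rate) and planted outliers (T2 at doubled length and doubled
  rate — strong as well as opposed signal);
* two categories: CDS-like (300–1500 bp, in frame, slower) and IGS-like
  (100–800 bp, 1.5-fold faster — plastome spacers evolve faster than
  coding regions); per-locus lognormal rate multipliers (median 1, sdlog
  0.4, so 95% of clean multipliers stay within about [0.45, 2.2], well
  clear of the 10-fold saturated class);
* incomplete coverage: each locus drops each taxon with probability 0.2
  (at least 60% retained), mirroring the trigger of the 55% coverage
  screen.

What the generator does *not* emulate: alignment error and indels (gaps
arise only from missing taxa), codon structure beyond frame (no
selection), rate variation correlated across adjacent loci, and base
compositional heterogeneity across lineages. Passing tests therefore
show the machinery is correct and the statistics behave as designed on
data matching the model's assumptions — not that the filters would make
the same decisions on real plastomes.

## Problem sizes and numerical choices

The test suite runs studies of 10–12 taxa with 20–45 loci and RELL
replicates at $B$ = 300–2000; the acceptance script uses the generator's
default study (12 taxa, 45 loci) with $B = 2000$ and 25 bootstrap
replicates behind the mean-support diagnostic. These sizes were chosen so
a full run completes on a laptop in minutes; all statistics scale
unchanged to larger studies, and `run_config()` exposes every knob
($B = 10{,}000$ and 100+ bootstrap replicates are conventional at
publication scale).

Numerical conventions: branch lengths are bounded to $[10^{-8}, 10]$
substitutions/site with convergence at $10^{-4}$ log-likelihood units;
two-taxon matrices are optimised by bounded one-dimensional search (the
round-robin optimiser needs an internal edge); gamma rate variation uses
four equal-probability categories; GLS ties within $10^{-9}$ are
ambiguous; values exactly at filter thresholds are kept; pipeline stages
derive their seeds from the run seed, so reruns are byte-identical.
Matrices whose trimming removes every column are carried as valid empty
matrices with a warning and skipped by the per-matrix analysis with a log
entry.

## Known limitations

* A single substitution model is fitted per matrix (no per-locus
  partitioned models); the model is fitted once per dataset family and
  shared by that family's matrices.
* The `All-Homblock` matrix approximates collinear-block mining by strict
  block-trimming of the whole concatenation; the label preserves the grid
  structure, not the original algorithm.
* Gene trees default to NJ topology with ML branch lengths for speed;
  likelihood NNI search is available but multiplies diagnostic cost by
  the bootstrap replicate count.
* The multispecies-coalescent species tree is out of scope; gene trees
  (with supports, low-support edges collapsible at 10%) are emitted for
  use by external tools.
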