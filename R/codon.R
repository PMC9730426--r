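# Codon-aware operations on nucleotide supermatrices: third-position removal,
# translation to amino acids, and a reading-frame checker.

# standard genetic code (NCBI table 1)
GENETIC_CODE_1 <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L", CTA = "L",
  CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M", GTT = "V", GTC = "V",
  GTA = "V", GTG = "V", TCT = "S", TCC = "S", TCA = "S", TCG = "S", CCT = "P",
  CCC = "P", CCA = "P", CCG = "P", ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*",
  TAG = "*", CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E", TGT = "C",
  TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R", GGT = "G", GGC = "G", GGA = "G",
  GGG = "G")

check_codon_partitions <- function(cm) {
  if (cm$alphabet != "NT") stop("codon operations require a nucleotide matrix")
  len <- cm$partitions$end - cm$partitions$start
  bad <- len %% 3L != 0L
  if (any(bad))
    stop("frame violation: partition length not divisible by 3 for ",
         paste(cm$partitions$locus_id[bad], collapse = ", "))
  invisible(cm)
}

#' Remove third codon positions
#'
#' Drops the third column of every codon in every partition; partitions must
#' be codon-aligned (length divisible by 3).  Applying the operation twice
#' removes positions again; the provenance label `rm3` records prior
#' application and triggers a warning on re-use.
#'
#' @param cm Nucleotide `concat_matrix` with codon-aligned partitions.
#' @return The reduced matrix (length 2/3 of the input).
#' @export
remove_third_codon <- function(cm) {
  check_codon_partitions(cm)
  if ("rm3" %in% cm$provenance)
    warning("matrix already carries 'rm3' provenance; removing positions again")
  keep <- unlist(lapply(seq_len(nrow(cm$partitions)), function(i) {
    cols <- (cm$partitions$start[i] + 1L):cm$partitions$end[i]
    cols[(seq_along(cols) - 1L) %% 3L != 2L]
  }))
  subset_columns(cm, keep, provenance_add = "rm3")
}

#' Translate a codon-aligned nucleotide matrix to amino acids
#'
#' Whole-gap codons (`---`) become `-`; codons containing `N` or a partial
#' gap become `X`; stop codons become `X` and are counted per locus in the
#' `stop_codons` attribute (with a summary warning when any occur).
#'
#' @param cm Nucleotide `concat_matrix`, codon-aligned.
#' @param table Genetic code id (only 1, the standard code, is supported).
#' @return An amino-acid `concat_matrix` of one third the length.
#' @export
translate_cds <- function(cm, table = 1L) {
  check_codon_partitions(cm)
  if (table != 1L) stop("only the standard genetic code (table = 1) is supported")
  L <- matrix_length(cm)
  n_cod <- L %/% 3L
  first <- seq(1L, L, by = 3L)
  aa <- matrix("X", nrow = length(cm$taxa), ncol = n_cod,
               dimnames = list(cm$taxa, NULL))
  c1 <- cm$mat[, first, drop = FALSE]
  c2 <- cm$mat[, first + 1L, drop = FALSE]
  c3 <- cm$mat[, first + 2L, drop = FALSE]
  cod <- matrix(paste0(c1, c2, c3), nrow = nrow(aa))
  aa[cod == "---"] <- "-"
  known <- cod %in% names(GENETIC_CODE_1)
  aa[known] <- GENETIC_CODE_1[cod[known]]
  stops <- aa == "*"
  aa[stops] <- "X"
  # per-locus stop counts
  p <- cm$partitions
  stopifnot(all(p$start %% 3L == 0L))
  stop_counts <- integer(nrow(p))
  for (i in seq_len(nrow(p))) {
    cods <- (p$start[i] / 3L + 1L):(p$end[i] / 3L)
    stop_counts[i] <- sum(stops[, cods])
  }
  names(stop_counts) <- p$locus_id
  if (any(stop_counts > 0L))
    warning(sum(stop_counts), " internal stop codon(s) translated as 'X'")
  newp <- data.frame(locus_id = p$locus_id, start = p$start / 3L,
                     end = p$end / 3L, category = p$category,
                     stringsAsFactors = FALSE)
  out <- new_concat_matrix(cm$taxa, aa, newp, "AA",
                           c(cm$provenance, "translate"))
  attr(out, "stop_codons") <- stop_counts
  out
}

#' Check the reading frame of one locus
#'
#' Verifies that the alignment length is divisible by 3 and that every gap
#' run in every sequence has a length divisible by 3 (so gaps never shift
#' the frame).  Report-only; sequences are not modified.
#'
#' @param locus A nucleotide [locus_alignment()].
#' @return Data frame of violations (`taxon`, `column`, `problem`); zero rows
#'   when the locus passes.
#' @export
enforce_codon_frame <- function(locus) {
  stopifnot(inherits(locus, "locus_alignment"))
  if (locus$alphabet != "NT") stop("frame check requires nucleotide data")
  out <- data.frame(taxon = character(), column = integer(),
                    problem = character(), stringsAsFactors = FALSE)
  L <- locus_length(locus)
  if (L == 0L)
    return(rbind(out, data.frame(taxon = NA_character_, column = 0L,
                                 problem = "empty")))
  if (L %% 3L != 0L)
    out <- rbind(out, data.frame(taxon = NA_character_, column = L,
                                 problem = "length not divisible by 3"))
  for (tx in locus_taxa(locus)) {
    r <- rle(locus$mat[tx, ] == "-")
    ends <- cumsum(r$lengths)
    bad <- which(r$values & r$lengths %% 3L != 0L)
    for (i in bad)
      out <- rbind(out, data.frame(taxon = tx,
                                   column = ends[i] - r$lengths[i] + 1L,
                                   problem = "gap run breaks frame"))
  }
  rownames(out) <- NULL
  out
}
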