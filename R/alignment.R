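# Core containers: single-locus alignments and concatenated supermatrices.
# Sequences are stored as upper-case character matrices (rows = taxa), which
# keeps column operations (trimming, codon masks) trivial and lets phangorn
# build phyDat objects directly.

NT_CHARS <- c("A", "C", "G", "T", "N", "-")
AA_CHARS <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "-")

#' Construct a single-locus alignment
#'
#' @param locus_id Character scalar identifying the locus.
#' @param category One of `"CDS"`, `"IGS"`, `"OTHER"`.
#' @param seqs Named character vector of equal-length sequences, or a
#'   character matrix with one row per taxon and one column per site.
#' @param alphabet `"NT"` (states A,C,G,T plus N and `-`) or `"AA"`
#'   (20 amino-acid letters plus X and `-`).  Input case is ignored.
#' @return An object of class `locus_alignment` with elements `locus_id`,
#'   `category`, `alphabet` and `mat` (upper-case character matrix).
#' @export
locus_alignment <- function(locus_id, category = c("CDS", "IGS", "OTHER"),
                            seqs, alphabet = c("NT", "AA")) {
  category <- match.arg(category)
  alphabet <- match.arg(alphabet)
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
      stop("sequences must be named by taxon")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment: sequence lengths differ in locus '", locus_id, "'")
    if (lens[1] == 0L) stop("empty alignment in locus '", locus_id, "'")
    mat <- do.call(rbind, strsplit(unname(seqs), ""))
    rownames(mat) <- names(seqs)
  }
  mat[] <- toupper(mat)
  if (is.null(rownames(mat))) stop("sequences must be named by taxon")
  if (anyDuplicated(rownames(mat)))
    stop("duplicate taxon label in locus '", locus_id, "'")
  if (ncol(mat) == 0L) stop("empty alignment in locus '", locus_id, "'")
  legal <- if (alphabet == "NT") NT_CHARS else AA_CHARS
  bad <- setdiff(unique(as.vector(mat)), legal)
  if (length(bad))
    stop("illegal character(s) ", paste(bad, collapse = " "),
         " for alphabet ", alphabet, " in locus '", locus_id, "'")
  structure(list(locus_id = locus_id, category = category,
                 alphabet = alphabet, mat = mat),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment>", x$locus_id, sprintf("[%s, %s]", x$category, x$alphabet),
      nrow(x$mat), "taxa x", ncol(x$mat), "sites\n")
  invisible(x)
}

locus_length <- function(locus) ncol(locus$mat)
locus_taxa <- function(locus) rownames(locus$mat)

#' Read one aligned locus from a FASTA file
#'
#' @param path FASTA file with at least two equal-length records.
#' @param locus_id Locus identifier; defaults to the file base name.
#' @param category Locus category (`"CDS"`, `"IGS"`, `"OTHER"`).
#' @param alphabet `"NT"` or `"AA"`.
#' @return A [locus_alignment()].
#' @export
read_locus_fasta <- function(path, locus_id = sub("\\.[^.]*$", "", basename(path)),
                             category = c("CDS", "IGS", "OTHER"),
                             alphabet = c("NT", "AA")) {
  category <- match.arg(category)
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  type <- if (alphabet == "NT") "DNA" else "AA"
  recs <- suppressWarnings(ape::read.FASTA(path, type = type))
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  if (length(recs) < 2L) stop("need at least 2 records in ", path)
  if (anyDuplicated(names(recs)))
    stop("duplicate header in ", path, ": ",
         names(recs)[duplicated(names(recs))][1])
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment in ", path, " (lengths ",
         paste(sort(unique(lens)), collapse = ", "), ")")
  mat <- toupper(as.character(as.matrix(recs)))
  locus_alignment(locus_id, category, mat, alphabet)
}

#' Concatenate loci into a supermatrix
#'
#' Taxa are the lexicographically sorted union over loci; a taxon absent from
#' a locus is padded with `-` across that locus's columns.  Partitions are
#' recorded in input order as 0-based half-open column intervals.
#'
#' @param loci Non-empty list of [locus_alignment()] objects sharing one
#'   alphabet.
#' @param provenance Character vector of strategy labels to record.
#' @return An object of class `concat_matrix` with elements `taxa`, `mat`,
#'   `partitions` (data.frame `locus_id`, `start`, `end`, `category`),
#'   `alphabet`, `provenance`.
#' @export
concatenate <- function(loci, provenance = character()) {
  if (length(loci) == 0L) stop("empty locus list")
  alph <- unique(vapply(loci, function(l) l$alphabet, ""))
  if (length(alph) != 1L) stop("mixed NT/AA alphabets cannot be concatenated")
  ids <- vapply(loci, function(l) l$locus_id, "")
  if (anyDuplicated(ids)) stop("duplicate locus_id in input")
  taxa <- sort(unique(unlist(lapply(loci, locus_taxa))))
  lens <- vapply(loci, locus_length, 0L)
  ends <- cumsum(lens)
  starts <- ends - lens
  L <- sum(lens)
  mat <- matrix("-", nrow = length(taxa), ncol = L, dimnames = list(taxa, NULL))
  for (i in seq_along(loci)) {
    l <- loci[[i]]
    mat[locus_taxa(l), (starts[i] + 1L):ends[i]] <- l$mat
  }
  partitions <- data.frame(locus_id = ids, start = starts, end = ends,
                           category = vapply(loci, function(l) l$category, ""),
                           stringsAsFactors = FALSE)
  new_concat_matrix(taxa, mat, partitions, alph, provenance)
}

new_concat_matrix <- function(taxa, mat, partitions, alphabet, provenance) {
  stopifnot(identical(rownames(mat), taxa))
  structure(list(taxa = taxa, mat = mat, partitions = partitions,
                 alphabet = alphabet, provenance = provenance),
            class = "concat_matrix")
}

#' @export
print.concat_matrix <- function(x, ...) {
  cat("<concat_matrix>", length(x$taxa), "taxa x", ncol(x$mat), "sites,",
      nrow(x$partitions), "partitions",
      if (length(x$provenance)) paste0("[", paste(x$provenance, collapse = "+"), "]")
      else "", "\n")
  invisible(x)
}

matrix_length <- function(cm) ncol(cm$mat)

validate_concat_matrix <- function(cm) {
  stopifnot(inherits(cm, "concat_matrix"))
  p <- cm$partitions
  L <- matrix_length(cm)
  ord <- order(p$start)
  if (!identical(p$start[ord], c(0L, p$end[ord][-nrow(p)])) &&
      !(nrow(p) == 1L && p$start == 0L))
    stop("partitions are not contiguous")
  if (p$end[ord][nrow(p)] != L || p$start[ord][1] != 0L)
    stop("partitions do not tile [0, L)")
  invisible(cm)
}

# Subset a concat_matrix to a set of kept columns (logical or integer index),
# rebuilding the partition map; zero-length partitions are dropped.
subset_columns <- function(cm, keep, provenance_add = NULL) {
  keep <- if (is.logical(keep)) which(keep) else sort(unique(as.integer(keep)))
  p <- cm$partitions
  kept_per <- integer(nrow(p))
  for (i in seq_len(nrow(p)))
    kept_per[i] <- sum(keep > p$start[i] & keep <= p$end[i])
  ends <- cumsum(kept_per)
  starts <- ends - kept_per
  newp <- data.frame(locus_id = p$locus_id, start = starts, end = ends,
                     category = p$category, stringsAsFactors = FALSE)
  newp <- newp[kept_per > 0L, , drop = FALSE]
  rownames(newp) <- NULL
  mat <- cm$mat[, keep, drop = FALSE]
  out <- new_concat_matrix(cm$taxa, mat, newp, cm$alphabet,
                           c(cm$provenance, provenance_add))
  attr(out, "kept_columns") <- keep
  out
}

# Keep a subset of loci (by locus_id), rebuilding the matrix from scratch so
# taxa that only occurred in dropped loci disappear from the row set.
subset_loci <- function(cm, locus_ids, provenance_add = NULL) {
  p <- cm$partitions
  sel <- p$locus_id %in% locus_ids
  if (!any(sel)) stop("no loci left after filtering")
  loci <- lapply(which(sel), function(i) {
    cols <- (p$start[i] + 1L):p$end[i]
    sub <- cm$mat[, cols, drop = FALSE]
    nongap <- rowSums(sub != "-") > 0L
    locus_alignment(p$locus_id[i], p$category[i], sub[nongap, , drop = FALSE],
                    cm$alphabet)
  })
  concatenate(loci, provenance = c(cm$provenance, provenance_add))
}

#' Write a supermatrix as FASTA plus a RAxML-style partition file
#'
#' The FASTA is wrapped at 80 columns and preserves taxon order.  The
#' partition file (`<path>.partitions` unless given) uses 1-based inclusive
#' coordinates, e.g. `DNA, locA = 1-400`.
#'
#' @param cm A `concat_matrix`.
#' @param path Output FASTA path.
#' @param partition_path Output partition file path; `NULL` skips it.
#' @return `path`, invisibly.
#' @export
write_matrix_fasta <- function(cm, path,
                               partition_path = paste0(path, ".partitions")) {
  stopifnot(inherits(cm, "concat_matrix"))
  if (matrix_length(cm) == 0L || length(cm$taxa) == 0L)
    stop("refusing to write an empty matrix")
  con <- file(path, "w")
  on.exit(close(con))
  seqs <- apply(cm$mat, 1L, paste, collapse = "")
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", cm$taxa[i]), con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = 80L)
    writeLines(substring(s, starts, pmin(starts + 79L, nchar(s))), con)
  }
  if (!is.null(partition_path)) {
    p <- cm$partitions
    tag <- if (cm$alphabet == "NT") "DNA" else "AA"
    writeLines(sprintf("%s, %s = %d-%d", tag, p$locus_id, p$start + 1L, p$end),
               partition_path)
  }
  invisible(path)
}

#' Read a supermatrix written by [write_matrix_fasta()]
#'
#' @param path FASTA path.
#' @param partition_path Partition file path.
#' @param alphabet `"NT"` or `"AA"`.
#' @param categories Optional named vector locus_id -> category.
#' @return A `concat_matrix`.
#' @export
read_matrix_fasta <- function(path, partition_path = paste0(path, ".partitions"),
                              alphabet = c("NT", "AA"), categories = NULL) {
  alphabet <- match.arg(alphabet)
  type <- if (alphabet == "NT") "DNA" else "AA"
  recs <- ape::read.FASTA(path, type = type)
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  mat <- toupper(as.character(as.matrix(recs)))
  lines <- readLines(partition_path)
  m <- regmatches(lines, regexec("^\\s*\\w+,\\s*(\\S+)\\s*=\\s*(\\d+)-(\\d+)\\s*$", lines))
  if (any(lengths(m) != 4L)) stop("malformed partition file: ", partition_path)
  ids <- vapply(m, `[`, "", 2L)
  start <- as.integer(vapply(m, `[`, "", 3L)) - 1L
  end <- as.integer(vapply(m, `[`, "", 4L))
  cat_of <- function(id) {
    if (!is.null(categories) && id %in% names(categories)) categories[[id]] else "OTHER"
  }
  partitions <- data.frame(locus_id = ids, start = start, end = end,
                           category = vapply(ids, cat_of, ""),
                           stringsAsFactors = FALSE)
  cm <- new_concat_matrix(rownames(mat), mat, partitions, alphabet, character())
  validate_concat_matrix(cm)
}
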