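# Tree IO and utilities.  Trees are ape "phylo" objects; bootstrap support
# lives in node.label as percentages in [0, 100].

#' Read a single Newick tree
#'
#' Support values are expected as internal node labels.
#'
#' @param path File containing one Newick tree.
#' @return An ape `phylo`.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree in ", path)
    tr <- tr[[1]]
  }
  if (is.null(tr)) stop("could not parse Newick in ", path)
  validate_tree(tr)
}

#' Write a tree as Newick text
#'
#' @param tree An ape `phylo`.
#' @param path Optional output file; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf label: ",
         tree$tip.label[duplicated(tree$tip.label)][1])
  if (!is.null(tree$edge.length)) {
    if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
      stop("branch lengths must be finite and non-negative")
  }
  tree
}

# numeric supports from node.label; NA where absent/blank (typically the root)
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(NULL)
  suppressWarnings(as.numeric(tree$node.label))
}

#' Patristic (path-length) distances between all leaf pairs
#'
#' @param tree An ape `phylo` with branch lengths.
#' @return Symmetric taxon-by-taxon matrix of path-length sums.
#' @export
patristic_distances <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ape::cophenetic.phylo(tree)
}

#' Collapse poorly supported internal edges into polytomies
#'
#' Internal edges whose support is below `threshold` are contracted; leaf
#' edges and edges at or above the threshold are untouched.
#'
#' @param tree `phylo` with numeric support in `node.label`.
#' @param threshold Support percentage below which edges are collapsed
#'   (default 10).
#' @return The (possibly multifurcating) tree.
#' @export
collapse_low_support <- function(tree, threshold = 10) {
  sup <- node_supports(tree)
  if (is.null(sup)) stop("tree has no support values (node labels)")
  # contract internal (non-root) edges with support < threshold
  ntip <- length(tree$tip.label)
  repeat {
    sup <- node_supports(tree)
    child <- tree$edge[, 2]
    int_edges <- which(child > ntip)
    int_sup <- sup[child[int_edges] - ntip]
    idx <- int_edges[!is.na(int_sup) & int_sup < threshold]
    if (length(idx) == 0L) break
    # contract one edge at a time: reattach the children of the edge's child
    # node to its parent, then rebuild
    e <- idx[1]
    par <- tree$edge[e, 1]; kid <- tree$edge[e, 2]
    len <- if (!is.null(tree$edge.length)) tree$edge.length[e] else NULL
    down <- tree$edge[, 1] == kid
    tree$edge[down, 1] <- par
    tree$edge <- tree$edge[-e, , drop = FALSE]
    if (!is.null(tree$edge.length)) tree$edge.length <- tree$edge.length[-e]
    # drop the removed internal node, renumbering those above it
    tree$node.label <- tree$node.label[-(kid - ntip)]
    tree$edge[tree$edge > kid] <- tree$edge[tree$edge > kid] - 1L
    tree$Nnode <- tree$Nnode - 1L
    ntip <- length(tree$tip.label)
  }
  tree
}

# All non-trivial bipartitions of an unrooted tree, as a character set:
# each split encoded by the lexicographically smaller side's sorted labels.
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- character()
  for (p in parts) {
    if (length(p) <= 1L || length(p) >= ntip - 1L) next
    a <- sort(labs[p]); b <- sort(setdiff(labs, labs[p]))
    key <- if (paste(a, collapse = ",") < paste(b, collapse = ","))
      paste(a, collapse = ",") else paste(b, collapse = ",")
    out <- c(out, key)
  }
  sort(unique(out))
}

# Robinson-Foulds distance via bipartition sets.
rf_distance <- function(t1, t2) {
  b1 <- tree_bipartitions(t1); b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Bundle candidate topologies
#'
#' @param trees Named list of `phylo` objects (e.g. `T1`, `T2`, `T3`)
#'   sharing one leaf set, with pairwise distinct topologies.
#' @return The validated list with class `topology_set`.
#' @export
topology_set <- function(trees) {
  stopifnot(is.list(trees), length(trees) >= 2L, !is.null(names(trees)))
  leaves <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(leaves[-1], identical, TRUE, leaves[[1]])))
    stop("topologies must share one leaf set")
  n <- length(trees)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (rf_distance(trees[[i]], trees[[j]]) == 0L)
      stop("topologies '", names(trees)[i], "' and '", names(trees)[j],
           "' are identical")
  structure(trees, class = c("topology_set", "list"))
}
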