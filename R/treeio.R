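## Tree input/output and structural utilities.
##
## The package represents phylogenies as "phylo" objects from ape, the
## de-facto standard container in R phylogenetics. The functions here add
## the strict validation the downstream likelihood code relies on
## (rootedness, unique labels, finite non-negative branch lengths) and a
## small set of structural queries. Polytomies are accepted throughout;
## branch lengths are interpreted as millions of years (Myr).

#' Parse a Newick string into a validated phylogeny
#'
#' Thin wrapper around [ape::read.tree()] that additionally enforces the
#' structural invariants assumed by every likelihood routine in the
#' package: a single root, unique non-empty tip labels, and finite,
#' non-negative branch lengths on every non-root node.
#'
#' @param text a Newick string (terminated by `;`).
#' @return an object of class `"phylo"`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop(sprintf("malformed Newick: %d '(' but %d ')'", n_open, n_close))
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("malformed Newick: ", conditionMessage(e)),
                   warning = function(w) stop("malformed Newick: ", conditionMessage(w)))
  if (is.null(tree)) stop("malformed Newick: could not parse tree")
  validate_phylo(tree)
  tree
}

#' Read a Newick file into a validated phylogeny
#' @param path path to a `.nwk`/`.tre` file containing one tree.
#' @return an object of class `"phylo"`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Write a phylogeny to Newick
#' @param tree a `"phylo"` object.
#' @param file optional path; if `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths (default 12 so that
#'   parse/write round-trips preserve lengths to at least 10 digits).
#' @return the Newick string, invisibly when writing to file.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Validate the structural invariants of a phylogeny
#'
#' @param tree a `"phylo"` object.
#' @param require_lengths require branch lengths (default TRUE).
#' @return `tree`, invisibly; otherwise an error describing the violation.
#' @export
validate_phylo <- function(tree, require_lengths = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a \"phylo\" object")
  ntip <- length(tree$tip.label)
  if (ntip < 1L) stop("tree has no tips")
  if (any(!nzchar(tree$tip.label))) stop("empty tip label")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  if (require_lengths) {
    if (is.null(tree$edge.length)) stop("tree has no branch lengths")
    bad <- which(!is.finite(tree$edge.length) | tree$edge.length < 0)
    if (length(bad))
      stop(sprintf("invalid branch length %s on edge %d",
                   format(tree$edge.length[bad[1]]), bad[1]))
  }
  nnode <- tree$Nnode
  ntot <- ntip + nnode
  # each non-root node has exactly one parent; connected and acyclic
  # (edge count == nodes - 1 and every non-root node appears once as child)
  child_counts <- tabulate(tree$edge[, 2], nbins = ntot)
  root <- ntip + 1L
  if (nrow(tree$edge) != ntot - 1L)
    stop("tree is not connected/acyclic: edge count != nodes - 1")
  if (child_counts[root] != 0L)
    stop("root node appears as a child; tree is unrooted or malformed")
  if (any(child_counts[-root] != 1L))
    stop("some node does not have exactly one parent")
  invisible(tree)
}

#' Prune a phylogeny to a set of taxa
#'
#' Removes all tips not in `taxa`; internal nodes left with a single child
#' are collapsed with branch lengths summed, so patristic distances among
#' the retained tips are unchanged.
#'
#' @param tree a `"phylo"` object.
#' @param taxa character vector of tip labels to keep (at least 2).
#' @return the pruned `"phylo"` object.
#' @export
prune_to_taxa <- function(tree, taxa) {
  validate_phylo(tree)
  taxa <- unique(as.character(taxa))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("unknown taxa: ", paste(missing, collapse = ", "))
  if (length(taxa) < 2L) stop("need at least 2 taxa to keep")
  ape::keep.tip(tree, taxa)
}

#' Most recent common ancestor of a set of tips
#'
#' @param tree a `"phylo"` object.
#' @param taxa character vector of tip labels (non-empty). A single taxon
#'   returns that tip's node index.
#' @return integer node index (ape numbering: tips `1..Ntip`, then
#'   internal nodes from the root `Ntip+1`).
#' @export
tree_mrca <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  if (!length(taxa)) stop("`taxa` must be non-empty")
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("unknown taxa: ", paste(missing, collapse = ", "))
  if (length(taxa) == 1L) return(match(taxa, tree$tip.label))
  ape::getMRCA(tree, taxa)
}

#' Root-to-node depths
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @return numeric vector of depths (root = 0) for all `Ntip + Nnode`
#'   nodes, in ape node numbering.
#' @export
node_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  depth <- numeric(ntot)
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(tr$edge)))
    depth[tr$edge[i, 2]] <- depth[tr$edge[i, 1]] + tr$edge.length[i]
  depth
}

#' Test whether a tree is ultrametric
#'
#' All root-to-tip depths must agree within `rel_tol` of the maximum
#' depth. This is the sanity check applied to time-calibrated input trees
#' and to the output of the birth-death simulator.
#'
#' @param tree a `"phylo"` object.
#' @param rel_tol relative tolerance (default 1e-6).
#' @return logical.
#' @export
is_ultrametric_tree <- function(tree, rel_tol = 1e-6) {
  validate_phylo(tree)
  if (length(tree$tip.label) < 2L) stop("need >= 2 tips")
  d <- node_depths(tree)[seq_along(tree$tip.label)]
  max(d) - min(d) <= rel_tol * max(d)
}

#' Patristic distances between tips
#'
#' Computed from root-to-tip depths and the shared-path matrix
#' ([ape::vcv.phylo()]), avoiding the all-nodes distance matrix.
#'
#' @param tree a `"phylo"` object.
#' @return symmetric matrix of tip-to-tip path lengths, labelled by tip.
#' @export
patristic_distances <- function(tree) {
  C <- ape::vcv.phylo(tree)
  d <- diag(C)
  D <- outer(d, d, "+") - 2 * C
  D[D < 0] <- 0
  D
}

#' Write a Newick string with per-node bracket annotations
#'
#' Serializes `annotations` (one string per node, ape numbering) as
#' square-bracket comments attached to nodes, e.g.
#' `"(A:1,B:1)[&absent=0.9,partial=0.1,complete=0]:1"`. Used to export
#' ancestral posteriors alongside the topology.
#'
#' @param tree a `"phylo"` object.
#' @param annotations character vector of length `Ntip + Nnode` (empty
#'   strings are omitted).
#' @param file optional output path.
#' @return the annotated Newick string.
#' @export
write_annotated_newick <- function(tree, annotations, file = NULL) {
  validate_phylo(tree)
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  stopifnot(length(annotations) == ntot)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt_node <- function(node) {
    ann <- annotations[node]
    ann <- if (nzchar(ann)) paste0("[", ann, "]") else ""
    if (node <= ntip) return(paste0(tree$tip.label[node], ann))
    kid_edges <- children[[as.character(node)]]
    parts <- vapply(kid_edges, function(e) {
      paste0(fmt_node(tree$edge[e, 2]), ":",
             format(tree$edge.length[e], digits = 12))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")", ann)
  }
  s <- paste0(fmt_node(ntip + 1L), ";")
  if (!is.null(file)) writeLines(s, file)
  s
}
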