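## Family-level robustness analysis: assign each family the ancestral
## strategy with highest posterior at its MRCA in the species-level
## reconstruction, build one-tip-per-family trees from two alternative
## topologies, re-run the reconstruction on both, and pair the results.

#' Assign an ancestral molt strategy to each family
#'
#' For every family, locates the MRCA of its species in the tree and
#' takes the argmax of the marginal posterior there; singleton families
#' use the tip's own posterior (the observed state). Ties are flagged
#' and broken toward the lowest state index (absent < partial <
#' complete).
#'
#' @param tree the species-level tree used for the reconstruction.
#' @param asr an `"asr_states"` object from [marginal_asr()] on `tree`.
#' @param family_map named character vector: species -> family.
#' @return data frame `family`, `state`, `n_species`, `mrca_node`,
#'   `tie_flag`, plus one posterior column per state.
#' @export
assign_family_states <- function(tree, asr, family_map) {
  validate_phylo(tree)
  if (is.null(names(family_map))) stop("`family_map` must be named by species")
  missing <- setdiff(names(family_map), tree$tip.label)
  if (length(missing))
    stop("species not in tree: ", paste(utils::head(missing, 5), collapse = ", "))
  states <- asr$states
  fams <- split(names(family_map), unname(family_map))
  rows <- lapply(names(fams), function(f) {
    sp <- fams[[f]]
    node <- tree_mrca(tree, sp)
    post <- asr$posterior[node, ]
    mx <- max(post)
    tie <- sum(post >= mx - 1e-12) > 1L
    st <- states[which(post >= mx - 1e-12)[1]]
    out <- data.frame(family = f, state = st, n_species = length(sp),
                      mrca_node = node, tie_flag = tie,
                      stringsAsFactors = FALSE)
    cbind(out, as.data.frame(as.list(post)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a one-tip-per-family tree from a species tree
#'
#' Keeps one representative species per family (by default the
#' alphabetically first, which makes the construction deterministic and
#' invariant to input row order) and relabels the retained tips with
#' family names.
#'
#' @param species_tree a `"phylo"` object.
#' @param family_map named character vector: species -> family (must
#'   cover >= 2 families).
#' @param representative_rule only `"alphabetical"` is provided.
#' @return a `"phylo"` object with one tip per family; the chosen
#'   representatives are recorded in attribute `"representatives"`.
#' @export
build_family_tree <- function(species_tree, family_map,
                              representative_rule = "alphabetical") {
  representative_rule <- match.arg(representative_rule, "alphabetical")
  validate_phylo(species_tree)
  missing <- setdiff(names(family_map), species_tree$tip.label)
  if (length(missing))
    stop("species not in tree: ", paste(utils::head(missing, 5), collapse = ", "))
  fams <- split(names(family_map), unname(family_map))
  reps <- vapply(fams, function(sp) sort(sp)[1], character(1))
  if (length(reps) < 2L) stop("need >= 2 families")
  tr <- prune_to_taxa(species_tree, unname(reps))
  tr$tip.label <- names(reps)[match(tr$tip.label, unname(reps))]
  attr(tr, "representatives") <- reps
  tr
}

#' Compare ancestral reconstructions on two alternative topologies
#'
#' Runs the fit/select/reconstruct pipeline on both trees with the same
#' per-family states and reports the paired root posteriors together
#' with the tip-to-tip correspondence table (the data behind a
#' tanglegram).
#'
#' @param tree_a,tree_b `"phylo"` objects with identical (family) tip
#'   sets.
#' @param family_states named state vector over the shared tips.
#' @param ... passed to [asr_pipeline()] (root prior, seed, ...).
#' @return an object of class `"topology_comparison"`: `pipeline_a`,
#'   `pipeline_b`, `root_posteriors` (2 x k matrix), `pairing` (family,
#'   tip index in each tree).
#' @export
compare_topologies <- function(tree_a, tree_b, family_states, ...) {
  validate_phylo(tree_a); validate_phylo(tree_b)
  d1 <- setdiff(tree_a$tip.label, tree_b$tip.label)
  d2 <- setdiff(tree_b$tip.label, tree_a$tip.label)
  if (length(d1) || length(d2))
    stop("tip sets differ: only in A: ", paste(d1, collapse = ","),
         "; only in B: ", paste(d2, collapse = ","))
  pa <- asr_pipeline(tree_a, family_states, ...)
  pb <- asr_pipeline(tree_b, family_states, ...)
  rp <- rbind(tree_a = pa$asr$root_posterior, tree_b = pb$asr$root_posterior)
  pairing <- data.frame(
    family = tree_a$tip.label,
    tip_a = seq_along(tree_a$tip.label),
    tip_b = match(tree_a$tip.label, tree_b$tip.label),
    stringsAsFactors = FALSE)
  structure(list(pipeline_a = pa, pipeline_b = pb, root_posteriors = rp,
                 pairing = pairing),
            class = "topology_comparison")
}

#' @export
print.topology_comparison <- function(x, ...) {
  cat(sprintf("Dual-topology comparison over %d shared tips\n",
              nrow(x$pairing)))
  cat(sprintf("  models: %s (A) vs %s (B)\n",
              x$pipeline_a$selection$selected, x$pipeline_b$selection$selected))
  cat("  root posteriors:\n")
  print(round(x$root_posteriors, 4))
  invisible(x)
}
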