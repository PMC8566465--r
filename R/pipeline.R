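## End-to-end orchestration: validate and name-match the inputs, fit and
## select the Mk models, reconstruct ancestral molt strategies and body
## mass, run the phylogenetic logistic regressions (full sample and
## eligible orders), and write a deterministic report bundle.

#' Run the full molt-evolution analysis
#'
#' Produces the complete report bundle: (a) the Mk model-selection table
#' with delta-AICc, (b) per-node ancestral posteriors (CSV + annotated
#' Newick), (c) the Brownian-motion body-mass reconstruction, (d) the
#' univariate phylogenetic logistic regressions of strategy on mass and
#' latitude, (e) descriptive summaries by strategy group, (f) order-level
#' regressions for eligible orders, and (g) a run manifest. All outputs
#' are deterministic given the inputs and `seed`; reruns are
#' byte-identical.
#'
#' @param tree a `"phylo"` object or path to a Newick file.
#' @param table a `"trait_table"` or path to a trait CSV.
#' @param output_dir directory for the report bundle (created if
#'   needed); `NULL` returns results without writing.
#' @param root_prior root prior policy for the Mk fits (default flat).
#' @param models Mk model classes to compare.
#' @param aicc_threshold decisiveness threshold (default 2).
#' @param exclude_bdpr drop species flagged as placed without genetic
#'   data before all analyses (default FALSE).
#' @param mass_transform `"none"` (default) or `"log10"` for the BM
#'   reconstruction.
#' @param order_min_count per-category minimum for order-level
#'   regressions (default 21, i.e. > 20).
#' @param n_restarts,seed optimizer restart controls.
#' @return an object of class `"molt_analysis"` with elements
#'   `selection`, `asr`, `bm`, `bm_nodes`, `phyloglm`, `order_fits`,
#'   `summaries`, `manifest` (and `output_dir` when written).
#' @export
run_full_analysis <- function(tree, table, output_dir = NULL,
                              root_prior = "flat",
                              models = c("ER", "SYM", "ARD"),
                              aicc_threshold = 2.0,
                              exclude_bdpr = FALSE,
                              mass_transform = c("none", "log10"),
                              order_min_count = 21L,
                              n_restarts = 5L, seed = 1L) {
  mass_transform <- match.arg(mass_transform)
  if (is.character(tree)) tree <- read_newick(tree)
  if (is.character(table)) table <- load_species_table(table)
  stopifnot(inherits(table, "trait_table"))
  n_input <- nrow(table)
  if (exclude_bdpr) {
    dropped <- normalize_species_names(table$species[table$bdpr_flag])
    table <- table[!table$bdpr_flag, , drop = FALSE]
    class(table) <- c("trait_table", "data.frame")
    keep_tips <- tree$tip.label[
      !normalize_species_names(tree$tip.label) %in% dropped]
    if (length(keep_tips) < length(tree$tip.label))
      tree <- prune_to_taxa(tree, keep_tips)
  }
  m <- match_tree_table(tree, table)
  tree <- m$tree; table <- m$table

  tip_states <- stats::setNames(as.character(table$molt_strategy),
                                table$species)

  pipe <- asr_pipeline(tree, tip_states, root_prior = root_prior,
                       models = models, threshold = aicc_threshold,
                       n_restarts = n_restarts, seed = seed)

  mass <- stats::setNames(table$body_mass_g, table$species)
  bm <- fit_bm(tree, mass, trait_transform = mass_transform)
  bm_nodes <- bm_asr(tree, mass, bm)

  summaries <- summarize_by_strategy(table)

  cb <- code_binary(table)
  reg_tree <- prune_to_taxa(tree, cb$species)
  uni <- univariate_table(reg_tree, cb$y, cb$X)

  eligible <- order_subsets(table, min_per_category = order_min_count)
  order_fits <- lapply(eligible, function(o) {
    sub <- table[table$order == o, , drop = FALSE]
    class(sub) <- c("trait_table", "data.frame")
    cbo <- code_binary(sub)
    tro <- prune_to_taxa(tree, cbo$species)
    tryCatch(univariate_table(tro, cbo$y, cbo$X),
             error = function(e) structure(conditionMessage(e),
                                           class = "order_fit_error"))
  })
  names(order_fits) <- eligible

  manifest <- list(
    package = "moltevol",
    version = as.character(utils::packageVersion("moltevol")),
    seed = seed,
    config = list(root_prior = root_prior, models = models,
                  aicc_threshold = aicc_threshold,
                  exclude_bdpr = exclude_bdpr,
                  mass_transform = mass_transform,
                  order_min_count = order_min_count,
                  n_restarts = n_restarts),
    n_species_input = n_input,
    n_species_analyzed = nrow(table),
    n_regression = length(cb$y),
    strategy_counts = as.list(table(table$molt_strategy)),
    eligible_orders = eligible,
    selected_model = pipe$selection$selected,
    input_hash = list(
      tree = unname(tools::md5sum(textConnection_md5(write_newick(tree)))),
      table = unname(tools::md5sum(textConnection_md5(
        paste(utils::capture.output(utils::write.csv(as.data.frame(table),
                                                     row.names = FALSE)),
              collapse = "\n"))))))

  res <- structure(list(tree = tree, table = table,
                        selection = pipe$selection, fits = pipe$fits,
                        asr = pipe$asr, bm = bm, bm_nodes = bm_nodes,
                        phyloglm = uni, order_fits = order_fits,
                        summaries = summaries, manifest = manifest),
                   class = "molt_analysis")
  if (!is.null(output_dir)) {
    write_analysis_bundle(res, output_dir)
    res$output_dir <- output_dir
  }
  res
}

# md5 of a string via a temp file (tools::md5sum wants a path)
textConnection_md5 <- function(x) {
  f <- tempfile()
  writeLines(x, f)
  f
}

#' Write the report bundle of a full analysis
#' @param res a `"molt_analysis"` object.
#' @param output_dir target directory.
#' @return `output_dir`, invisibly.
#' @export
write_analysis_bundle <- function(res, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(output_dir, ...)
  utils::write.csv(res$selection$table, p("model_selection.csv"),
                   row.names = FALSE)
  utils::write.csv(asr_table(res$asr, internal_only = FALSE),
                   p("node_posteriors.csv"), row.names = FALSE)
  asr_annotated_newick(res$asr, file = p("asr_annotated.nwk"))
  utils::write.csv(res$bm_nodes, p("bm_mass_nodes.csv"), row.names = FALSE)
  utils::write.csv(phyloglm_summary_table(res$phyloglm),
                   p("phyloglm_table.csv"), row.names = FALSE)
  utils::write.csv(res$summaries, p("descriptive_summaries.csv"),
                   row.names = FALSE)
  order_tab <- do.call(rbind, lapply(names(res$order_fits), function(o) {
    f <- res$order_fits[[o]]
    if (inherits(f, "order_fit_error"))
      return(data.frame(order = o, parameter = NA, alpha = NA,
                        estimate = NA, se = NA, z = NA, p = NA, n = NA,
                        error = as.character(f), stringsAsFactors = FALSE))
    cbind(order = o, phyloglm_summary_table(f), error = "")
  }))
  if (is.null(order_tab))
    order_tab <- data.frame(order = character(), parameter = character(),
                            alpha = numeric(), estimate = numeric(),
                            se = numeric(), z = numeric(), p = numeric(),
                            n = integer(), error = character())
  utils::write.csv(order_tab, p("order_level_phyloglm.csv"),
                   row.names = FALSE)
  mk_json <- list(
    selected = res$selection$selected,
    decisive = res$selection$decisive,
    table = res$selection$table,
    rates = as.list(res$selection$fit$rates),
    root_posterior = as.list(res$asr$root_posterior))
  jsonlite::write_json(mk_json, p("mk_fit.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(output_dir)
}

#' @export
print.molt_analysis <- function(x, ...) {
  cat(sprintf("Molt-strategy analysis: %d species (%d in regression subset)\n",
              x$manifest$n_species_analyzed, x$manifest$n_regression))
  print(x$selection)
  cat("root posterior:\n")
  print(round(x$asr$root_posterior, 4))
  cat(sprintf("BM mass: root %.4g, sigma2 %.4g\n",
              x$bm$root_value, x$bm$sigma2))
  print(phyloglm_summary_table(x$phyloglm), row.names = FALSE)
  invisible(x)
}

#' Run the family-level dual-topology analysis
#'
#' Assigns each family an ancestral strategy from a species-level
#' reconstruction, builds a one-tip-per-family tree from the species
#' tree, and compares reconstructions between that tree and an
#' alternative family-level topology.
#'
#' @param species_tree species-level `"phylo"` (or Newick path).
#' @param table `"trait_table"` (or CSV path) with the family column.
#' @param alt_family_tree alternative family-level `"phylo"` (or Newick
#'   path) whose tips are family names; must cover the same families.
#' @param species_asr optional precomputed `"asr_states"` on the species
#'   tree (e.g. from [run_full_analysis()]); computed if missing.
#' @param output_dir optional directory for the paired report.
#' @param ... passed to [asr_pipeline()].
#' @return an object of class `"family_analysis"`: `assignments`,
#'   `family_tree` (from the species tree), `comparison`
#'   (`"topology_comparison"`).
#' @export
run_family_analysis <- function(species_tree, table, alt_family_tree,
                                species_asr = NULL, output_dir = NULL,
                                ...) {
  if (is.character(species_tree)) species_tree <- read_newick(species_tree)
  if (is.character(table)) table <- load_species_table(table)
  if (is.character(alt_family_tree))
    alt_family_tree <- read_newick(alt_family_tree)
  m <- match_tree_table(species_tree, table)
  species_tree <- m$tree; table <- m$table
  fam_map <- stats::setNames(as.character(table$family), table$species)
  if (is.null(species_asr)) {
    tip_states <- stats::setNames(as.character(table$molt_strategy),
                                  table$species)
    species_asr <- asr_pipeline(species_tree, tip_states, ...)$asr
  }
  assignments <- assign_family_states(species_tree, species_asr, fam_map)
  fam_tree <- build_family_tree(species_tree, fam_map)
  fam_states <- stats::setNames(assignments$state, assignments$family)
  comparison <- compare_topologies(fam_tree, alt_family_tree, fam_states,
                                   ...)
  res <- structure(list(assignments = assignments, family_tree = fam_tree,
                        comparison = comparison),
                   class = "family_analysis")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(assignments,
                     file.path(output_dir, "family_assignments.csv"),
                     row.names = FALSE)
    utils::write.csv(comparison$pairing,
                     file.path(output_dir, "family_pairing.csv"),
                     row.names = FALSE)
    asr_annotated_newick(comparison$pipeline_a$asr,
                         file = file.path(output_dir, "family_tree_a.nwk"))
    asr_annotated_newick(comparison$pipeline_b$asr,
                         file = file.path(output_dir, "family_tree_b.nwk"))
    utils::write.csv(as.data.frame(comparison$root_posteriors),
                     file.path(output_dir, "family_root_posteriors.csv"))
    res$output_dir <- output_dir
  }
  res
}

#' @export
print.family_analysis <- function(x, ...) {
  cat(sprintf("Family-level analysis: %d families\n", nrow(x$assignments)))
  print(table(x$assignments$state))
  print(x$comparison)
  invisible(x)
}
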