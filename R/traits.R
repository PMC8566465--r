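## Species trait table: schema validation, the latitude index, binary
## coding for the regression stage, descriptive summaries, and
## order-level subset selection.
##
## CSV schema (one row per species):
##   species, order, family, molt_strategy, body_mass_g,
##   mid_latitude_deg, bdpr_flag
## molt_strategy is one of absent/partial/complete (case-insensitive);
## body_mass_g > 0 (grams); mid_latitude_deg in [0, 90] (absolute
## degrees from the equator); bdpr_flag marks species placed in the tree
## without genetic data (birth-death polytomy resolution).

TRAIT_COLUMNS <- c("species", "order", "family", "molt_strategy",
                   "body_mass_g", "mid_latitude_deg", "bdpr_flag")

#' Validate a species trait data frame
#'
#' @param df data frame with the trait-table columns.
#' @param source optional provenance string recorded as an attribute.
#' @return the validated data frame (class `c("trait_table",
#'   "data.frame")`), with `molt_strategy` as a factor in canonical
#'   order and `bdpr_flag` logical.
#' @export
as_trait_table <- function(df, source = NA_character_) {
  missing_cols <- setdiff(TRAIT_COLUMNS, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[TRAIT_COLUMNS]
  df$species <- as.character(df$species)
  dup <- unique(df$species[duplicated(df$species)])
  if (length(dup))
    stop("duplicate species: ", paste(utils::head(dup, 5), collapse = ", "))
  strat <- tolower(trimws(as.character(df$molt_strategy)))
  bad <- which(!strat %in% molt_states())
  if (length(bad))
    stop(sprintf("row %d: invalid molt_strategy '%s'", bad[1],
                 df$molt_strategy[bad[1]]))
  df$molt_strategy <- factor(strat, levels = molt_states())
  df$body_mass_g <- as.numeric(df$body_mass_g)
  bad <- which(!is.finite(df$body_mass_g) | df$body_mass_g <= 0)
  if (length(bad))
    stop(sprintf("row %d: body_mass_g must be positive and finite", bad[1]))
  df$mid_latitude_deg <- as.numeric(df$mid_latitude_deg)
  bad <- which(!is.finite(df$mid_latitude_deg) |
                 df$mid_latitude_deg < 0 | df$mid_latitude_deg > 90)
  if (length(bad))
    stop(sprintf("row %d: mid_latitude_deg must be in [0, 90]", bad[1]))
  df$bdpr_flag <- as.logical(df$bdpr_flag)
  if (anyNA(df$bdpr_flag)) stop("bdpr_flag must be TRUE/FALSE")
  attr(df, "source") <- source
  attr(df, "n_rows") <- nrow(df)
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Load a species trait table from CSV
#' @param path CSV file with the trait-table schema (UTF-8).
#' @return a validated `"trait_table"` data frame.
#' @export
load_species_table <- function(path) {
  if (!file.exists(path)) stop("trait table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  as_trait_table(df, source = path)
}

#' Write a trait table to CSV
#' @param table a `"trait_table"`.
#' @param path output CSV path.
#' @export
write_species_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Absolute mid-distribution latitude
#'
#' The latitude index of a species: absolute value of the midpoint of
#' its full annual latitudinal range, in degrees from the equator.
#'
#' @param lat_south,lat_north signed southern/northern range extremes in
#'   degrees, `-90 <= lat_south <= lat_north <= 90` (vectorized).
#' @return absolute mid-latitude in degrees.
#' @examples
#' latitude_index(-10, 30)   # 10
#' latitude_index(-40, -20)  # 30
#' @export
latitude_index <- function(lat_south, lat_north) {
  if (any(lat_south < -90 | lat_north > 90))
    stop("latitudes must be within [-90, 90]")
  if (any(lat_south > lat_north))
    stop("reversed bounds: lat_south > lat_north")
  abs((lat_south + lat_north) / 2)
}

#' Binary coding of molt strategy for regression
#'
#' Excludes partial-molt species (whose molt extent cannot be placed in
#' either category) and codes complete = 1, absent = 0.
#'
#' @param table a `"trait_table"`.
#' @return list with `y` (named 0/1 vector), `X` (matrix with columns
#'   `body_mass_g`, `mid_latitude_deg`, species rownames), `species`
#'   (retained names), `n_excluded` (partial-molt count).
#' @export
code_binary <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  keep <- table$molt_strategy != "partial"
  if (!any(keep)) stop("no complete/absent species left after exclusion")
  tab <- table[keep, , drop = FALSE]
  y <- as.numeric(tab$molt_strategy == "complete")
  names(y) <- tab$species
  X <- cbind(body_mass_g = tab$body_mass_g,
             mid_latitude_deg = tab$mid_latitude_deg)
  rownames(X) <- tab$species
  list(y = y, X = X, species = tab$species, n_excluded = sum(!keep))
}

#' Descriptive summaries by molt-strategy grouping
#'
#' Summarizes body mass and latitude for the complete-molt group versus
#' the pooled partial+absent group (the contrast used in descriptive
#' results), plus each strategy separately. SD uses the sample (n-1)
#' denominator.
#'
#' @param table a `"trait_table"`.
#' @return data frame with columns group, variable, n, mean, sd, min,
#'   max. Empty groups yield `NaN` statistics and are flagged via n = 0.
#' @export
summarize_by_strategy <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  groups <- list(
    complete = table$molt_strategy == "complete",
    partial_absent = table$molt_strategy %in% c("partial", "absent"),
    partial = table$molt_strategy == "partial",
    absent = table$molt_strategy == "absent"
  )
  vars <- c(body_mass_g = "body_mass_g", mid_latitude_deg = "mid_latitude_deg")
  rows <- list()
  for (g in names(groups)) for (v in names(vars)) {
    x <- table[[vars[v]]][groups[[g]]]
    rows[[paste(g, v)]] <- data.frame(
      group = g, variable = v, n = length(x),
      mean = if (length(x)) mean(x) else NaN,
      sd = if (length(x) > 1) stats::sd(x) else NaN,
      min = if (length(x)) min(x) else NaN,
      max = if (length(x)) max(x) else NaN,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Orders eligible for order-level regression
#'
#' Returns the orders in which both the complete and the absent strategy
#' have more than `min_per_category - 1` species (default: more than 20
#' in each category).
#'
#' @param table a `"trait_table"`.
#' @param min_per_category minimum count per category (default 21, i.e.
#'   strictly more than 20).
#' @return character vector of order names.
#' @export
order_subsets <- function(table, min_per_category = 21L) {
  stopifnot(inherits(table, "trait_table"))
  tab <- table(order = table$order, strategy = table$molt_strategy)
  ok <- tab[, "complete"] >= min_per_category & tab[, "absent"] >= min_per_category
  sort(rownames(tab)[ok])
}

#' Match a trait table against a tree's tips
#'
#' Species matching is exact after underscore/space normalization and
#' case folding. Mismatches in either direction are reported.
#'
#' @param tree a `"phylo"` object.
#' @param table a `"trait_table"`.
#' @param error if TRUE (default) mismatches are an error, else a
#'   warning and the intersection is returned.
#' @return list `tree`, `table` restricted to the common species, with
#'   table rows ordered to match (tree tip labels are kept as-is).
#' @export
match_tree_table <- function(tree, table, error = TRUE) {
  validate_phylo(tree)
  stopifnot(inherits(table, "trait_table"))
  tip_norm <- normalize_species_names(tree$tip.label)
  sp_norm <- normalize_species_names(table$species)
  only_tree <- tree$tip.label[!tip_norm %in% sp_norm]
  only_table <- table$species[!sp_norm %in% tip_norm]
  if (length(only_tree) || length(only_table)) {
    msg <- sprintf("name mismatch: %d tips without trait rows (%s...), %d rows without tips (%s...)",
                   length(only_tree), paste(utils::head(only_tree, 3), collapse = ","),
                   length(only_table), paste(utils::head(only_table, 3), collapse = ","))
    if (error) stop(msg) else warning(msg)
  }
  keep_tips <- tree$tip.label[tip_norm %in% sp_norm]
  tr <- if (length(keep_tips) < length(tree$tip.label))
    prune_to_taxa(tree, keep_tips) else tree
  idx <- match(normalize_species_names(tr$tip.label), sp_norm)
  tab <- table[idx, , drop = FALSE]
  tab$species <- tr$tip.label  # align naming to the tree's convention
  class(tab) <- c("trait_table", "data.frame")
  list(tree = tr, table = tab)
}
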