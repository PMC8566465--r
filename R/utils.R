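#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a local, restorable RNG state
#'
#' All stochastic functions in the package funnel their randomness through
#' this helper so that a single integer seed makes a whole analysis
#' reproducible without clobbering the caller's RNG.
#'
#' @param seed single integer seed (must be < 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite integer")
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a child seed deterministically, staying within 32-bit integer range
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483587L
}

#' Molt-strategy state labels in canonical order
#'
#' The package fixes the state order `absent < partial < complete`
#' everywhere (rate indexing, posterior vectors, output columns).
#'
#' @return character vector of length 3.
#' @export
molt_states <- function() c("absent", "partial", "complete")

# normalize species names for tree/table matching: underscores vs spaces,
# case folding
normalize_species_names <- function(x) {
  x <- gsub("[ ]+", "_", trimws(as.character(x)))
  tolower(x)
}
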