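## Marginal (empirical-Bayes) ancestral state reconstruction under an Mk
## model: one post-order ("down") pass computing conditional likelihoods
## of each subtree, one pre-order ("up") pass propagating the likelihood
## of the rest of the tree, combined into exact per-node posteriors with
## the rate parameters held fixed. This is the up-down algorithm; it is
## mathematically identical to re-rooting the tree at every node but
## costs a single O(n) sweep per direction.

#' Marginal ancestral state posteriors under a fixed Mk generator
#'
#' For every node `v`, computes `P(state(v) = s | tip data)` exactly (no
#' sampling), with the generator fixed (empirical Bayes). Tips with
#' observed states get unit-vector posteriors; missing tips get genuine
#' posteriors.
#'
#' @inheritParams mk_loglik
#' @return an object of class `"asr_states"`: `posterior` (matrix
#'   `(Ntip + Nnode) x k`, rows = ape node numbering, columns = states),
#'   `root_posterior`, `logL`, and the tree.
#' @export
marginal_asr <- function(tree, tip_states, Q, root_prior = "flat") {
  prep <- mk_prep(tree)
  tr <- prep$tree
  k <- nrow(Q)
  states <- if (!is.null(rownames(Q))) rownames(Q) else molt_states()
  L <- mk_tip_matrix(prep, tip_states, k = k, states = states)
  dp <- mk_down_pass(prep, L, Q, keep_contrib = TRUE)
  L <- dp$L
  prior <- resolve_root_prior(root_prior, Q, L_root = L[prep$root, ], k = k)
  lik_root <- sum(prior * L[prep$root, ])
  if (lik_root <= 0) stop("data have zero likelihood under this generator")
  logL <- log(lik_root) + dp$logscale

  E <- prep$edge
  ntot <- prep$ntot
  # per-edge transition matrices (child conditioned on parent)
  Parr <- transition_probs(Q, prep$el)
  if (length(prep$el) == 1L) Parr <- array(Parr, c(k, k, 1))
  children_of <- split(seq_len(nrow(E)), E[, 1])

  FF <- matrix(0, ntot, k)           # upward (outside) partials
  FF[prep$root, ] <- prior
  # pre-order = reverse post-order over edges
  for (i in rev(seq_len(nrow(E)))) {
    p <- E[i, 1]; ch <- E[i, 2]
    sibs <- setdiff(children_of[[as.character(p)]], i)
    g <- FF[p, ]
    for (s in sibs) g <- g * dp$contrib[s, ]
    FF[ch, ] <- as.vector(g %*% Parr[, , i])
    m <- max(FF[ch, ])
    if (m > 0) FF[ch, ] <- FF[ch, ] / m
  }
  post <- L * FF
  rs <- rowSums(post)
  if (any(rs <= 0)) stop("zero posterior mass at some node")
  post <- post / rs
  colnames(post) <- states
  structure(list(posterior = post, root_posterior = post[prep$root, ],
                 root = prep$root, logL = logL, tree = tr, states = states,
                 root_prior = prior),
            class = "asr_states")
}

#' @export
print.asr_states <- function(x, ...) {
  cat(sprintf("Marginal ancestral state reconstruction (%d nodes, logL = %.4f)\n",
              nrow(x$posterior), x$logL))
  cat("root posterior:\n")
  print(round(x$root_posterior, 4))
  invisible(x)
}

#' Export ancestral posteriors as a data frame
#' @param asr an `"asr_states"` object.
#' @param internal_only drop tip rows (default TRUE).
#' @return data frame with `node`, `is_tip`, `label`, and one posterior
#'   column per state.
#' @export
asr_table <- function(asr, internal_only = TRUE) {
  ntip <- length(asr$tree$tip.label)
  ntot <- nrow(asr$posterior)
  df <- data.frame(node = seq_len(ntot),
                   is_tip = seq_len(ntot) <= ntip,
                   label = c(asr$tree$tip.label, rep("", ntot - ntip)),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(asr$posterior))
  if (internal_only) df <- df[!df$is_tip, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Annotated Newick with per-node posterior comments
#' @param asr an `"asr_states"` object.
#' @param file optional output path.
#' @param digits digits for posteriors.
#' @return the Newick string.
#' @export
asr_annotated_newick <- function(asr, file = NULL, digits = 4) {
  post <- asr$posterior
  ann <- apply(post, 1, function(p)
    paste0("&", paste0(colnames(post), "=", format(round(p, digits),
                                                   trim = TRUE),
                       collapse = ",")))
  write_annotated_newick(asr$tree, ann, file = file)
}

#' Fit, select, and reconstruct in one step
#'
#' Fits the ER, SYM and ARD Mk models, applies AICc selection with the
#' given decisiveness threshold, and runs the marginal reconstruction
#' under the selected model's ML generator.
#'
#' @inheritParams fit_mk
#' @param models model classes to compare (default all three).
#' @param threshold AICc decisiveness threshold (default 2).
#' @return an object of class `"asr_pipeline"`: `selection`
#'   (`"mk_model_selection"`), `fits` (named list), and `asr`
#'   (`"asr_states"` under the selected model).
#' @export
asr_pipeline <- function(tree, tip_states, root_prior = "flat",
                         models = c("ER", "SYM", "ARD"), threshold = 2.0,
                         n_restarts = 5L, seed = 1L) {
  fits <- lapply(seq_along(models), function(i)
    fit_mk(tree, tip_states, models[i], root_prior = root_prior,
           n_restarts = n_restarts, seed = derive_seed(seed, i)))
  names(fits) <- models
  sel <- select_model(fits, threshold = threshold)
  asr <- marginal_asr(tree, tip_states, sel$fit$Q, root_prior = root_prior)
  structure(list(selection = sel, fits = fits, asr = asr),
            class = "asr_pipeline")
}

#' @export
print.asr_pipeline <- function(x, ...) {
  print(x$selection)
  print(x$asr)
  invisible(x)
}
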