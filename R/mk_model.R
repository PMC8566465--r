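## Mk (k-state continuous-time Markov) models of discrete character
## evolution: generator construction, transition probabilities, the
## pruning-algorithm likelihood, maximum-likelihood fitting, and
## AICc-based model selection. Written generically in k but used at k = 3
## for the molt-strategy states (absent, partial, complete).

MK_MODELS <- c("ER", "SYM", "ARD")

#' Number of free rate parameters of an Mk model class
#' @param model_class one of `"ER"`, `"SYM"`, `"ARD"`.
#' @param k number of states.
#' @return integer.
#' @export
mk_n_params <- function(model_class, k = 3L) {
  model_class <- match.arg(model_class, MK_MODELS)
  switch(model_class, ER = 1L, SYM = k * (k - 1L) %/% 2L, ARD = k * (k - 1L))
}

#' Assemble an Mk generator matrix from free rates
#'
#' Off-diagonal cells are filled row-major: for `SYM` the upper triangle
#' (`q12, q13, q23`, mirrored below), for `ARD` all off-diagonals
#' (`q12, q13, q21, q23, q31, q32`). States are ordered
#' `absent < partial < complete`, so e.g. the first `ARD` rate is the
#' absent-to-partial transition rate. Rates are in Myr^-1.
#'
#' @param model_class one of `"ER"`, `"SYM"`, `"ARD"`.
#' @param params positive free rates, length [mk_n_params()].
#' @param k number of states (default 3).
#' @param states optional state names for dimnames.
#' @return a `k x k` generator matrix (rows sum to zero) with attributes
#'   `model_class` and `params`.
#' @examples
#' build_q("ER", 0.1)
#' @export
build_q <- function(model_class, params, k = 3L, states = NULL) {
  model_class <- match.arg(model_class, MK_MODELS)
  npar <- mk_n_params(model_class, k)
  if (length(params) != npar)
    stop(sprintf("%s with k=%d needs %d rate(s), got %d",
                 model_class, k, npar, length(params)))
  if (any(!is.finite(params) | params <= 0))
    stop("all rates must be positive and finite")
  Q <- matrix(0, k, k)
  if (model_class == "ER") {
    Q[] <- params[1]
  } else if (model_class == "SYM") {
    idx <- 1L
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      Q[i, j] <- Q[j, i] <- params[idx]; idx <- idx + 1L
    }
  } else {
    idx <- 1L
    for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
      Q[i, j] <- params[idx]; idx <- idx + 1L
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  if (is.null(states) && k == 3L) states <- molt_states()
  if (!is.null(states)) dimnames(Q) <- list(states, states)
  structure(Q, model_class = model_class, params = as.numeric(params))
}

#' Names of the free rates of an Mk model class
#' @inheritParams build_q
#' @return character vector like `"q_absent.partial"`.
#' @export
mk_rate_names <- function(model_class, k = 3L, states = NULL) {
  model_class <- match.arg(model_class, MK_MODELS)
  if (is.null(states)) states <- if (k == 3L) molt_states() else paste0("s", seq_len(k))
  nm <- character(0)
  if (model_class == "ER") return("q")
  if (model_class == "SYM") {
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k))
      nm <- c(nm, paste0("q_", states[i], ".", states[j]))
  } else {
    for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
      nm <- c(nm, paste0("q_", states[i], ".", states[j]))
  }
  nm
}

# Eigen-decomposition of Q with a guard for near-defective matrices.
# Returns list(values, U, Uinv, ok). Complex output is allowed; the
# transition probabilities are real up to round-off and are clamped.
q_eigen <- function(Q) {
  eg <- eigen(Q)
  U <- eg$vectors
  Uinv <- tryCatch(solve(U), error = function(e) NULL)
  if (is.null(Uinv)) return(list(ok = FALSE))
  # defectiveness check: reconstruct Q
  Qr <- Re(U %*% diag(eg$values, nrow(Q)) %*% Uinv)
  if (max(abs(Qr - Q)) > 1e-8 * max(1, max(abs(Q)))) return(list(ok = FALSE))
  list(values = eg$values, U = U, Uinv = Uinv, ok = TRUE)
}

# Scaling-and-squaring matrix exponential (fallback when the eigen route
# is unreliable); adequate for the small k x k generators used here.
expm_ss <- function(A) {
  nrm <- max(abs(A))
  j <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 4L)
  As <- A / 2^j
  X <- diag(nrow(A)); term <- diag(nrow(A))
  for (m in 1:12) { term <- term %*% As / m; X <- X + term }
  for (i in seq_len(j)) X <- X %*% X
  X
}

#' Transition probability matrix of an Mk generator
#'
#' `P(t) = exp(Q t)`; rows sum to one, entries are clamped to `[0, 1]`
#' against round-off. Uses eigen-decomposition with a series-based
#' fallback for (near-)defective generators.
#'
#' @param Q generator matrix (from [build_q()] or any valid generator).
#' @param t branch length, `t >= 0` (vectorized).
#' @return a `k x k` matrix if `t` is scalar, else a `k x k x length(t)`
#'   array.
#' @export
transition_probs <- function(Q, t) {
  stopifnot(all(is.finite(t)), all(t >= 0))
  k <- nrow(Q)
  eg <- q_eigen(Q)
  one <- function(ti) {
    P <- if (eg$ok) Re(eg$U %*% diag(exp(eg$values * ti), k) %*% eg$Uinv)
         else expm_ss(Q * ti)
    P[P < 0] <- 0; P[P > 1] <- 1
    P <- P / rowSums(P)
    dimnames(P) <- dimnames(Q)
    P
  }
  if (length(t) == 1L) return(one(t))
  out <- array(NA_real_, c(k, k, length(t)))
  for (i in seq_along(t)) out[, , i] <- one(t[i])
  out
}

# ---------------------------------------------------------------------
# Pruning machinery
# ---------------------------------------------------------------------

# Precompute the traversal structure used by the vectorized pruning pass:
# postorder edges grouped into "rounds" such that within a round every
# child's conditional likelihood is already final; duplicate parents
# within a round are handled by occurrence ranks.
mk_prep <- function(tree) {
  validate_phylo(tree)
  tr <- ape::reorder.phylo(tree, "postorder")
  E <- tr$edge; el <- tr$edge.length
  ntip <- length(tr$tip.label)
  ntot <- ntip + tr$Nnode
  round_of <- integer(ntot)
  for (i in seq_len(nrow(E)))
    round_of[E[i, 1]] <- max(round_of[E[i, 1]], round_of[E[i, 2]] + 1L)
  g <- round_of[E[, 2]]
  groups <- lapply(sort(unique(g)), function(gg) {
    idx <- which(g == gg)
    pa <- E[idx, 1]
    rank <- stats::ave(seq_along(pa), pa, FUN = seq_along)
    list(child = E[idx, 2], parent = pa, t = el[idx], rank = rank)
  })
  list(tree = tr, edge = E, el = el, ntip = ntip, ntot = ntot,
       root = ntip + 1L, groups = groups)
}

# Convert user tip states (named character/factor/integer, NA = missing)
# into an ntot x k conditional-likelihood matrix initialized for tips.
mk_tip_matrix <- function(prep, tip_states, k = 3L, states = molt_states()) {
  labels <- prep$tree$tip.label
  if (is.null(names(tip_states)))
    stop("`tip_states` must be named by tip label")
  miss <- setdiff(labels, names(tip_states))
  if (length(miss))
    stop("tips without a state entry: ", paste(utils::head(miss, 5), collapse = ", "))
  x <- tip_states[labels]
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    idx <- match(tolower(x), states)
    if (any(!is.na(x) & is.na(idx)))
      stop("unknown state value(s): ",
           paste(unique(x[!is.na(x) & is.na(idx)]), collapse = ", "))
  } else {
    idx <- as.integer(x) + 1L  # external 0-based indices
    if (any(!is.na(idx) & (idx < 1L | idx > k)))
      stop("state index out of range 0..", k - 1L)
  }
  L <- matrix(0, prep$ntot, k)
  L[seq_len(prep$ntip), ] <- 0
  for (i in seq_len(prep$ntip)) {
    if (is.na(idx[i])) L[i, ] <- 1 else L[i, idx[i]] <- 1
  }
  L[(prep$ntip + 1L):prep$ntot, ] <- 1
  L
}

# Vectorized post-order pruning pass. Returns list(L = scaled conditional
# likelihood matrix, logscale = summed log scale factors, contrib = per-
# edge contribution vectors if keep_contrib). The likelihood of the data
# is sum(prior * L[root,]) * exp(logscale).
mk_down_pass <- function(prep, L, Q, keep_contrib = FALSE) {
  k <- nrow(Q)
  eg <- q_eigen(Q)
  logscale <- 0
  contrib <- if (keep_contrib) matrix(NA_real_, nrow(prep$edge), k) else NULL
  # map (child,parent) group rows back to edge indices when keeping contribs
  if (keep_contrib) {
    edge_key <- paste(prep$edge[, 1], prep$edge[, 2])
  }
  for (grp in prep$groups) {
    if (eg$ok) {
      M <- L[grp$child, , drop = FALSE] %*% t(eg$Uinv)
      Eg <- exp(outer(grp$t, eg$values))
      Cg <- Re((M * Eg) %*% t(eg$U))
    } else {
      Cg <- matrix(NA_real_, length(grp$child), k)
      for (i in seq_along(grp$child))
        Cg[i, ] <- expm_ss(Q * grp$t[i]) %*% L[grp$child[i], ]
    }
    Cg[Cg < 0] <- 0
    if (keep_contrib) {
      ei <- match(paste(grp$parent, grp$child), edge_key)
      contrib[ei, ] <- Cg
    }
    for (r in seq_len(max(grp$rank))) {
      sel <- grp$rank == r
      L[grp$parent[sel], ] <- L[grp$parent[sel], , drop = FALSE] *
        Cg[sel, , drop = FALSE]
    }
    # rescale the parents touched in this round
    pa <- unique(grp$parent)
    mx <- apply(L[pa, , drop = FALSE], 1, max)
    pos <- mx > 0
    if (any(pos)) {
      L[pa[pos], ] <- L[pa[pos], , drop = FALSE] / mx[pos]
      logscale <- logscale + sum(log(mx[pos]))
    }
  }
  list(L = L, logscale = logscale, contrib = contrib)
}

resolve_root_prior <- function(root_prior, Q, L_root = NULL, k = 3L) {
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == k, all(root_prior >= 0))
    return(root_prior / sum(root_prior))
  }
  policy <- match.arg(root_prior, c("flat", "stationary", "fitzjohn"))
  if (policy == "flat") return(rep(1 / k, k))
  if (policy == "stationary") {
    # left null vector of Q
    ns <- MASS_null_left(Q)
    return(ns / sum(ns))
  }
  # fitzjohn: proportional to the root conditional likelihoods
  if (is.null(L_root)) stop("fitzjohn prior needs root likelihoods")
  if (sum(L_root) == 0) return(rep(1 / k, k))
  L_root / sum(L_root)
}

# left null space of a generator via eigen of t(Q)
MASS_null_left <- function(Q) {
  eg <- eigen(t(Q))
  i <- which.min(abs(eg$values))
  v <- abs(Re(eg$vectors[, i]))
  v / sum(v)
}

#' Log-likelihood of tip states under an Mk model (pruning algorithm)
#'
#' Computes `log sum_s pi_s L_root(s)` by the post-order pruning
#' (dynamic-programming) algorithm, with per-node rescaling for numerical
#' stability. Multifurcations are handled as products over all children;
#' missing tip states (NA) contribute a flat conditional likelihood.
#'
#' @param tree a `"phylo"` object.
#' @param tip_states named vector over tips: state names
#'   (`"absent"/"partial"/"complete"`), 0-based indices, or `NA`.
#' @param Q generator matrix.
#' @param root_prior `"flat"` (default), `"stationary"`, `"fitzjohn"`, or
#'   a numeric probability vector of length `k`.
#' @param prep optional precomputed traversal from internal prep (reused
#'   across likelihood evaluations during fitting).
#' @return log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, tip_states, Q, root_prior = "flat", prep = NULL) {
  if (is.null(prep)) prep <- mk_prep(tree)
  k <- nrow(Q)
  states <- if (!is.null(rownames(Q))) rownames(Q) else molt_states()
  L <- mk_tip_matrix(prep, tip_states, k = k, states = states)
  dp <- mk_down_pass(prep, L, Q)
  Lr <- dp$L[prep$root, ]
  prior <- resolve_root_prior(root_prior, Q, L_root = Lr, k = k)
  lik <- sum(prior * Lr)
  if (lik <= 0) return(-Inf)
  log(lik) + dp$logscale
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param logL log-likelihood.
#' @param k_free number of free parameters.
#' @param n sample size (number of tips for Mk fits).
#' @return AICc value.
#' @export
aicc <- function(logL, k_free, n) {
  stopifnot(is.finite(logL), k_free >= 0, n > 0)
  if (n <= k_free + 1)
    stop(sprintf("AICc undefined: n = %d <= k + 1 = %d", n, k_free + 1))
  -2 * logL + 2 * k_free + 2 * k_free * (k_free + 1) / (n - k_free - 1)
}

#' Maximum-likelihood fit of an Mk model
#'
#' Optimizes the free transition rates on the log scale with a
#' box-constrained quasi-Newton method (`nlminb`), bounds
#' `[1e-8, 1e3]` Myr^-1, from a data-informed start plus `n_restarts`
#' random restarts (ARD likelihood surfaces can be multimodal). The fit
#' is deterministic given `seed`.
#'
#' @inheritParams mk_loglik
#' @param model_class `"ER"`, `"SYM"` or `"ARD"`.
#' @param n_restarts number of random restarts (default 5).
#' @param seed integer seed controlling the restart draws.
#' @return an object of class `"mk_fit"`: rates, `logL`, `aicc`,
#'   root-prior policy, convergence diagnostics, and a
#'   `non_identifiable` flag when tips are monomorphic.
#' @export
fit_mk <- function(tree, tip_states, model_class, root_prior = "flat",
                   n_restarts = 5L, seed = 1L) {
  model_class <- match.arg(model_class, MK_MODELS)
  prep <- mk_prep(tree)
  k <- 3L
  states <- molt_states()
  L0 <- mk_tip_matrix(prep, tip_states, k = k, states = states)
  observed <- apply(L0[seq_len(prep$ntip), , drop = FALSE], 1, function(r) {
    if (sum(r) == 1) which(r == 1) else NA_integer_
  })
  n_obs_states <- length(unique(stats::na.omit(observed)))
  non_identifiable <- n_obs_states < 2L
  if (non_identifiable)
    warning("fewer than 2 observed states: rates are non-identifiable; ",
            "returning boundary fit")
  npar <- mk_n_params(model_class, k)
  lb <- log(1e-8); ub <- log(1e3)
  negll <- function(logp) {
    Q <- build_q(model_class, exp(logp), k = k)
    -mk_loglik(tree, tip_states, Q, root_prior = root_prior, prep = prep)
  }
  if (non_identifiable) {
    par <- rep(lb, npar)
    best <- list(par = par, objective = negll(par), convergence = 0L)
    restarts <- data.frame(restart = 0L, objective = best$objective,
                           convergence = 0L)
  } else {
    height <- max(node_depths(tree)[seq_len(prep$ntip)])
    r0 <- log(max(1e-6, 1 / height))
    starts <- list(rep(r0, npar))
    if (n_restarts > 0) {
      rnd <- with_local_seed(derive_seed(seed, 17L),
                             matrix(stats::runif(n_restarts * npar,
                                                 r0 - 3, r0 + 3),
                                    n_restarts, npar))
      rnd[rnd < lb] <- lb; rnd[rnd > ub] <- ub
      for (i in seq_len(n_restarts)) starts <- c(starts, list(rnd[i, ]))
    }
    fits <- lapply(starts, function(s)
      tryCatch(stats::nlminb(s, negll, lower = lb, upper = ub,
                             control = list(iter.max = 500, eval.max = 1000)),
               error = function(e) list(objective = Inf, convergence = 1L,
                                        par = s, message = conditionMessage(e))))
    objs <- vapply(fits, function(f) f$objective, numeric(1))
    if (all(!is.finite(objs)))
      stop("Mk optimization failed to converge from any start")
    best <- fits[[which.min(objs)]]
    restarts <- data.frame(restart = seq_along(fits) - 1L, objective = objs,
                           convergence = vapply(fits, function(f)
                             as.integer(f$convergence %||% 1L), integer(1)))
  }
  rates <- exp(best$par)
  names(rates) <- mk_rate_names(model_class, k)
  Q <- build_q(model_class, rates, k = k)
  logL <- -best$objective
  prior_vec <- if (is.numeric(root_prior)) root_prior / sum(root_prior) else {
    # for reporting: resolve with the fitted Q (fitzjohn resolved per-eval)
    if (identical(root_prior, "fitzjohn")) rep(NA_real_, k)
    else resolve_root_prior(root_prior, Q, k = k)
  }
  structure(list(
    model_class = model_class, rates = rates, Q = Q, logL = logL,
    k_free = npar, n = prep$ntip, aicc = aicc(logL, npar, prep$ntip),
    root_prior = root_prior, root_prior_vector = prior_vec,
    non_identifiable = non_identifiable,
    n_restarts = if (non_identifiable) 0L else n_restarts,
    best_restart_objective = best$objective, restarts = restarts,
    convergence = as.integer(best$convergence %||% 0L)
  ), class = "mk_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("Mk model fit (%s), %d tips\n", x$model_class, x$n))
  cat(sprintf("  logL = %.4f  AICc = %.4f  (k = %d)\n", x$logL, x$aicc, x$k_free))
  cat("  rates (Myr^-1):\n")
  print(signif(x$rates, 4))
  if (x$non_identifiable) cat("  WARNING: non-identifiable (monomorphic tips)\n")
  invisible(x)
}

#' AICc model selection with a decisiveness threshold
#'
#' The minimum-AICc model is selected only if its advantage over the
#' runner-up exceeds `threshold` (strict inequality); otherwise the fit
#' with the fewest parameters among those within `threshold` of the best
#' AICc is returned and `decisive` is `FALSE`.
#'
#' @param fits list of `"mk_fit"` objects fitted to the same data.
#' @param threshold AICc difference required to be decisive (default 2).
#' @return an object of class `"mk_model_selection"`: `selected` (model
#'   name), `fit` (the selected fit), `decisive`, and `table` (model,
#'   k_free, logL, AICc, delta_aicc).
#' @export
select_model <- function(fits, threshold = 2.0) {
  stopifnot(length(fits) >= 2L, threshold > 0)
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$model_class, character(1))
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1L)
    stop("fits were made on different data (tip counts differ: ",
         paste(unique(ns), collapse = ", "), ")")
  tab <- data.frame(
    model = vapply(fits, function(f) f$model_class, character(1)),
    k_free = vapply(fits, function(f) f$k_free, integer(1)),
    logL = vapply(fits, function(f) f$logL, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    row.names = NULL
  )
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  ord <- order(tab$aicc)
  decisive <- (tab$aicc[ord[2]] - tab$aicc[ord[1]]) > threshold
  if (decisive) {
    sel <- ord[1]
  } else {
    within <- which(tab$delta_aicc <= threshold)
    sel <- within[order(tab$k_free[within], tab$aicc[within])][1]
  }
  structure(list(selected = tab$model[sel], fit = fits[[sel]],
                 decisive = decisive, threshold = threshold,
                 table = tab[order(tab$aicc), ]),
            class = "mk_model_selection")
}

#' @export
print.mk_model_selection <- function(x, ...) {
  cat(sprintf("Mk model selection: %s (%s, threshold %.2f)\n", x$selected,
              if (x$decisive) "decisive" else "indecisive; simplest within threshold",
              x$threshold))
  print(transform(x$table, logL = round(logL, 3), aicc = round(aicc, 3),
                  delta_aicc = round(delta_aicc, 3)), row.names = FALSE)
  invisible(x)
}
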