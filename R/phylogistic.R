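## Phylogenetic logistic regression (Ives-Garland-type model): a binary
## tip trait whose expectation is a logistic function of covariates and
## whose residual dependence follows a two-state Markov switching process
## on the tree with total switching rate alpha (Myr^-1). Correlation
## between two tips decays as exp(-alpha d) with their patristic
## distance d; the mean structure carries the pendant-edge equilibration
## of the switching process, mu_i = p_i + (pbar - p_i) exp(-alpha t_i)
## with p_i = plogis(x_i' beta) and pbar the average stationary
## probability. In the no-signal limit (large alpha, or a star tree)
## this collapses to ordinary logistic regression.
##
## Estimation is by iterated quasi-Fisher scoring on the estimating
## equations D' V^-1 (y - mu) = 0 with working covariance
## V = A^(1/2) R(alpha) A^(1/2), R_ij = exp(-alpha d_ij),
## A = diag(mu(1-mu)); alpha is profiled on a log grid and refined
## against the Gaussian working likelihood of the residuals. Wald
## statistics (z = estimate/se from the inverse information) are
## reported for every coefficient; in addition each slope gets an
## efficient-score (Rao) test computed at the constrained fit, which
## stays calibrated at small effective sample sizes where the Wald
## statistic saturates (the Hauck-Donner effect) -- see the methods
## vignette.

# geometry shared by all fits on one tree: patristic distances and
# pendant edge lengths
pglm_geometry <- function(tree, tips) {
  C <- ape::vcv.phylo(tree)[tips, tips]
  depth <- diag(C)
  dmat <- outer(depth, depth, "+") - 2 * C
  dmat[dmat < 0] <- 0
  ntip <- length(tips)
  pend <- numeric(ntip)
  is_tip_edge <- tree$edge[, 2] <= ntip
  pend[tree$edge[is_tip_edge, 2]] <- tree$edge.length[is_tip_edge]
  names(pend) <- tree$tip.label
  list(dmat = dmat, pend = pend[tips])
}

pglm_mu <- function(eta, a_pend) {
  p <- stats::plogis(eta)
  pbar <- mean(p)
  list(p = p, pbar = pbar, mu = (1 - a_pend) * p + a_pend * pbar)
}

# dmu/dbeta: rows tips, cols coefficients
pglm_D <- function(X, p, a_pend) {
  w <- p * (1 - p)
  (1 - a_pend) * w * X + outer(a_pend, colMeans(w * X))
}

# iterated scoring at fixed alpha for an arbitrary design matrix.
# penalty = "firth" applies the Jeffreys-type adjusted residual
# e + h (1/2 - mu) with h the V-metric leverages.
pglm_score_iter <- function(y, X, cholR, a_pend, beta0, penalty = "none",
                            max_iter = 100, tol = 1e-6, btol = 40) {
  vsol <- function(z, s)
    backsolve(cholR, backsolve(cholR, z / s, transpose = TRUE)) / s
  beta <- beta0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mm <- pglm_mu(drop(X %*% beta), a_pend)
    mu <- pmin(pmax(mm$mu, 1e-10), 1 - 1e-10)
    s <- sqrt(mu * (1 - mu))
    D <- pglm_D(X, mm$p, a_pend)
    Vi_D <- apply(D, 2, vsol, s = s)
    I_mat <- crossprod(D, Vi_D)
    M <- tryCatch(solve(I_mat), error = function(e)
      solve(I_mat + diag(1e-8, ncol(X))))
    e <- y - mu
    if (penalty == "firth") {
      h <- rowSums((D %*% M) * Vi_D)
      e <- e + h * (0.5 - mu)
    }
    delta <- drop(M %*% crossprod(D, vsol(e, s)))
    step <- 1
    while (max(abs(beta + step * delta)) > btol && step > 1e-4)
      step <- step / 2
    beta <- beta + step * delta
    if (max(abs(step * delta)) < tol) { converged <- TRUE; break }
  }
  if (max(abs(beta)) >= btol)
    stop("coefficients diverged (|beta| >= ", btol,
         "): possible complete separation; refusing boundary estimates")
  # final quantities at the solution
  mm <- pglm_mu(drop(X %*% beta), a_pend)
  mu <- pmin(pmax(mm$mu, 1e-10), 1 - 1e-10)
  s <- sqrt(mu * (1 - mu))
  D <- pglm_D(X, mm$p, a_pend)
  Vi_D <- apply(D, 2, vsol, s = s)
  I_mat <- crossprod(D, Vi_D)
  e <- y - mu
  logdetV <- 2 * sum(log(diag(cholR))) + 2 * sum(log(s))
  wll <- -0.5 * (logdetV + sum(e * vsol(e, s)))
  list(beta = beta, I_mat = I_mat, converged = converged, wll = wll,
       mu = mu, p = mm$p, vsol = vsol, s = s)
}

# profile alpha (log grid + local refinement) for a given design matrix;
# returns the best fit plus chol(R) and attenuation at alpha-hat
pglm_profile_alpha <- function(y, X, geom, beta0, penalty,
                               alpha_bounds, grid_size, max_iter, tol) {
  n <- length(y)
  fit_at <- function(a) {
    R <- exp(-a * geom$dmat); diag(R) <- 1
    cholR <- tryCatch(chol(R), error = function(e) chol(R + diag(1e-8, n)))
    a_pend <- exp(-a * geom$pend)
    f <- pglm_score_iter(y, X, cholR, a_pend, beta0, penalty = penalty,
                         max_iter = max_iter, tol = tol)
    c(f, list(alpha = a, cholR = cholR, a_pend = a_pend))
  }
  la <- seq(log(alpha_bounds[1]), log(alpha_bounds[2]),
            length.out = grid_size)
  prof <- vapply(la, function(l) {
    f <- tryCatch(fit_at(exp(l)), error = function(e) NULL)
    if (is.null(f)) -Inf else f$wll
  }, numeric(1))
  if (all(!is.finite(prof)))
    stop("alpha profile failed everywhere (separation or singular V)")
  i <- which.max(prof)
  opt <- stats::optimize(function(l) {
    f <- tryCatch(fit_at(exp(l)), error = function(e) NULL)
    if (is.null(f) || !is.finite(f$wll)) -1e300 else f$wll
  }, lower = la[max(1, i - 1)], upper = la[min(length(la), i + 1)],
  maximum = TRUE, tol = 1e-4)
  # keep whichever of the refined point and the best grid point wins
  a_hat <- if (opt$objective >= prof[i]) exp(opt$maximum) else exp(la[i])
  fit_at(a_hat)
}

#' Phylogenetic logistic regression of a binary trait
#'
#' Fits the two-state Markov switching model described above. The signal
#' parameter `alpha` (Myr^-1) is the total switching rate: small values
#' mean strong phylogenetic correlation (decay scale `1/alpha`), large
#' values approach ordinary logistic regression. Every coefficient gets
#' a Wald `z = estimate/se` and two-tailed normal p-value; every
#' non-intercept coefficient additionally gets an efficient-score (Rao)
#' test computed at the constrained fit with that coefficient at zero
#' (`score_z`, `score_p`), referred to a t distribution with
#' `1'R^-1 1 - p` effective degrees of freedom. The score test is the
#' package's recommended slope test: under strong phylogenetic
#' correlation the Wald statistic saturates (Hauck-Donner effect) and
#' the effective sample size is far below the tip count, both of which
#' the score/t combination corrects for.
#'
#' @param tree a `"phylo"` object.
#' @param y named binary (0/1) vector over the tips; both classes must
#'   be present.
#' @param X covariate matrix or data frame with rownames matching tips
#'   (an intercept column is added automatically).
#' @param alpha `NULL` to estimate (default), or a fixed positive value.
#' @param alpha_bounds search bounds for `alpha` (default
#'   `c(1e-6, 1e3)`); estimates at the bounds are flagged.
#' @param penalty `"none"` (default; plain quasi-Fisher scoring, with
#'   divergence detected and refused) or `"firth"` (Jeffreys-type
#'   adjusted-residual stabilization).
#' @param grid_size number of log-spaced profile points (default 12).
#' @param max_iter,tol scoring iteration controls.
#' @param score_tests compute the per-slope score tests (default TRUE).
#' @return an object of class `"phyloglm_fit"`: `alpha`,
#'   `alpha_boundary`, `coefficients` (term, estimate, se, z, p,
#'   score_z, score_p), `vcov`, `n`, `converged`, `working_loglik`.
#' @export
fit_phyloglm <- function(tree, y, X, alpha = NULL,
                         alpha_bounds = c(1e-6, 1e3),
                         penalty = c("none", "firth"),
                         grid_size = 12, max_iter = 100, tol = 1e-6,
                         score_tests = TRUE) {
  penalty <- match.arg(penalty)
  validate_phylo(tree)
  tips <- tree$tip.label
  if (is.null(names(y))) stop("`y` must be named by tip label")
  X <- as.matrix(X)
  if (is.null(rownames(X))) stop("`X` must have species rownames")
  miss_y <- setdiff(tips, names(y)); miss_x <- setdiff(tips, rownames(X))
  if (length(miss_y) || length(miss_x))
    stop("species missing from data: ",
         paste(utils::head(unique(c(miss_y, miss_x)), 5), collapse = ", "))
  y <- as.numeric(y[tips]); X <- X[tips, , drop = FALSE]
  if (!all(y %in% c(0, 1))) stop("`y` must be 0/1")
  if (length(unique(y)) < 2L) stop("`y` is constant; both classes required")
  if (any(!is.finite(X))) stop("non-finite covariate values")
  Xd <- cbind(`(Intercept)` = 1, X)
  n <- length(y)
  geom <- pglm_geometry(tree, tips)

  start_for <- function(Xs) {
    b <- tryCatch(
      suppressWarnings(
        stats::glm.fit(Xs, y, family = stats::binomial())$coefficients),
      error = function(e) rep(0, ncol(Xs)))
    b[!is.finite(b)] <- 0
    pmin(pmax(b, -10), 10)
  }

  if (!is.null(alpha)) {
    stopifnot(is.numeric(alpha), alpha > 0)
    R <- exp(-alpha * geom$dmat); diag(R) <- 1
    cholR <- tryCatch(chol(R), error = function(e) chol(R + diag(1e-8, n)))
    best <- c(pglm_score_iter(y, Xd, cholR, exp(-alpha * geom$pend),
                              start_for(Xd), penalty = penalty,
                              max_iter = max_iter, tol = tol),
              list(alpha = alpha, cholR = cholR,
                   a_pend = exp(-alpha * geom$pend)))
    boundary <- FALSE
  } else {
    best <- pglm_profile_alpha(y, Xd, geom, start_for(Xd), penalty,
                               alpha_bounds, grid_size, max_iter, tol)
    boundary <- best$alpha <= alpha_bounds[1] * 1.01 ||
      best$alpha >= alpha_bounds[2] * 0.99
  }

  vc <- solve(best$I_mat)
  se <- sqrt(pmax(diag(vc), 0))
  z <- best$beta / se
  pv <- 2 * stats::pnorm(-abs(z))
  coefs <- data.frame(term = colnames(Xd), estimate = best$beta, se = se,
                      z = z, p = pv, score_z = NA_real_,
                      score_df = NA_real_, score_p = NA_real_,
                      row.names = NULL, stringsAsFactors = FALSE)

  if (score_tests && ncol(Xd) > 1L) {
    for (j in seq(2L, ncol(Xd))) {
      Xn <- Xd[, -j, drop = FALSE]
      null_fit <- tryCatch({
        if (!is.null(alpha)) {
          c(pglm_score_iter(y, Xn, best$cholR, best$a_pend, start_for(Xn),
                            penalty = "none", max_iter = max_iter,
                            tol = tol),
            list(alpha = alpha, cholR = best$cholR, a_pend = best$a_pend))
        } else {
          pglm_profile_alpha(y, Xn, geom, start_for(Xn), "none",
                             alpha_bounds, grid_size, max_iter, tol)
        }
      }, error = function(e) NULL)
      if (is.null(null_fit)) next
      beta_null <- numeric(ncol(Xd))
      beta_null[-j] <- null_fit$beta
      mm <- pglm_mu(drop(Xd %*% beta_null), null_fit$a_pend)
      mu <- pmin(pmax(mm$mu, 1e-10), 1 - 1e-10)
      s <- sqrt(mu * (1 - mu))
      vsol <- function(zv)
        backsolve(null_fit$cholR,
                  backsolve(null_fit$cholR, zv / s, transpose = TRUE)) / s
      D <- pglm_D(Xd, mm$p, null_fit$a_pend)
      Vi_D <- apply(D, 2, vsol)
      I_mat <- crossprod(D, Vi_D)
      U <- drop(crossprod(D, vsol(y - mu)))
      I_eff <- I_mat[j, j] -
        I_mat[j, -j, drop = FALSE] %*%
        solve(I_mat[-j, -j, drop = FALSE]) %*% I_mat[-j, j, drop = FALSE]
      if (I_eff > 0) {
        coefs$score_z[j] <- U[j] / sqrt(drop(I_eff))
        # small-sample t reference: the phylogenetic correlation leaves
        # only ~1'R^-1 1 effective observations, so a normal reference
        # is anti-conservative; df = effective n minus estimated mean
        # parameters
        u1 <- backsolve(null_fit$cholR, rep(1, n), transpose = TRUE)
        df_eff <- max(sum(u1^2) - ncol(Xd), 1)
        coefs$score_df[j] <- df_eff
        coefs$score_p[j] <- 2 * stats::pt(-abs(coefs$score_z[j]), df_eff)
      }
    }
  }

  structure(list(alpha = best$alpha, alpha_boundary = boundary,
                 coefficients = coefs, vcov = vc, n = n,
                 converged = best$converged,
                 working_loglik = best$wll, penalty = penalty,
                 alpha_fixed = !is.null(alpha)),
            class = "phyloglm_fit")
}

#' @export
print.phyloglm_fit <- function(x, ...) {
  cat(sprintf("Phylogenetic logistic regression (n = %d)\n", x$n))
  cat(sprintf("  alpha = %.4g Myr^-1%s%s\n", x$alpha,
              if (x$alpha_fixed) " (fixed)" else "",
              if (x$alpha_boundary) " [at search boundary]" else ""))
  tab <- x$coefficients
  for (cn in c("estimate", "se", "score_z"))
    tab[[cn]] <- signif(tab[[cn]], 4)
  tab$z <- round(tab$z, 3)
  tab$p <- signif(tab$p, 3); tab$score_p <- signif(tab$score_p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Univariate phylogenetic logistic regressions
#'
#' Fits one intercept + single-covariate model per column of `X`,
#' producing the classic one-row-per-predictor results table
#' (parameter, alpha, estimate, SE, Z, p) plus the score-test columns.
#'
#' @inheritParams fit_phyloglm
#' @param ... passed to [fit_phyloglm()].
#' @return a list of `"phyloglm_fit"` objects (one per column), with a
#'   `summary_table` attribute collecting the slope rows.
#' @export
univariate_table <- function(tree, y, X, ...) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  fits <- lapply(colnames(X), function(cn)
    fit_phyloglm(tree, y, X[, cn, drop = FALSE], ...))
  names(fits) <- colnames(X)
  rows <- lapply(colnames(X), function(cn) {
    f <- fits[[cn]]
    co <- f$coefficients[f$coefficients$term == cn, ]
    data.frame(parameter = cn, alpha = f$alpha, estimate = co$estimate,
               se = co$se, z = co$z, p = co$p, score_z = co$score_z,
               score_df = co$score_df, score_p = co$score_p, n = f$n,
               stringsAsFactors = FALSE)
  })
  attr(fits, "summary_table") <- do.call(rbind, rows)
  fits
}

#' Summary table of univariate phylogenetic regressions
#' @param fits result of [univariate_table()].
#' @return data frame with columns parameter, alpha, estimate, se, z, p,
#'   score_z, score_p, n.
#' @export
phyloglm_summary_table <- function(fits) attr(fits, "summary_table")
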