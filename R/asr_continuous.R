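## Brownian-motion reconstruction of a continuous trait. The root value
## is the GLS mean under the BM tip covariance V (V_ij = shared root-to-
## MRCA path length), sigma^2 the ML (1/n) estimator, both obtained by a
## linear-time contrast (pruning) recursion rather than a dense solve;
## ancestral node values come from Gaussian message passing with a flat
## root prior, which reproduces the classic re-rooted GLS estimates.

# post-order pruning pass: per-node conditional (mean, variance-scale)
# from the subtree below, plus the contrast decomposition of log|V| and
# of the GLS residual quadratic form. Polytomies are combined by
# sequential pairwise merging (equivalent to a zero-length resolution);
# the accumulated quantities are invariant to the merge order.
bm_down_pass <- function(tree, x) {
  tr <- ape::reorder.phylo(tree, "postorder")
  E <- tr$edge; el <- tr$edge.length
  ntip <- length(tr$tip.label)
  ntot <- ntip + tr$Nnode
  xm <- numeric(ntot); vv <- numeric(ntot)
  xm[seq_len(ntip)] <- x[tr$tip.label]
  logdet <- 0; SS <- 0
  children_of <- split(seq_len(nrow(E)), E[, 1])
  # postorder node sequence: parents in the order their last edge appears
  node_order <- unique(E[, 1])
  for (p in node_order) {
    eidx <- children_of[[as.character(p)]]
    ch <- E[eidx, 2]
    w <- vv[ch] + el[eidx]
    x0 <- xm[ch[1]]; w0 <- w[1]
    if (length(ch) > 1L) {
      for (j in 2:length(ch)) {
        varc <- w0 + w[j]
        if (varc <= 0)
          stop("zero patristic distance between subtrees; V is singular")
        contrast <- x0 - xm[ch[j]]
        logdet <- logdet + log(varc)
        SS <- SS + contrast^2 / varc
        x0 <- (x0 * w[j] + xm[ch[j]] * w0) / varc
        w0 <- w0 * w[j] / varc
      }
    }
    xm[p] <- x0; vv[p] <- w0
  }
  root <- ntip + 1L
  list(tree = tr, edge = E, el = el, ntip = ntip, ntot = ntot, root = root,
       xm = xm, vv = vv, logdet_contrasts = logdet, SS = SS,
       children_of = children_of)
}

#' Maximum-likelihood Brownian-motion fit
#'
#' Estimates the root value (GLS mean) and the BM rate `sigma2` (ML,
#' `1/n` denominator) for a continuous trait on a phylogeny, via the
#' linear-time contrast recursion. Identical, up to floating point, to
#' the dense-matrix GLS formulas
#' `mu = (1'V^-1 1)^-1 1'V^-1 x` and
#' `sigma2 = (x - mu)' V^-1 (x - mu) / n`.
#'
#' @param tree a `"phylo"` object (>= 3 tips, positive depth).
#' @param tip_values named numeric vector over the tips (finite).
#' @param trait_transform `"none"` (default) or `"log10"`; applied before
#'   fitting and recorded in the result.
#' @return an object of class `"bm_fit"`: `sigma2`, `root_value`,
#'   `root_var` (variance of the root estimate), `logL`
#'   (NA when `sigma2 = 0`), `n`, `trait_transform`.
#' @export
fit_bm <- function(tree, tip_values, trait_transform = c("none", "log10")) {
  trait_transform <- match.arg(trait_transform)
  validate_phylo(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 3L) stop("need >= 3 tips for a meaningful sigma2 estimate")
  if (is.null(names(tip_values)))
    stop("`tip_values` must be named by tip label")
  miss <- setdiff(tree$tip.label, names(tip_values))
  if (length(miss))
    stop("tips without values: ", paste(utils::head(miss, 5), collapse = ", "))
  x <- tip_values[tree$tip.label]
  if (any(!is.finite(x))) stop("non-finite tip values")
  if (trait_transform == "log10") {
    if (any(x <= 0)) stop("log10 transform requires positive values")
    x <- log10(x)
  }
  if (max(node_depths(tree)[seq_len(ntip)]) <= 0)
    stop("zero-depth tree: all branch lengths are zero")
  dn <- bm_down_pass(tree, x)
  mu <- dn$xm[dn$root]
  v_root <- dn$vv[dn$root]
  sigma2 <- dn$SS / ntip
  logdetV <- dn$logdet_contrasts + log(v_root)
  logL <- if (sigma2 > 0)
    -ntip / 2 * log(2 * pi * sigma2) - logdetV / 2 - ntip / 2
  else NA_real_
  structure(list(sigma2 = sigma2, root_value = mu,
                 root_var = sigma2 * v_root, logL = logL, n = ntip,
                 trait_transform = trait_transform, down = dn),
            class = "bm_fit")
}

#' @export
print.bm_fit <- function(x, ...) {
  cat(sprintf("Brownian-motion fit (%d tips, transform = %s)\n",
              x$n, x$trait_transform))
  cat(sprintf("  sigma2 = %.6g per Myr,  root = %.6g (var %.4g),  logL = %.4f\n",
              x$sigma2, x$root_value, x$root_var, x$logL))
  invisible(x)
}

#' Ancestral node estimates under Brownian motion
#'
#' Combines the downward (subtree) conditional moments with an upward
#' pass carrying the information from the rest of the tree under a flat
#' root prior; the resulting per-node means equal the GLS root estimate
#' of the tree re-rooted at that node. Tip estimates equal the
#' observations with zero variance.
#'
#' @param tree the tree used in [fit_bm()].
#' @param tip_values the tip values used in [fit_bm()].
#' @param fit a `"bm_fit"` from [fit_bm()] on the same tree/data.
#' @return data frame `node`, `is_tip`, `label`, `estimate`, `variance`
#'   (conditional variance scaled by the fitted `sigma2`), on the
#'   transformed scale recorded in the fit.
#' @export
bm_asr <- function(tree, tip_values, fit = NULL) {
  if (is.null(fit)) fit <- fit_bm(tree, tip_values)
  dn <- fit$down
  E <- dn$edge; el <- dn$el
  ntip <- dn$ntip; ntot <- dn$ntot
  ux <- numeric(ntot); uprec <- numeric(ntot)  # upward message (mean, precision)
  ux[dn$root] <- 0; uprec[dn$root] <- 0        # flat root prior
  for (i in rev(seq_len(nrow(E)))) {           # pre-order
    p <- E[i, 1]; ch <- E[i, 2]
    prec <- uprec[p]
    m <- if (prec > 0) ux[p] * prec else 0
    for (s in dn$children_of[[as.character(p)]]) {
      if (s == i) next
      wb <- dn$vv[E[s, 2]] + el[s]
      prec <- prec + 1 / wb
      m <- m + dn$xm[E[s, 2]] / wb
    }
    if (prec > 0) {
      v_at_p <- 1 / prec
      ux[ch] <- m / prec
      uprec[ch] <- 1 / (v_at_p + el[i])
    } else {
      ux[ch] <- 0; uprec[ch] <- 0
    }
  }
  est <- numeric(ntot); vr <- numeric(ntot)
  for (v in seq_len(ntot)) {
    if (v <= ntip) { est[v] <- dn$xm[v]; vr[v] <- 0; next }
    pd <- if (dn$vv[v] > 0) 1 / dn$vv[v] else Inf
    pu <- uprec[v]
    if (is.infinite(pd)) { est[v] <- dn$xm[v]; vr[v] <- 0 }
    else {
      est[v] <- (dn$xm[v] * pd + ux[v] * pu) / (pd + pu)
      vr[v] <- fit$sigma2 / (pd + pu)
    }
  }
  tr <- dn$tree
  data.frame(node = seq_len(ntot), is_tip = seq_len(ntot) <= ntip,
             label = c(tr$tip.label, rep("", ntot - ntip)),
             estimate = est, variance = vr, stringsAsFactors = FALSE)
}
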