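# Independent oracles used across the suite. These deliberately avoid
# the package's pruning/message-passing code paths: likelihoods by
# exhaustive enumeration over internal-state assignments, posteriors by
# enumeration, GLS by dense matrix algebra, logistic regression by glm's
# IRLS.

# exhaustive-enumeration log-likelihood for small trees (<= 6 tips)
brute_mk_loglik <- function(tree, tip_states, Q, prior = rep(1 / 3, 3)) {
  k <- nrow(Q)
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  E <- tree$edge
  Ps <- lapply(seq_len(nrow(E)), function(e)
    transition_probs(Q, tree$edge.length[e]))
  obs <- match(tip_states[tree$tip.label], rownames(Q))
  sets <- c(lapply(seq_len(ntip),
                   function(i) if (is.na(obs[i])) seq_len(k) else obs[i]),
            rep(list(seq_len(k)), ntot - ntip))
  grid <- as.matrix(expand.grid(sets))
  w <- apply(grid, 1, function(a) {
    lik <- prior[a[ntip + 1]]
    for (e in seq_len(nrow(E)))
      lik <- lik * Ps[[e]][a[E[e, 1]], a[E[e, 2]]]
    lik
  })
  log(sum(w))
}

# exhaustive-enumeration marginal posteriors for small trees
brute_mk_posterior <- function(tree, tip_states, Q, prior = rep(1 / 3, 3)) {
  k <- nrow(Q)
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  E <- tree$edge
  Ps <- lapply(seq_len(nrow(E)), function(e)
    transition_probs(Q, tree$edge.length[e]))
  obs <- match(tip_states[tree$tip.label], rownames(Q))
  sets <- c(lapply(seq_len(ntip),
                   function(i) if (is.na(obs[i])) seq_len(k) else obs[i]),
            rep(list(seq_len(k)), ntot - ntip))
  grid <- as.matrix(expand.grid(sets))
  w <- apply(grid, 1, function(a) {
    lik <- prior[a[ntip + 1]]
    for (e in seq_len(nrow(E)))
      lik <- lik * Ps[[e]][a[E[e, 1]], a[E[e, 2]]]
    lik
  })
  post <- matrix(0, ntot, k)
  for (v in seq_len(ntot)) for (s in seq_len(k))
    post[v, s] <- sum(w[grid[, v] == s])
  post / rowSums(post)
}

# dense-matrix GLS estimates of the BM root and rate
dense_bm_gls <- function(tree, x) {
  V <- ape::vcv.phylo(tree)
  x <- x[tree$tip.label]
  Vi <- solve(V)
  n <- length(x)
  mu <- sum(Vi %*% x) / sum(Vi)
  s2 <- drop(t(x - mu) %*% Vi %*% (x - mu)) / n
  logL <- -n / 2 * log(2 * pi * s2) -
    0.5 * as.numeric(determinant(V)$modulus) - n / 2
  list(root = mu, sigma2 = s2, logL = logL)
}

# dense re-rooted GLS ancestral estimate at a given node, from the
# all-node distance matrix (shared path from node a: (d_ai+d_aj-d_ij)/2)
dense_bm_node_estimate <- function(tree, x, node, D = ape::dist.nodes(tree)) {
  n <- length(tree$tip.label)
  Va <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    Va[i, j] <- (D[node, i] + D[node, j] - D[i, j]) / 2
  Vai <- solve(Va)
  sum(Vai %*% x[tree$tip.label]) / sum(Vai)
}

# random small tree + states for oracle sweeps
random_mk_case <- function(seed, n_min = 3, n_max = 6, allow_missing = TRUE) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1)
  tr <- simulate_tree(n, birth_rate = 0.3, seed = seed)
  cls <- sample(c("ER", "SYM", "ARD"), 1)
  Q <- build_q(cls, stats::runif(mk_n_params(cls), 0.05, 0.6))
  pool <- if (allow_missing) c(molt_states(), NA) else molt_states()
  st <- sample(pool, n, replace = TRUE)
  if (all(is.na(st))) st[1] <- "absent"
  names(st) <- tr$tip.label
  list(tree = tr, Q = Q, states = st)
}
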