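test_that("build_q assembles valid generators for all model classes", {
  Q <- build_q("ER", 0.1)
  expect_equal(unname(Q[1, 2]), 0.1)
  expect_equal(unname(diag(Q)), rep(-0.2, 3))
  expect_equal(rowSums(Q), c(absent = 0, partial = 0, complete = 0))

  Qs <- build_q("SYM", c(0.1, 0.2, 0.3))
  expect_equal(unname(Qs[1, 2]), 0.1)
  expect_equal(unname(Qs[2, 1]), 0.1)
  expect_equal(unname(Qs[1, 3]), 0.2)
  expect_equal(unname(Qs[2, 3]), 0.3)
  expect_true(isSymmetric(unname(Qs)))

  Qa <- build_q("ARD", c(1, 2, 3, 4, 5, 6) / 10)
  expect_false(isSymmetric(unname(Qa)))
  expect_equal(unname(rowSums(Qa)), rep(0, 3))
  expect_equal(unname(Qa[1, 2]), 0.1)  # row-major off-diagonal order
  expect_equal(unname(Qa[3, 2]), 0.6)

  expect_error(build_q("ER", c(0.1, 0.2)), "needs 1 rate")
  expect_error(build_q("SYM", c(0.1, -0.2, 0.3)), "positive")
})

test_that("transition probabilities are stochastic and match a series expansion", {
  Q <- build_q("ARD", c(0.12, 0.31, 0.05, 0.2, 0.44, 0.09))
  expect_equal(transition_probs(Q, 0), diag(3), ignore_attr = TRUE)

  # symmetric chain converges to the uniform stationary distribution
  P_inf <- transition_probs(build_q("ER", 0.1), 1e6)
  expect_equal(unname(P_inf), matrix(1 / 3, 3, 3), tolerance = 1e-9)

  # two independent evaluations: eigen route vs truncated series
  for (t in c(0.5, 1, 7)) {
    P <- transition_probs(Q, t)
    A <- Q * t
    S <- diag(3); term <- diag(3)
    for (m in 1:60) { term <- term %*% A / m; S <- S + term }
    expect_equal(unname(P), unname(S), tolerance = 1e-10)
    expect_equal(unname(rowSums(P)), rep(1, 3), tolerance = 1e-12)
    expect_true(all(P >= 0 & P <= 1))
  }
})

test_that("pruning log-likelihood matches limiting cases", {
  tr <- parse_newick("(A:1,B:1);")
  # rate -> 0: no change possible, root must equal the shared tip state
  ll <- mk_loglik(tr, c(A = "absent", B = "absent"), build_q("ER", 1e-9))
  expect_equal(ll, log(1 / 3), tolerance = 1e-6)
  # all tips missing: likelihood is 1
  expect_equal(mk_loglik(tr, c(A = NA, B = NA), build_q("ER", 0.5)), 0,
               tolerance = 1e-9)
  expect_error(mk_loglik(tr, c(A = "absent"), build_q("ER", 0.1)),
               "without a state entry")
  expect_error(mk_loglik(tr, c(A = 0, B = 5), build_q("ER", 0.1)),
               "out of range")
})

test_that("pruning equals exhaustive enumeration on random small cases", {
  for (r in 1:40) {
    cs <- random_mk_case(100 + r)
    a <- mk_loglik(cs$tree, cs$states, cs$Q)
    b <- brute_mk_loglik(cs$tree, cs$states, cs$Q)
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("likelihood respects relabeling symmetry and multifurcations", {
  # permuting states of the data and permuting Q accordingly leaves
  # the likelihood unchanged
  cs <- random_mk_case(7, allow_missing = FALSE)
  perm <- c(3, 1, 2)
  st_perm <- stats::setNames(molt_states()[perm][match(cs$states,
                                                       molt_states())],
                             names(cs$states))
  Qp <- cs$Q[order(perm), order(perm)]
  dimnames(Qp) <- dimnames(cs$Q)
  expect_equal(mk_loglik(cs$tree, st_perm, Qp),
               mk_loglik(cs$tree, cs$states, cs$Q), tolerance = 1e-10)

  # polytomies: star tree likelihood equals the product of per-tip
  # transition sums from the root
  star <- parse_newick("(A:2,B:1,C:3,D:1.5);")
  st <- c(A = "absent", B = "partial", C = "complete", D = "absent")
  Q <- build_q("SYM", c(0.2, 0.1, 0.3))
  direct <- log(sum(vapply(1:3, function(s) {
    (1 / 3) * prod(vapply(names(st), function(tip) {
      t_i <- star$edge.length[star$edge[, 2] == match(tip, star$tip.label)]
      transition_probs(Q, t_i)[s, match(st[tip], molt_states())]
    }, numeric(1)))
  }, numeric(1))))
  expect_equal(mk_loglik(star, st, Q), direct, tolerance = 1e-10)

  # ER/SYM likelihood is invariant to re-rooting (reversible chain,
  # flat prior)
  tr <- simulate_tree(8, birth_rate = 0.2, seed = 5)
  st8 <- simulate_mk(tr, Q, seed = 6)$tip_states
  ll0 <- mk_loglik(tr, st8, Q)
  rerooted <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[4],
                        resolve.root = TRUE)
  expect_equal(mk_loglik(rerooted, st8, Q), ll0, tolerance = 1e-8)
})

test_that("aicc evaluates the small-sample correction", {
  expect_equal(aicc(-100, 6, 1808), 212 + 84 / 1801)
  expect_equal(aicc(-100, 1, 4), 204)
  expect_equal(aicc(-123.4, 0, 10), 246.8)
  expect_error(aicc(-100, 6, 7), "undefined")
})

test_that("fitted models are nested: logL ER <= SYM <= ARD", {
  tr <- simulate_tree(60, birth_rate = 0.1, seed = 21)
  st <- simulate_mk(tr, build_q("ARD", c(0.02, 0.01, 0.03, 0.015,
                                         0.025, 0.01)),
                    seed = 22)$tip_states
  fits <- lapply(c("ER", "SYM", "ARD"), function(m)
    fit_mk(tr, st, m, n_restarts = 3, seed = 1))
  ll <- vapply(fits, function(f) f$logL, numeric(1))
  expect_true(ll[1] <= ll[2] + 1e-6)
  expect_true(ll[2] <= ll[3] + 1e-6)
  # AICc fields are internally consistent
  for (f in fits)
    expect_equal(f$aicc, aicc(f$logL, f$k_free, f$n))
})

test_that("monomorphic data are flagged non-identifiable", {
  tr <- simulate_tree(10, seed = 2)
  st <- stats::setNames(rep("absent", 10), tr$tip.label)
  expect_warning(f <- fit_mk(tr, st, "ER", seed = 1), "non-identifiable")
  expect_true(f$non_identifiable)
})

test_that("model selection applies the decisiveness threshold", {
  mk_stub <- function(model, k, aicc_val, logL = -100, n = 500) {
    structure(list(model_class = model, k_free = k, logL = logL,
                   aicc = aicc_val, n = n), class = "mk_fit")
  }
  # clear winner
  s1 <- select_model(list(mk_stub("ER", 1L, 300), mk_stub("SYM", 3L, 250),
                          mk_stub("ARD", 6L, 206)))
  expect_equal(s1$selected, "ARD")
  expect_true(s1$decisive)
  expect_equal(s1$table$delta_aicc[s1$table$model == "SYM"], 44)

  # indecisive: simplest model within the threshold wins
  s2 <- select_model(list(mk_stub("ER", 1L, 206.5), mk_stub("SYM", 3L, 206),
                          mk_stub("ARD", 6L, 207)))
  expect_equal(s2$selected, "ER")
  expect_false(s2$decisive)

  # boundary: delta exactly 2.0 is not decisive (strict inequality)
  s3 <- select_model(list(mk_stub("ER", 1L, 208), mk_stub("ARD", 6L, 206)))
  expect_false(s3$decisive)
  expect_equal(s3$selected, "ER")

  expect_error(select_model(list(mk_stub("ER", 1L, 10, n = 100),
                                 mk_stub("SYM", 3L, 11, n = 200))),
               "different data")
})

test_that("fitting is deterministic given a seed and agrees with an independent implementation", {
  tr <- simulate_tree(80, birth_rate = 0.1, seed = 31)
  st <- simulate_mk(tr, build_q("ER", 0.02), seed = 32)$tip_states
  f1 <- fit_mk(tr, st, "SYM", n_restarts = 3, seed = 9)
  f2 <- fit_mk(tr, st, "SYM", n_restarts = 3, seed = 9)
  expect_identical(f1$rates, f2$rates)

  skip_if_not_installed("phytools")
  fer <- fit_mk(tr, st, "ER", n_restarts = 2, seed = 9)
  ref <- phytools::fitMk(tr, stats::setNames(as.character(st),
                                             names(st)),
                         model = "ER", pi = "equal")
  expect_equal(fer$logL, as.numeric(ref$logLik), tolerance = 1e-4)
})
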