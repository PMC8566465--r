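test_that("birth-death trees are ultrametric, sized, and seeded", {
  tr <- simulate_tree(2, birth_rate = 0.5, seed = 1)
  expect_equal(ape::Ntip(tr), 2)
  expect_true(is_ultrametric_tree(tr))

  t1 <- simulate_tree(50, seed = 7)
  t2 <- simulate_tree(50, seed = 7)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_false(identical(write_newick(simulate_tree(50, seed = 8)),
                         write_newick(t1)))

  # Yule expectation: mean pendant edge approx 1/(2 lambda)
  big <- simulate_tree(4000, birth_rate = 1, seed = 9)
  pend <- big$edge.length[big$edge[, 2] <= 4000]
  expect_equal(mean(pend), 0.5, tolerance = 0.1)
})

test_that("Markov character simulation matches its generator", {
  tr <- simulate_tree(20, seed = 11)
  # rate ~ 0: every node inherits the root state
  sim0 <- simulate_mk(tr, build_q("ER", 1e-10), root_state = "partial",
                      seed = 12)
  expect_true(all(sim0$node_states == "partial"))

  # saturation: long branches reach the uniform stationary distribution
  star <- ape::stree(6000, "star")
  star$edge.length <- rep(500, 6000)
  sim_s <- simulate_mk(star, build_q("ER", 0.5), root_state = "absent",
                       seed = 13)
  freqs <- table(sim_s$tip_states) / 6000
  expect_equal(unname(as.vector(freqs)), rep(1 / 3, 3), tolerance = 0.06)

  # endpoint distribution over one branch matches P(t) row-wise
  # (10,000 independent draws; 0.02 is ~4 binomial SDs)
  one <- ape::stree(10000, "star")
  one$edge.length <- rep(3, 10000)
  Q <- build_q("ARD", c(0.2, 0.05, 0.1, 0.3, 0.15, 0.25))
  sim1 <- simulate_mk(one, Q, root_state = "partial", seed = 14)
  emp <- as.vector(table(sim1$tip_states) / 10000)
  expect_lt(max(abs(emp - unname(transition_probs(Q, 3)["partial", ]))),
            0.02)

  # determinism
  expect_identical(simulate_mk(tr, Q, seed = 5)$tip_states,
                   simulate_mk(tr, Q, seed = 5)$tip_states)
})

test_that("Brownian simulation obeys the variance and covariance laws", {
  tr <- simulate_tree(12, seed = 21)
  sim0 <- simulate_bm(tr, sigma2 = 0, root_value = 3, seed = 22)
  expect_equal(unname(sim0$tip_values), rep(3, 12))

  # Var(tip) ~ sigma2 * depth across replicates on a fixed tree
  depth <- max(node_depths(tr)[1:12])
  tipvals <- vapply(1:400, function(r)
    simulate_bm(tr, sigma2 = 1.5, seed = 3000 + r)$tip_values[[1]],
    numeric(1))
  expect_equal(stats::var(tipvals), 1.5 * depth, tolerance = 0.15)

  # Cov(sisters) ~ sigma2 * shared path length
  cherry <- parse_newick("((A:2,B:2):3,C:5);")
  ab <- vapply(1:600, function(r) {
    tv <- simulate_bm(cherry, sigma2 = 2, seed = 4000 + r)$tip_values
    c(tv[["A"]], tv[["B"]])
  }, numeric(2))
  expect_equal(stats::cov(ab[1, ], ab[2, ]), 2 * 3, tolerance = 0.2)
})

test_that("binary switching simulation approaches independence as alpha grows", {
  tr <- simulate_tree(800, birth_rate = 0.1, seed = 31)
  set.seed(32)
  X <- cbind(x = stats::rnorm(800))
  rownames(X) <- tr$tip.label
  beta <- c(0.3, 1)
  p <- stats::plogis(0.3 + X[, 1])
  # large alpha: P(y=1) tracks the tip-specific logistic probability
  ybar <- rowMeans(vapply(1:10, function(r)
    simulate_binary_ig10(tr, X, beta, alpha = 50, seed = 33 + r),
    numeric(800)))
  expect_equal(mean(ybar), mean(p), tolerance = 0.03)
  expect_gt(mean(ybar[p > 0.7]), mean(ybar[p < 0.3]) + 0.3)
  expect_equal(mean(ybar[p < 0.3]), mean(p[p < 0.3]), tolerance = 0.2)

  # beta = 0, symmetric process: overall frequency near 1/2
  ys <- vapply(1:30, function(r)
    mean(simulate_binary_ig10(tr, X, c(0, 0), alpha = 0.5,
                              seed = 40 + r)), numeric(1))
  expect_equal(mean(ys), 0.5, tolerance = 0.05)

  # correlation between two moderately separated tips decays with
  # alpha: pick the pair whose patristic distance is closest to 1 Myr
  D <- patristic_distances(tr)
  diag(D) <- Inf
  pair <- arrayInd(which.min(abs(D - 1)), dim(D))
  tips2 <- tr$tip.label[pair]
  pair_cor <- function(alpha) {
    states <- vapply(1:150, function(r)
      simulate_binary_ig10(tr, X, c(0, 0), alpha = alpha,
                           seed = round(1e4 * alpha) + r)[tips2],
      numeric(2))
    stats::cor(states[1, ], states[2, ])
  }
  expect_gt(pair_cor(0.05), pair_cor(5) + 0.2)
})

test_that("the study-like dataset reproduces the design conditions exactly", {
  ds <- make_study_like_dataset(seed = 17)
  expect_equal(nrow(ds$table), 1808)
  expect_equal(ape::Ntip(ds$tree), 1808)
  expect_true(is_ultrametric_tree(ds$tree))
  counts <- table(ds$table$molt_strategy)
  expect_equal(unname(as.vector(counts)), c(1059, 217, 532))
  expect_equal(length(code_binary(ds$table)$y), 1591)
  expect_equal(sum(ds$table$bdpr_flag), 179)
  expect_equal(length(unique(ds$table$order)), 27)
  expect_equal(length(unique(ds$table$family)), 146)
  expect_true(all(ds$table$mid_latitude_deg >= 0 &
                    ds$table$mid_latitude_deg <= 90))
  expect_true(all(ds$table$body_mass_g > 0))
  # complete-molt species sit closer to the equator by design
  s <- summarize_by_strategy(ds$table)
  lat_c <- s[s$group == "complete" & s$variable == "mid_latitude_deg",
             "mean"]
  lat_o <- s[s$group == "partial_absent" &
               s$variable == "mid_latitude_deg", "mean"]
  expect_lt(lat_c, lat_o)

  # byte-level determinism of the serialized table
  f1 <- tempfile(); f2 <- tempfile()
  write_species_table(ds$table, f1)
  write_species_table(make_study_like_dataset(seed = 17)$table, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("closing the loop: fitted parameters recover the generator", {
  # Mk: ER rate recovered on a moderate tree
  tr <- simulate_tree(500, birth_rate = 0.1, seed = 51)
  sim <- simulate_mk(tr, build_q("ER", 0.02), seed = 52)
  f <- fit_mk(tr, sim$tip_states, "ER", n_restarts = 2, seed = 53)
  expect_equal(unname(f$rates[1]), 0.02, tolerance = 0.30)

  # BM: sigma2 recovered
  simb <- simulate_bm(tr, sigma2 = 2, root_value = 10, seed = 54)
  fb <- fit_bm(tr, simb$tip_values)
  expect_equal(fb$sigma2, 2, tolerance = 0.3)
})
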