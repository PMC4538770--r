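test_that("cutoff transform matches its closed form", {
  expect_equal(adjust_cutoff(0.05, 1), 0.05)
  expect_equal(adjust_cutoff(0.19, 2), 0.1)
  expect_equal(adjust_cutoff(0.2, 10), 1 - 0.8^0.1)
  expect_equal(adjust_cutoff(0.2, 10), 0.022067, tolerance = 1e-4)
  # strictly decreasing in K
  ks <- 1:8
  vals <- vapply(ks, function(k) adjust_cutoff(0.1, k), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(adjust_cutoff(0, 2), "between")
  expect_error(adjust_cutoff(1, 2), "between")
})

test_that("profile initialization is valid and deterministic", {
  pr <- init_profiles(3, 5, seed = 99)
  expect_length(pr, 3)
  for (p in pr) {
    expect_setequal(p$order, 1:5)
    expect_length(p$members, 0)
  }
  expect_identical(pr, init_profiles(3, 5, seed = 99))
  expect_false(identical(pr, init_profiles(3, 5, seed = 100)))
  expect_error(init_profiles(0, 5), "positive")
})

test_that("assignment gates genes on significance", {
  set.seed(21)
  n <- 40
  prof_order <- sample(n)
  # one gene strictly monotone along profile 1's order, rest independent
  x <- matrix(rnorm(30 * n), 30, n)
  x[1, prof_order] <- seq(-2, 2, length.out = n)
  x <- standardize_rows(x)
  x <- rbind(x, flat = 0)  # constant gene
  np <- dcol_null_params(x, B = 400, seed = 5)
  profiles <- list(list(members = integer(0), order = prof_order),
                   list(members = integer(0), order = sample(n)))
  asg <- assign_genes(x, profiles, np, cutoff = 0.05)
  expect_equal(unname(asg$assignment[1]), 1)
  expect_lt(asg$p_values[1], 1e-6)
  # constant gene: degenerate policy, never assigned
  expect_equal(unname(asg$assignment[["flat"]]), 0)
  expect_equal(unname(asg$p_values[["flat"]]), 1)
  # gates: anything above the transformed cutoff is unassigned
  thr <- adjust_cutoff(0.05, 2)
  expect_true(all(asg$p_values[asg$assignment == 0] > thr))
  expect_true(all(asg$p_values[asg$assignment != 0] <= thr))
})

test_that("profile update sorts single-gene clusters and reseeds empties", {
  set.seed(3)
  x <- standardize_rows(matrix(rnorm(4 * 12), 4, 12))
  assignment <- c(1L, 0L, 0L, 0L)
  pr <- update_profiles(x, assignment, K = 2, seed = 17)
  expect_true(orders_equivalent(pr[[1]]$order, order(x[1, ])))
  expect_setequal(pr[[2]]$order, 1:12)
  expect_identical(pr, update_profiles(x, assignment, K = 2, seed = 17))
  # two identical genes give the same order as one alone (up to reversal)
  x2 <- rbind(x[1, ], x[1, ])
  pr2 <- update_profiles(x2, c(1L, 1L), K = 1, seed = 17)
  expect_true(orders_equivalent(pr2[[1]]$order, pr[[1]]$order))
  expect_error(update_profiles(x, c(5L, 0L, 0L, 0L), K = 2), "0..K")
})

test_that("cluster_score sums negative log p-values with a floor", {
  expect_equal(cluster_score(c(1, 1, 1)), 0)
  expect_equal(cluster_score(c(0.1, 0.01)), -log(0.1) - log(0.01))
  expect_equal(cluster_score(c(0.1, 0.01)), 6.9078, tolerance = 1e-4)
  expect_equal(cluster_score(c(0, 1)), -log(1e-300))
  # monotone: lowering any p-value strictly increases the score
  p <- c(0.5, 0.2, 0.9)
  for (i in seq_along(p)) {
    q <- p
    q[i] <- p[i] / 2
    expect_gt(cluster_score(q), cluster_score(p))
  }
})

test_that("the fit is deterministic and keeps noise out of profiles", {
  sim <- tiny_sim(seed = 6)
  f1 <- kprofiles(sim$matrix, K = 2, B = 100, seed = 5)
  f2 <- kprofiles(sim$matrix, K = 2, B = 100, seed = 5)
  expect_identical(f1[c("assignment", "p_values", "score")],
                   f2[c("assignment", "p_values", "score")])
  # assigned genes partition across member sets
  members <- unlist(lapply(f1$profiles, `[[`, "members"))
  expect_equal(sort(members), which(f1$assignment != 0))
  expect_equal(anyDuplicated(members), 0)
  # every member passed the final gate
  thr <- adjust_cutoff(0.05, 2)
  expect_true(all(f1$p_values[members] <= thr))
  expect_error(kprofiles(sim$matrix[, 1:2], K = 2), "samples")
})

test_that("zero-noise structure is recovered exactly on small data", {
  sim <- simulate_expression(m_clusters = 2, genes_per_cluster = 20,
                             n_samples = 40, n_noise_genes = 0,
                             noise_sd = 0, seed = 13)
  fit <- kprofiles(sim$matrix, K = 2, B = 200, seed = 13)
  expect_equal(adjusted_rand_index(fit$assignment, sim$labels), 1)
  expect_true(all(fit$assignment != 0))
})
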