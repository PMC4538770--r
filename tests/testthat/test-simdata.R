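test_that("link functions have the documented raw shapes", {
  expect_equal(apply_link("linear", 0.5, standardize = FALSE), 0.5)
  expect_equal(apply_link("abs", -2, standardize = FALSE), 2)
  expect_equal(apply_link("box", c(0.5, 1.5), standardize = FALSE),
               c(1, -1))
  expect_equal(apply_link("sine", 0.5, standardize = FALSE), 1)
  z <- rnorm(50)
  std <- apply_link("sine", z)
  expect_equal(mean(std), 0, tolerance = 1e-12)
  expect_equal(sd(std), 1, tolerance = 1e-12)
  expect_error(apply_link("cubic", 1), "unknown link")
})

test_that("row and label bookkeeping is exact for every mechanism", {
  for (mech in c("hidden_factor", "dep1", "dep2")) {
    sim <- simulate_expression(m_clusters = 2, genes_per_cluster = 3,
                               n_samples = 10, n_noise_genes = 1,
                               mechanism = mech, noise_sd = 0.3, seed = 4)
    expect_equal(dim(sim$matrix), c(7, 10))
    expect_equal(unname(sim$labels), c(1L, 1L, 1L, 2L, 2L, 2L, 0L))
    expect_equal(rownames(sim$matrix), names(sim$labels))
  }
  big <- simulate_expression(m_clusters = 10, seed = 1)
  expect_equal(dim(big$matrix), c(1100, 100))
  expect_equal(sum(big$labels == 0), 100)
  expect_equal(as.integer(table(big$labels[big$labels != 0])),
               rep(100L, 10))
})

test_that("generation is deterministic given the seed", {
  a <- simulate_expression(3, 5, 20, 2, "dep2", noise_sd = 0.5, seed = 77)
  b <- simulate_expression(3, 5, 20, 2, "dep2", noise_sd = 0.5, seed = 77)
  expect_identical(a, b)
  c <- simulate_expression(3, 5, 20, 2, "dep2", noise_sd = 0.5, seed = 78)
  expect_false(identical(a$matrix, c$matrix))
})

test_that("hidden-factor genes are exact link transforms at zero noise", {
  sim <- simulate_expression(m_clusters = 2, genes_per_cluster = 8,
                             n_samples = 25, n_noise_genes = 0,
                             noise_sd = 0, seed = 9)
  for (m in 1:2) {
    z <- sim$spec$details[[m]]$z
    links <- sim$spec$details[[m]]$links
    rows <- which(sim$labels == m)
    for (i in seq_along(rows)) {
      expect_equal(unname(sim$matrix[rows[i], ]),
                   apply_link(links[i], z), tolerance = 1e-12)
    }
  }
})

test_that("dependent mechanisms chain genes as documented", {
  sim <- simulate_expression(m_clusters = 1, genes_per_cluster = 6,
                             n_samples = 30, n_noise_genes = 0,
                             mechanism = "dep1", noise_sd = 0, seed = 10)
  det <- sim$spec$details[[1]]
  for (g in 2:6) {
    par <- det$parents[[g]]
    expect_true(par >= 1 && par < g)
    expect_equal(unname(sim$matrix[g, ]),
                 unname(apply_link(det$links[g], sim$matrix[par, ])),
                 tolerance = 1e-12)
  }
  sim2 <- simulate_expression(m_clusters = 2, genes_per_cluster = 5,
                              n_samples = 30, n_noise_genes = 0,
                              mechanism = "dep2", noise_sd = 0.2, seed = 11)
  for (m in 1:2) {
    det <- sim2$spec$details[[m]]
    for (g in 2:5) {
      expect_true(all(det$betas[[g]] >= -1 & det$betas[[g]] <= 1))
      expect_true(all(det$parents[[g]] < g))
    }
    # the second gene's two picks fall on the only available predecessor
    expect_equal(det$parents[[2]], c(1L, 1L))
  }
  expect_error(simulate_expression(2, 1, 10, 0, "dep2", seed = 1),
               "at least 2 genes")
})

test_that("cluster genes are strongly dependent on their own trajectory", {
  sim <- simulate_expression(m_clusters = 1, genes_per_cluster = 10,
                             n_samples = 100, n_noise_genes = 90,
                             noise_sd = 0, seed = 14)
  x <- standardize_rows(sim$matrix)
  np <- dcol_null_params(x, B = 300, seed = 15)
  z_ord <- order(sim$spec$details[[1]]$z)
  p <- dcol_pvalue(kprofiles:::dcol_rows(x, z_ord), np$mu, np$sigma)
  expect_true(all(p[sim$labels == 1] < 1e-3))
})

test_that("achieved dependence degrades monotonically with noise", {
  # same seed, increasing noise: median p of cluster genes against the
  # true trajectory order must not decrease
  meds <- vapply(c(0.2, 1.0, 2.0), function(s) {
    sim <- simulate_expression(m_clusters = 1, genes_per_cluster = 20,
                               n_samples = 60, n_noise_genes = 0,
                               noise_sd = s, seed = 22)
    x <- standardize_rows(sim$matrix)
    np <- dcol_null_params(x, B = 200, seed = 23)
    z_ord <- order(sim$spec$details[[1]]$z)
    median(dcol_pvalue(kprofiles:::dcol_rows(x, z_ord), np$mu, np$sigma))
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})
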