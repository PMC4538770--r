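test_that("sample distances are Euclidean on the gene subspace", {
  x <- rbind(a = c(0, 3, 4), b = c(0, 0, 0))
  d <- sample_distances(x, 1)
  expect_equal(d[1, 2], 3)
  expect_equal(d[2, 3], 1)
  expect_equal(d[1, 3], 4)
  x2 <- rbind(g1 = c(0, 3, 0), g2 = c(0, 4, 0))
  d2 <- sample_distances(x2, 1:2)
  expect_equal(d2[1, 2], 5)  # 3-4-5 triangle
  expect_equal(d2[1, 3], 0)  # identical sample columns
  expect_equal(unname(diag(d2)), rep(0, 3))
  expect_true(isSymmetric(unname(d2)))
  expect_error(sample_distances(x, integer(0)), "nonempty")
})

test_that("path_length telescopes in 1-D and is reversal invariant", {
  x <- matrix(c(1, 2, 4), 1)
  d <- sample_distances(x, 1)
  expect_equal(path_length(d, 1:3), 3)
  expect_equal(path_length(d, 3:1), 3)
  expect_equal(path_length(d[1:2, 1:2], 1:2), d[1, 2])
  expect_error(path_length(d, c(1, 1, 2)), "permutation")
  set.seed(2)
  d5 <- sample_distances(matrix(rnorm(3 * 5), 3), 1:3)
  o <- sample(5)
  expect_equal(path_length(d5, o), path_length(d5, rev(o)))
})

test_that("hamiltonian_order sorts single-gene clusters (1-D lemma)", {
  # 1-D point sets: the value-sorted order is the unique shortest path
  expect_true(orders_equivalent(
    hamiltonian_order(sample_distances(matrix(c(5, 1, 3), 1), 1)),
    c(2, 3, 1)))
  set.seed(31)
  for (n in 3:8) {
    y <- rnorm(n)
    o <- hamiltonian_order(sample_distances(matrix(y, 1), 1), seed = n)
    expect_true(orders_equivalent(o, order(y)))
    # exhaustive check that sorting minimizes the adjacent-difference sum
    d <- sample_distances(matrix(y, 1), 1)
    expect_equal(path_length(d, order(y)), brute_shortest_path(d))
  }
})

test_that("hamiltonian_order contracts hold on small instances", {
  expect_equal(sort(hamiltonian_order(matrix(c(0, 1, 1, 0), 2))), 1:2)
  set.seed(8)
  x <- matrix(rnorm(2 * 7), 2, 7)
  d <- sample_distances(x, 1:2)
  o <- hamiltonian_order(d, seed = 4)
  expect_setequal(o, 1:7)
  # never better than the brute-force optimum, never worse than any
  # nearest-neighbor construction
  opt <- brute_shortest_path(d)
  expect_gte(path_length(d, o) - opt, -1e-10)
  nn_worst <- max(vapply(1:7, function(s)
    path_length(d, kprofiles:::nn_path(d, s)), numeric(1)))
  expect_lte(path_length(d, o), nn_worst + 1e-10)
  expect_error(hamiltonian_order(matrix(0, 2, 3)), "square")
})

test_that("a single-gene profile attains the gene's minimal DCOL", {
  set.seed(12)
  y <- rnorm(7)
  o <- hamiltonian_order(sample_distances(matrix(y, 1), 1), seed = 2)
  d_prof <- dcol(y, o)
  perms <- all_perms(7)
  d_all <- apply(perms, 1, function(p) dcol(y, p))
  expect_equal(d_prof, min(d_all))
})

test_that("orders_equivalent identifies undirected paths", {
  expect_true(orders_equivalent(c(1, 2, 3), c(3, 2, 1)))
  expect_false(orders_equivalent(c(1, 2, 3), c(1, 3, 2)))
  o <- c(4, 2, 1, 3)
  expect_true(orders_equivalent(o, o))
  expect_error(orders_equivalent(1:3, 1:4), "length")
})
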