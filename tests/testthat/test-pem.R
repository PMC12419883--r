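test_that("edge weight rule matches its closed forms", {
  expect_equal(edge_weights(4, edge_weighting(a = 0, psi = 1)), 2)
  expect_equal(edge_weights(c(0.5, 7), edge_weighting(a = 1, psi = 9)),
               c(3, 3))
  expect_equal(edge_weights(16, edge_weighting(a = 0.5, psi = 4)), 4)
  expect_equal(edge_weights(0, edge_weighting(a = 0.5)), 0)
  expect_error(edge_weighting(a = 1.2), "steepness")
  expect_error(edge_weighting(psi = 0), "psi")
})

test_that("PEM basis columns are orthonormal, centered, rank-bounded", {
  set.seed(31)
  for (i in 1:8) {
    tr <- random_tree(sample(4:40, 1))
    b <- build_pem(influence_matrix(tr))
    k <- ncol(b$U)
    expect_lte(k, length(tr$tip.label) - 1L)
    expect_equal(crossprod(b$U), diag(k), ignore_attr = TRUE,
                 tolerance = 1e-10)
    expect_lt(max(abs(colSums(b$U))), 1e-10)
    expect_true(all(diff(b$d) <= 0))
    expect_true(all(b$d > 0))
  }
})

test_that("Brownian limit: PEM Gram equals doubly-centered path matrix", {
  set.seed(37)
  for (i in 1:8) {
    tr <- random_tree(sample(4:30, 1))
    im <- influence_matrix(tr)
    b <- build_pem(im, edge_weighting(a = 0, psi = 1))
    P <- path_length_matrix(im$tree)[rownames(im$I), rownames(im$I)]
    n <- nrow(P)
    C <- diag(n) - matrix(1 / n, n, n)
    G <- b$U %*% diag(b$d^2, length(b$d)) %*% t(b$U)
    expect_lt(max(abs(G - C %*% P %*% C)), 1e-10)
  }
})

test_that("eigenvector signs are fixed and the basis is reproducible", {
  set.seed(41)
  tr <- random_tree(15)
  b1 <- build_pem(influence_matrix(tr))
  b2 <- build_pem(influence_matrix(tr))
  expect_identical(b1$U, b2$U)
  expect_identical(b1$d, b2$d)
  for (j in seq_len(ncol(b1$U)))
    expect_gt(b1$U[which.max(abs(b1$U[, j])), j], 0)
})

test_that("re-scored training tips reproduce their own eigenvector rows", {
  set.seed(43)
  tr <- random_tree(12)
  im <- influence_matrix(tr)
  b <- build_pem(im)
  for (tip in rownames(im$I)) {
    sc <- location_scores(b, training_tip_location(im, tip))
    expect_equal(sc, b$U[tip, ], tolerance = 1e-8)
  }
})

test_that("root attachment with traversed 0 scores to -means projection", {
  set.seed(47)
  tr <- random_tree(10)
  im <- influence_matrix(tr)
  b <- build_pem(im)
  loc <- structure(list(label = "x", edge = 1L, traversed = 0, pendant = 1),
                   class = "tip_location")
  expected <- as.numeric((-b$means) %*% b$V %*% diag(1 / b$d,
                                                     length(b$d)))
  expect_equal(unname(location_scores(b, loc)), expected, tolerance = 1e-12)
})

test_that("location scores are invariant to the global rate psi", {
  set.seed(53)
  tr <- random_tree(14)
  train <- sample(tr$tip.label, 9)
  im <- influence_matrix(tr, train)
  locs <- locate_targets(tr, train)
  for (a in c(0, 0.4)) {
    b1 <- build_pem(im, edge_weighting(a = a, psi = 1))
    b100 <- build_pem(im, edge_weighting(a = a, psi = 100))
    s1 <- location_scores(b1, locs)
    s100 <- location_scores(b100, locs)
    expect_equal(s1, s100, tolerance = 1e-9)
  }
})

test_that("location_scores rejects out-of-bounds traversed lengths", {
  set.seed(59)
  im <- influence_matrix(random_tree(8))
  b <- build_pem(im)
  bad <- structure(list(label = "x", edge = 1L,
                        traversed = im$edges$length[1L] + 1, pendant = 0),
                   class = "tip_location")
  expect_error(location_scores(b, bad), "traversed")
})

test_that("steepness estimate is boxed and beats a grid-search oracle", {
  set.seed(61)
  tr <- random_tree(24)
  im <- influence_matrix(tr)
  y <- stats::rnorm(nrow(im$I))
  est <- estimate_steepness(im, y)
  expect_gte(est$a, 0)
  expect_lte(est$a, 1)
  grid <- seq(0, 1, by = 0.1)
  lls <- vapply(grid, function(a) pemretro:::.steepness_loglik(im, y, a),
                numeric(1L))
  expect_gte(est$logLik, max(lls) - 1e-6)
})

test_that("steepness estimate recovers the Brownian boundary", {
  ## traits simulated under Brownian motion (a = 0): the median estimate
  ## over seeds should sit near the 0 boundary
  a_hats <- vapply(1:20, function(s) {
    cfg <- sim_config(n_tips = 64, fossil_fraction = 0, seed = 1000 + s)
    sim <- simulate_dataset(cfg)
    im <- influence_matrix(sim$tree)
    estimate_steepness(im, log(sim$table$RBC_area))$a
  }, numeric(1L))
  expect_lt(stats::median(a_hats), 0.3)
})
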