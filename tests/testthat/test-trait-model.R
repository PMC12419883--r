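test_that("forward selection finds an exact eigenvector signal", {
  set.seed(71)
  tr <- random_tree(12)
  b <- build_pem(influence_matrix(tr))
  y <- 2 * b$U[, 3L]
  sel <- forward_select_eigenvectors(b$U, y)
  expect_identical(sel[1L], 3L)
  fit <- stats::lm.fit(cbind(1, b$U[, sel, drop = FALSE]), y)
  expect_lt(sum(fit$residuals^2), 1e-20)
})

test_that("a zero eigenvector budget returns the co-predictor-only model", {
  set.seed(73)
  tr <- random_tree(10)
  b <- build_pem(influence_matrix(tr))
  y <- stats::rnorm(10)
  expect_identical(forward_select_eigenvectors(b$U, y, max_k = 0),
                   integer(0))
})

test_that("first selected index matches an exhaustive AICc oracle", {
  set.seed(79)
  for (rep in 1:5) {
    tr <- random_tree(8)
    b <- build_pem(influence_matrix(tr))
    U3 <- b$U[, 1:3, drop = FALSE]
    z <- stats::rnorm(8)
    y <- 0.5 * z + U3 %*% c(0.3, 0.8, 0.1) + stats::rnorm(8, 0, 0.2)
    y <- as.numeric(y)
    sel <- forward_select_eigenvectors(U3, y, Z = cbind(z = z), max_k = 1)
    oracle <- vapply(1:3, function(j)
      aicc_oracle(stats::lm(y ~ z + U3[, j])), numeric(1L))
    base <- aicc_oracle(stats::lm(y ~ z))
    if (min(oracle) < base) {
      expect_identical(sel, which.min(oracle))
    } else {
      expect_identical(sel, integer(0))
    }
  }
})

test_that("R-squared is nondecreasing along the forward path", {
  set.seed(83)
  tr <- random_tree(16)
  b <- build_pem(influence_matrix(tr))
  y <- as.numeric(b$U[, 1:4] %*% c(1, 0.7, 0.5, 0.3)) +
    stats::rnorm(16, 0, 0.3)
  sel <- forward_select_eigenvectors(b$U, y)
  r2 <- function(idx) {
    X <- cbind(1, b$U[, idx, drop = FALSE])
    f <- stats::lm.fit(X, y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }
  path <- vapply(seq_along(sel), function(i) r2(sel[seq_len(i)]),
                 numeric(1L))
  expect_true(all(diff(c(r2(integer(0)), path)) >= -1e-12))
})

test_that("a saturated co-predictor gives R2 = 1 and p near 0", {
  set.seed(89)
  tr <- random_tree(10)
  b <- build_pem(influence_matrix(tr))
  tab <- algebraic_table(tr, beta0 = 0.5, beta1 = 2, noise = 0)
  fit <- fit_candidate_model(tab, b,
                             candidate_model("RBC_area", "lnCan_min",
                                             use_phylogeny = FALSE))
  expect_equal(fit$r_squared, 1)
  expect_lt(fit$p_value, 1e-12)
  expect_equal(unname(fit$coefficients["lnCan_min"]), 2, tolerance = 1e-8)
})

test_that("phylogeny-off fits equal the closed-form simple regression", {
  set.seed(97)
  tr <- random_tree(14)
  b <- build_pem(influence_matrix(tr))
  tab <- algebraic_table(tr, beta0 = 1.5, beta1 = 0.8, noise = 0.3)
  fit <- fit_candidate_model(tab, b,
                             candidate_model("RBC_area", "lnCan_min",
                                             use_phylogeny = FALSE))
  y <- log(tab$RBC_area); z <- tab$lnCan_min
  slope <- stats::cov(y, z) / stats::var(z)
  expect_equal(unname(fit$coefficients["lnCan_min"]), slope,
               tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["(Intercept)"]),
               mean(y) - slope * mean(z), tolerance = 1e-10)
})

test_that("Holm-Sidak adjustment matches its closed forms", {
  expect_equal(holm_sidak_adjust(0.05), 0.05)
  expect_equal(holm_sidak_adjust(c(0.01, 0.04)), c(0.0199, 0.04))
  ## all-equal inputs: first sorted element 1 - (1 - p)^m, constant after
  p <- rep(0.02, 4)
  adj <- holm_sidak_adjust(p)
  expect_equal(adj, rep(1 - (1 - 0.02)^4, 4))
})

test_that("Holm-Sidak output dominates input and is step-down monotone", {
  set.seed(101)
  for (i in 1:20) {
    p <- stats::runif(sample(1:8, 1))
    adj <- holm_sidak_adjust(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(holm_sidak_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the comparison grid has four ranked rows and a best flag", {
  set.seed(103)
  cfg <- sim_config(n_tips = 20, fossil_fraction = 0, seed = 103)
  sim <- simulate_dataset(cfg)
  b <- build_pem(influence_matrix(sim$tree))
  cmp <- model_comparison_table(sim$table, b, "RBC_area")
  expect_equal(nrow(cmp$table), 4L)
  expect_setequal(cmp$table$model,
                  c("lnOsteo_volume + phylogeny",
                    "lnCan_harmean + phylogeny",
                    "lnCan_min + phylogeny", "phylogeny"))
  expect_equal(sum(cmp$table$best), 1L)
  expect_equal(which(cmp$table$best),
               which.max(cmp$table$r_squared))
  ok <- !is.na(cmp$table$p_adjusted)
  expect_true(all(cmp$table$p_adjusted[ok] >= cmp$table$p_value[ok]))
})

test_that("the R2-maximizing criterion fills its budget and dominates AICc fits", {
  cfg <- sim_config(n_tips = 18, fossil_fraction = 0, seed = 109)
  sim <- simulate_dataset(cfg)
  b <- build_pem(influence_matrix(sim$tree))
  spec <- candidate_model("RBC_area", "lnCan_min")
  f_aicc <- fit_candidate_model(sim$table, b, spec, criterion = "aicc")
  f_r2 <- fit_candidate_model(sim$table, b, spec, criterion = "r2")
  expect_gte(f_r2$r_squared, f_aicc$r_squared - 1e-12)
  expect_gte(length(f_r2$selected), length(f_aicc$selected))
})

test_that("fits are fully deterministic given identical inputs", {
  cfg <- sim_config(n_tips = 18, fossil_fraction = 0, seed = 107)
  sim <- simulate_dataset(cfg)
  b <- build_pem(influence_matrix(sim$tree))
  f1 <- fit_candidate_model(sim$table, b,
                            candidate_model("RBC_area", "lnCan_min"))
  f2 <- fit_candidate_model(sim$table, b,
                            candidate_model("RBC_area", "lnCan_min"))
  expect_identical(f1$selected, f2$selected)
  expect_identical(f1$coefficients, f2$coefficients)
})
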