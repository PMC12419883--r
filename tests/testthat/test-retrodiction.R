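test_that("in-sample retrodiction reproduces the fitted values", {
  cfg <- sim_config(n_tips = 16, fossil_fraction = 0, seed = 19)
  sim <- simulate_dataset(cfg)
  im <- influence_matrix(sim$tree)
  b <- build_pem(im)
  fit <- fit_candidate_model(sim$table, b,
                             candidate_model("RBC_area", "lnCan_min"))
  locs <- lapply(b$tips, function(t) training_tip_location(im, t))
  res <- retrodict_traits(fit, b, locs, sim$table)
  expect_equal(res$ln_prediction, unname(fit$fitted), tolerance = 1e-8)
  expect_true(all(res$prediction > 0))
  expect_equal(res$prediction, exp(res$ln_prediction))
})

test_that("predictions are invariant to psi and to uniform branch scaling", {
  cfg <- sim_config(n_tips = 20, fossil_fraction = 0.3, seed = 23)
  sim <- simulate_dataset(cfg)
  train <- sim$table$taxon[sim$table$status == "extant"]
  predict_with <- function(tree, psi) {
    im <- influence_matrix(tree, train)
    b <- build_pem(im, edge_weighting(a = 0, psi = psi))
    fit <- fit_candidate_model(sim$table, b,
                               candidate_model("RBC_area", "lnCan_min"))
    locs <- locate_targets(tree, train)
    retrodict_traits(fit, b, locs, sim$table)$prediction
  }
  base <- predict_with(sim$tree, 1)
  expect_equal(predict_with(sim$tree, 100), base, tolerance = 1e-6)
  scaled <- sim$tree
  scaled$edge.length <- scaled$edge.length * 3
  expect_equal(predict_with(scaled, 1), base, tolerance = 1e-6)
})

test_that("a fossil missing its co-predictor fails alone", {
  cfg <- sim_config(n_tips = 14, fossil_fraction = 0.3, seed = 29)
  sim <- simulate_dataset(cfg)
  tab <- sim$table
  fossils <- tab$taxon[tab$status == "fossil"]
  tab$lnCan_min[tab$taxon == fossils[1L]] <- NA
  train <- tab$taxon[tab$status == "extant"]
  im <- influence_matrix(sim$tree, train)
  b <- build_pem(im)
  fit <- fit_candidate_model(tab, b, candidate_model("RBC_area", "lnCan_min"))
  res <- retrodict_traits(fit, b, locate_targets(sim$tree, train), tab)
  bad <- res$taxon == fossils[1L]
  expect_match(res$error[bad], "missing predictor")
  expect_true(all(is.finite(res$prediction[!bad])))
  expect_true(all(res$error[!bad] == ""))
})

test_that("masked-tip prediction error shrinks as proxy noise shrinks", {
  mse_at <- function(noise, seed) {
    cfg <- sim_config(n_tips = 16, fossil_fraction = 0.25,
                      proxy_noise_sd = rep(noise, 3), seed = seed)
    sim <- simulate_dataset(cfg)
    train <- sim$table$taxon[sim$table$status == "extant"]
    im <- influence_matrix(sim$tree, train)
    b <- build_pem(im)
    fit <- fit_candidate_model(sim$table, b,
                               candidate_model("RBC_area", "lnCan_min"))
    res <- retrodict_traits(fit, b, locate_targets(sim$tree, train),
                            sim$table)
    m <- merge(res, sim$truth, by = "taxon")
    mean((m$ln_prediction - m$ln_RBC_area)^2)
  }
  seeds <- 300 + 1:30
  low <- vapply(seeds, function(s) mse_at(0.02, s), numeric(1L))
  high <- vapply(seeds, function(s) mse_at(0.8, s), numeric(1L))
  expect_lt(stats::median(low), stats::median(high))
})

test_that("the pipeline runs, validates and reruns byte-identically", {
  cfg <- sim_config(n_tips = 12, fossil_fraction = 1 / 3, seed = 31)
  sim <- simulate_dataset(cfg)
  d <- withr::local_tempdir()
  paths <- write_fixture(sim$tree, sim$table, d)
  rc <- run_config(paths[["tree"]], paths[["characters"]],
                   out_dir = file.path(d, "out"))
  res <- run_pipeline(rc, quiet = TRUE)
  expect_equal(nrow(res$comparisons$RBC_area$table), 4L)
  fossils <- sim$table$taxon[sim$table$status == "fossil"]
  expect_setequal(res$retrodictions$taxon, fossils)
  expect_true(all(res$retrodictions$error == ""))
  first <- lapply(res$files, readLines)
  res2 <- run_pipeline(rc, quiet = TRUE)
  expect_identical(lapply(res2$files, readLines), first)

  ## taxon mismatch aborts with both unmatched lists reported
  tab2 <- sim$table
  tab2$taxon[1L] <- "renamed_taxon"
  write_character_matrix(tab2, file.path(d, "bad.csv"))
  rc_bad <- run_config(paths[["tree"]], file.path(d, "bad.csv"),
                       out_dir = file.path(d, "out2"))
  err <- tryCatch(run_pipeline(rc_bad, quiet = TRUE),
                  error = conditionMessage)
  expect_match(err, "reconciliation")
  expect_match(err, "renamed_taxon")
  expect_match(err, sim$table$taxon[1L])
})
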