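test_that("generators are pure functions of params, design, and seed", {
  p <- exponential_params(17.37, 0.0203)
  a <- gen_enzyme_series(p, noise = noise_spec(level = 0.05, seed = 4))
  b <- gen_enzyme_series(p, noise = noise_spec(level = 0.05, seed = 4))
  c_ <- gen_enzyme_series(p, noise = noise_spec(level = 0.05, seed = 5))
  expect_identical(a$y, b$y)
  expect_false(identical(a$y, c_$y))
  pm <- resource_params(4.72, 29.19, reduced = TRUE)
  d <- gen_nitrogen_series(pm, noise = noise_spec("additive_gaussian", 0.05,
                                                  seed = 4))
  e <- gen_nitrogen_series(pm, noise = noise_spec("additive_gaussian", 0.05,
                                                  seed = 4))
  expect_identical(d$y, e$y)
})

test_that("zero noise reproduces the model curves exactly", {
  p <- exponential_params(12, 0.03)
  s <- gen_enzyme_series(p, noise = noise_spec(level = 0))
  expect_equal(s$y, predict_exponential(p, s$x), tolerance = 1e-15)
  pm <- resource_params(4, 25, R0 = 2, ln_P0 = 0.5)
  sm <- gen_nitrogen_series(pm, noise = noise_spec("additive_gaussian", 0))
  expect_equal(log(sm$y), predict_resource_response(pm, sm$x),
               tolerance = 1e-12)
})

test_that("noise magnitudes match their nominal levels at large n", {
  # moment oracle at n = 1e4
  p <- exponential_params(10, 0.01)
  grid <- seq(1, 200, length.out = 1e4)
  s <- gen_enzyme_series(p, x_grid = grid,
                         noise = noise_spec("multiplicative_lognormal", 0.05,
                                            seed = 12))
  ratio <- s$y / predict_exponential(p, grid)
  expect_lt(abs(stats::sd(ratio) / mean(ratio) - 0.05), 0.005)
  pm <- resource_params(4.72, 29.19, reduced = TRUE)
  sm <- gen_nitrogen_series(pm, R_grid = seq(3, 117, length.out = 1e4),
                            noise = noise_spec("additive_gaussian", 0.05,
                                               seed = 12))
  resid <- log(sm$y) - predict_resource_response(pm, sm$x)
  expect_lt(abs(stats::sd(resid) - 0.05) / 0.05, 0.02)
})

test_that("noise specifications validate and guard the log domain", {
  expect_error(noise_spec(level = -0.1), class = "edm_validation_error")
  p <- resource_params(4, 20, R0 = 5, reduced = TRUE)
  expect_error(gen_nitrogen_series(p, R_grid = c(1, 10, 20, 30),
                                   noise = noise_spec(level = 0)),
               class = "edm_domain_error")
  expect_error(gen_enzyme_series(exponential_params(1, 1), x_grid = c(1, 2),
                                 noise = noise_spec(level = 0)),
               class = "edm_insufficient_data")
})

test_that("study suite holds 13 enzyme and 7 nitrogen series and is reproducible", {
  suite <- gen_study_suite(seed = 1)
  expect_length(suite$series, 20)
  kinds <- vapply(suite$series, `[[`, character(1), "predictor_kind")
  expect_equal(sum(kinds == "enzyme_activity"), 13)
  expect_equal(sum(kinds == "leaf_N"), 7)
  expect_equal(nrow(suite$registry), 20)
  # byte-identical across runs at the same seed
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  gen_study_suite(seed = 9, noise_level = 0.05, dir = d1)
  gen_study_suite(seed = 9, noise_level = 0.05, dir = d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("refitting the zero-noise suite returns every preset", {
  suite <- gen_study_suite(seed = 2, noise_level = 0)
  presets <- edm_presets()
  for (i in seq_len(nrow(presets$table1))) {
    row <- presets$table1[i, ]
    id <- tolower(gsub("[^A-Za-z0-9]+", "_", row$preset))
    f <- fit_exponential(suite$series[[id]])
    expect_equal(f$params$alpha, row$alpha, tolerance = 1e-4)
    expect_equal(f$params$b, row$b, tolerance = 1e-4)
  }
  for (i in seq_len(nrow(presets$table2))) {
    row <- presets$table2[i, ]
    id <- tolower(gsub("[^A-Za-z0-9]+", "_", row$preset))
    f <- fit_resource_response(suite$series[[id]], reduced = TRUE)
    expect_equal(f$params$ln_P_max, row$ln_P_max,
                 tolerance = 1e-4 * row$ln_P_max)
    expect_equal(f$params$Kp, row$Kp, tolerance = 1e-4 * row$Kp)
  }
})

test_that("preset lookup resolves both tables and rejects unknowns", {
  pe <- preset_params("table1/wheat/cpFBPase")
  expect_s3_class(pe, "exponential_params")
  expect_equal(pe$alpha, 17.37)
  pm <- preset_params("table2/oryza_sativa/36Pa")
  expect_s3_class(pm, "resource_params")
  expect_equal(pm$Kp, 46.83)
  expect_true(pm$reduced)
  expect_error(preset_params("table1/wheat/nope"),
               class = "edm_validation_error")
})

test_that("recovery experiment matches an independent plain-loop aggregation", {
  p <- exponential_params(15, 0.02)
  grid <- seq(10, 100, length.out = 10)
  rep_ <- recovery_experiment(p, grid = grid,
                              noise = noise_spec("multiplicative_lognormal",
                                                 0.05),
                              n_reps = 25, seed = 6, compare = FALSE)
  # plain loop on the same per-replicate seed scheme
  est <- t(vapply(1:25, function(r) {
    s <- gen_enzyme_series(p, x_grid = grid,
                           noise = noise_spec("multiplicative_lognormal",
                                              0.05, seed = 6000 + r))
    f <- fit_exponential(s, seed = 6000 + r)
    c(f$params$alpha, f$params$b)
  }, numeric(2)))
  expect_equal(unname(rep_$bias),
               unname(colMeans(est) - c(15, 0.02)), tolerance = 1e-10)
  expect_equal(unname(rep_$rmse),
               unname(sqrt(colMeans(sweep(est, 2, c(15, 0.02))^2))),
               tolerance = 1e-10)
  # RMSE^2 >= bias^2 componentwise
  expect_true(all(rep_$rmse^2 >= rep_$bias^2 - 1e-15))
})

test_that("zero-noise recovery report is exact and flagged degenerate", {
  p <- exponential_params(15, 0.02)
  rep_ <- recovery_experiment(p, noise = noise_spec(level = 0),
                              n_reps = 3, seed = 2, compare = FALSE)
  expect_true(all(abs(rep_$bias) < 1e-6))
  expect_true(all(rep_$rmse < 1e-6))
  expect_true(rep_$coverage_degenerate)
  expect_error(recovery_experiment(p, n_reps = 1),
               class = "edm_validation_error")
})

test_that("more design points shrink the RMSE of the activity coefficient", {
  p <- exponential_params(15, 0.02)
  r8 <- recovery_experiment(p, grid = seq(0.2, 2, length.out = 8) / 0.02,
                            noise = noise_spec("multiplicative_lognormal",
                                               0.05),
                            n_reps = 120, seed = 3, compare = FALSE)
  r30 <- recovery_experiment(p, grid = seq(0.2, 2, length.out = 30) / 0.02,
                             noise = noise_spec("multiplicative_lognormal",
                                                0.05),
                             n_reps = 120, seed = 3, compare = FALSE)
  expect_lt(r30$rmse[["b"]], r8$rmse[["b"]])
})
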