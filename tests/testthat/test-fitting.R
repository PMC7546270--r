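test_that("noiseless exponential data are recovered exactly", {
  s <- gen_enzyme_series(exponential_params(2, 0.5), x_grid = 0:4,
                         noise = noise_spec(level = 0))
  f <- fit_exponential(s)
  expect_true(f$converged)
  expect_equal(f$params$alpha, 2, tolerance = 1e-6)
  expect_equal(f$params$b, 0.5, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
})

test_that("exponential optimum matches the brute-force grid oracle", {
  s <- toy_exp_series()
  f <- fit_exponential(s)
  oracle <- grid_oracle_exponential(s$x, s$y)
  expect_lte(f$rss, oracle$rss + 1e-9)
  expect_equal(f$params$alpha, oracle$alpha, tolerance = 1e-3)
  expect_equal(f$params$b, oracle$b, tolerance = 1e-3)
})

test_that("linear fit equals the normal-equations solution", {
  s <- toy_exp_series()
  f <- fit_linear(s)
  oracle <- ols_oracle(s$x, s$y)
  expect_equal(f$params$intercept, oracle$intercept, tolerance = 1e-12)
  expect_equal(f$params$slope, oracle$slope, tolerance = 1e-12)
  expect_equal(f$rss, oracle$rss, tolerance = 1e-12)
  # exact line and constant-response edge cases
  line <- response_series(0:4, 1 + 2 * (0:4))
  fl <- fit_linear(line)
  expect_equal(fl$params$intercept, 1, tolerance = 1e-12)
  expect_equal(fl$params$slope, 2, tolerance = 1e-12)
  expect_equal(fl$r_squared, 1, tolerance = 1e-12)
  const <- response_series(0:4, rep(3, 5))
  expect_equal(fit_linear(const)$params$slope, 0, tolerance = 1e-12)
  expect_error(fit_linear(response_series(rep(2, 4), 1:4)),
               class = "edm_validation_error")
})

test_that("reduced nitrogen-response fit matches its grid oracle and presets", {
  s <- toy_mm_series()
  f <- fit_resource_response(s, reduced = TRUE)
  oracle <- grid_oracle_resource(s$x, log(s$y), reduced = TRUE)
  expect_lte(f$rss, oracle$rss + 1e-9)
  # zero-noise preset recovery (maize at 36 Pa)
  p <- preset_params("table2/zea_mays/36Pa")
  sz <- gen_nitrogen_series(p, noise = noise_spec("additive_gaussian", 0))
  fz <- fit_resource_response(sz, reduced = TRUE)
  expect_true(fz$converged)
  expect_equal(fz$params$ln_P_max, 4.72, tolerance = 1e-5)
  expect_equal(fz$params$Kp, 29.19, tolerance = 1e-4)
})

test_that("full nitrogen-response fit recovers the identifiable combinations", {
  # the 4-parameter variant carries a structural ridge: only the asymptote,
  # the product ln_P_max * Kp and the shift R0 - Kp are determined by data
  truth <- resource_params(4, 20, R0 = 5, ln_P0 = 1)
  s <- gen_nitrogen_series(truth, R_grid = seq(6, 120, length.out = 12),
                           noise = noise_spec("additive_gaussian", 0))
  f <- fit_resource_response(s, reduced = FALSE)
  expect_lt(f$rss, 1e-12)
  got <- resource_identifiable(f$params$ln_P_max, f$params$Kp,
                               f$params$R0, f$params$ln_P0)
  want <- resource_identifiable(4, 20, 5, 1)
  expect_equal(got, want, tolerance = 1e-4)
  # and its optimum is no worse than the brute-force 4-D grid oracle
  st <- toy_mm_series()
  ff <- fit_resource_response(st, reduced = FALSE)
  oracle <- grid_oracle_resource(st$x, log(st$y), reduced = FALSE)
  expect_lte(ff$rss, oracle$rss + 1e-9)
})

test_that("R0 never exceeds the smallest observed nitrogen content", {
  withr::with_seed(31, {
    for (i in 1:20) {
      p <- resource_params(runif(1, 1, 6), runif(1, 5, 60),
                           R0 = runif(1, -10, 10), reduced = TRUE)
      s <- gen_nitrogen_series(p, noise = noise_spec("additive_gaussian",
                                                     0.1, seed = i))
      f <- fit_resource_response(s, reduced = TRUE, seed = i)
      expect_lte(f$params$R0, min(s$x))
    }
  })
})

test_that("linear standard errors equal the textbook OLS formulas", {
  s <- toy_exp_series()
  f <- fit_linear(s)
  sm <- summary(stats::lm(s$y ~ s$x))
  expect_equal(unname(f$se), unname(sm$coefficients[, "Std. Error"]),
               tolerance = 1e-10)
})

test_that("exponential standard errors agree with nlsLM's covariance", {
  s <- gen_enzyme_series(exponential_params(15, 0.02),
                         noise = noise_spec(level = 0.05, seed = 9))
  f <- fit_exponential(s)
  ref <- minpack.lm::nlsLM(y ~ a * exp(b * x),
                           data = data.frame(x = s$x, y = s$y),
                           start = list(a = f$params$alpha, b = f$params$b))
  expect_equal(unname(f$se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-4)
})

test_that("degenerate designs yield undefined SEs with a diagnostic, not zeros", {
  # n == k_model: zero residual degrees of freedom
  s <- response_series(c(1, 1, 2), c(2, 2.5, 3))
  f <- fit_linear(response_series(c(1, 2, 3), c(2, 2.5, 3)))
  f$n <- 2L  # simulate n == k_model for the SE path
  se <- estimate_standard_errors(f, response_series(c(1, 2, 3), c(2, 2.5, 3)))
  expect_true(all(is.na(se$se)))
  expect_match(se$diagnostic, "degrees of freedom")
})

test_that("information criteria follow the stated Gaussian formulas", {
  ic <- information_criteria(rss = 10, n = 20, k = 3)
  expect_equal(ic$aic, -7.8629436112, tolerance = 1e-9)
  expect_equal(ic$aicc, -6.3629436112, tolerance = 1e-9)
  # one extra parameter at equal rss costs exactly 2 AIC units
  expect_equal(information_criteria(5, 20, 4)$aic -
                 information_criteria(5, 20, 3)$aic, 2)
  # halving rss at fixed n, k lowers AIC by n log 2
  expect_equal(information_criteria(10, 20, 3)$aic -
                 information_criteria(5, 20, 3)$aic, 20 * log(2))
  # AICc exceeds AIC and is undefined without enough points
  expect_gt(ic$aicc, ic$aic)
  tight <- information_criteria(1, 4, 3)
  expect_false(tight$aicc_defined)
  expect_true(is.na(tight$aicc))
  expect_error(information_criteria(0, 10, 2),
               class = "edm_validation_error")
  expect_error(information_criteria(1, 3, 3), class = "edm_validation_error")
})

test_that("fits refuse series that are too short", {
  s <- response_series(c(1, 2, 3), c(1, 2, 3) + 0.5)
  expect_error(fit_exponential(response_series(1:2 * 1.0, c(1, 2),
                                               series_id = "short")),
               class = "edm_insufficient_data")
  expect_error(fit_resource_response(s, reduced = FALSE),
               class = "edm_insufficient_data")
  # but the reduced variant accepts 3 points
  expect_s3_class(suppressWarnings(fit_resource_response(s, reduced = TRUE)),
                  "edm_fit")
})

test_that("zero-noise parameter recovery holds across seeded draws", {
  withr::with_seed(99, {
    for (i in 1:30) {
      pe <- exponential_params(runif(1, 5, 30), runif(1, 0.005, 0.08))
      se <- gen_enzyme_series(pe, noise = noise_spec(level = 0))
      fe <- fit_exponential(se)
      expect_equal(fe$params$alpha, pe$alpha, tolerance = 1e-4)
      expect_equal(fe$params$b, pe$b, tolerance = 1e-4)

      pm <- resource_params(runif(1, 1, 6), runif(1, 5, 60),
                            R0 = runif(1, -5, 5), reduced = TRUE)
      sm <- gen_nitrogen_series(pm, noise = noise_spec("additive_gaussian", 0))
      fm <- fit_resource_response(sm, reduced = TRUE)
      expect_equal(fm$params$ln_P_max, pm$ln_P_max,
                   tolerance = 1e-4 * max(1, pm$ln_P_max))
      expect_equal(fm$params$Kp, pm$Kp, tolerance = 1e-4 * pm$Kp)
    }
  })
})

test_that("estimation error grows with the noise level", {
  pe <- exponential_params(15, 0.02)
  pm <- resource_params(4.72, 29.19, R0 = 0, reduced = TRUE)
  med_b <- med_Kp <- numeric(0)
  for (lv in c(0, 0.02, 0.05, 0.10)) {
    re <- recovery_experiment(pe, grid = seq(0.2, 2, length.out = 20) / 0.02,
                              noise = noise_spec("multiplicative_lognormal",
                                                 lv),
                              n_reps = 60, seed = 5, compare = FALSE)
    rm_ <- recovery_experiment(pm,
                               grid = seq(2.9, 117, length.out = 20),
                               noise = noise_spec("additive_gaussian", lv),
                               n_reps = 60, seed = 5, compare = FALSE)
    med_b <- c(med_b, median(abs(re$estimates[, "b"] - pe$b), na.rm = TRUE))
    med_Kp <- c(med_Kp, median(abs(rm_$estimates[, "Kp"] - pm$Kp),
                               na.rm = TRUE))
  }
  expect_true(all(diff(med_b) >= 0))
  expect_true(all(diff(med_Kp) >= 0))
})

test_that("fitting a mismatched predictor kind warns but proceeds", {
  s <- gen_nitrogen_series(resource_params(4, 20, reduced = TRUE),
                           noise = noise_spec("additive_gaussian", 0))
  expect_warning(fit_exponential(s), "enzyme activity")
  s2 <- gen_enzyme_series(exponential_params(10, 0.05),
                          noise = noise_spec(level = 0))
  expect_warning(fit_resource_response(s2, reduced = TRUE), "leaf N")
})
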