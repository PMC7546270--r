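# Nonlinear least-squares estimation of the three model families.
#
# Conventions, applied uniformly:
#   * exponential and linear models are fitted on the raw response scale;
#     the nitrogen-response model on the log scale (responses are
#     log-transformed before that fit);
#   * R^2 = 1 - RSS/TSS on the fitting scale (may be negative, not clamped);
#   * AIC uses the Gaussian profile likelihood, AIC = n log(RSS/n) + 2k,
#     with k = free curve parameters + 1 for the residual variance;
#   * standard errors come from the linearization s^2 (J'J)^-1 with
#     s^2 = RSS/(n - k_model) and J the prediction Jacobian at the optimum.

new_edm_fit <- function(model_kind, params, se, n, k_model, rss, tss,
                        r_squared, aic, aicc, converged, n_starts,
                        best_start, scale, series_id) {
  structure(
    list(model_kind = model_kind, params = params, se = se, n = n,
         k_model = k_model, k = k_model + 1L, rss = rss, tss = tss,
         r_squared = r_squared, aic = aic, aicc = aicc,
         converged = converged, n_starts = n_starts, best_start = best_start,
         scale = scale, series_id = series_id),
    class = "edm_fit"
  )
}

#' @export
print.edm_fit <- function(x, ...) {
  cat(sprintf("<edm_fit> %s on series '%s' (%s scale)\n",
              x$model_kind, x$series_id, x$scale))
  est <- unlist(x$params[names(x$se)])
  tab <- data.frame(estimate = signif(est, 6),
                    se = signif(x$se, 4))
  print(tab)
  cat(sprintf("  n = %d, RSS = %.6g, R2 = %.4f, AIC = %.3f, AICc = %s\n",
              x$n, x$rss, x$r_squared, x$aic,
              if (is.na(x$aicc)) "undefined" else sprintf("%.3f", x$aicc)))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' Gaussian-likelihood information criteria
#'
#' Computes AIC = n log(RSS/n) + 2k and its small-sample correction
#' AICc = AIC + 2k(k+1)/(n - k - 1), where k counts all estimated
#' parameters including the residual variance. AICc is undefined (returned
#' as `NA` with `aicc_defined = FALSE`) when `n <= k + 1`.
#'
#' @param rss Residual sum of squares on the fitting scale, positive.
#' @param n Number of observations.
#' @param k Total parameter count (curve parameters + 1 for the variance).
#' @return List with `aic`, `aicc`, `aicc_defined`.
#' @examples
#' information_criteria(rss = 10, n = 20, k = 3)
#' @export
information_criteria <- function(rss, n, k) {
  if (!is.finite(rss) || rss <= 0) {
    edm_stop("`rss` must be positive; an exact fit has no finite AIC.",
             "edm_validation_error")
  }
  if (n <= k) {
    edm_stop("`n` must exceed the parameter count `k`.",
             "edm_validation_error")
  }
  aic <- n * log(rss / n) + 2 * k
  if (n <= k + 1) {
    list(aic = aic, aicc = NA_real_, aicc_defined = FALSE)
  } else {
    list(aic = aic, aicc = aic + 2 * k * (k + 1) / (n - k - 1),
         aicc_defined = TRUE)
  }
}

# Safe criteria for fits: an exact (rss ~ 0) fit gets -Inf so it still wins
# comparisons, and a saturated fit (n <= k) gets NA rather than an error so
# minimal-length series can still be fitted and reported.
fit_criteria <- function(rss, n, k) {
  if (n <= k) {
    return(list(aic = NA_real_, aicc = NA_real_, aicc_defined = FALSE))
  }
  if (rss <= .Machine$double.xmin) {
    return(list(aic = -Inf, aicc = -Inf, aicc_defined = n > k + 1))
  }
  information_criteria(rss, n, k)
}

#' Linearization-based standard errors
#'
#' Recomputes per-parameter standard errors for a fitted model from the
#' first-order covariance s^2 (J'J)^-1, where J is the Jacobian of the
#' model predictions with respect to the curve parameters at the optimum and
#' s^2 = RSS/(n - k_model). A singular J'J (e.g. a degenerate design or
#' zero residual degrees of freedom) yields `NA` standard errors together
#' with a `diagnostic` message, never zeros.
#'
#' @param fit An `edm_fit` object.
#' @param series The `response_series` the fit was computed on.
#' @return List with `se` (named numeric) and `diagnostic` (`NULL` or
#'   character).
#' @export
estimate_standard_errors <- function(fit, series) {
  stopifnot(inherits(fit, "edm_fit"))
  check_series(series, min_n = 2L)
  x <- series$x
  p <- fit$params
  J <- switch(
    fit$model_kind,
    exponential = {
      e <- exp(p$b * x)
      cbind(alpha = e, b = p$alpha * x * e)
    },
    linear = cbind(intercept = rep(1, length(x)), slope = x),
    resource_response_full = ,
    resource_response_reduced = {
      u <- x - p$R0
      d <- p$Kp + u
      Jm <- cbind(ln_P_max = u / d,
                  Kp = -p$ln_P_max * u / d^2,
                  R0 = -p$ln_P_max * p$Kp / d^2)
      if (fit$model_kind == "resource_response_full") {
        Jm <- cbind(Jm, ln_P0 = rep(1, length(x)))
      }
      Jm
    },
    edm_stop(sprintf("Unknown model kind '%s'.", fit$model_kind),
             "edm_validation_error")
  )
  dof <- fit$n - fit$k_model
  if (dof <= 0) {
    return(list(se = stats::setNames(rep(NA_real_, ncol(J)), colnames(J)),
                diagnostic = "zero residual degrees of freedom"))
  }
  JtJ <- crossprod(J)
  inv <- tryCatch(solve(JtJ), error = function(e) NULL)
  if (is.null(inv) || any(!is.finite(diag(inv))) || any(diag(inv) < 0)) {
    return(list(se = stats::setNames(rep(NA_real_, ncol(J)), colnames(J)),
                diagnostic = "singular J'J: standard errors undefined"))
  }
  s2 <- fit$rss / dof
  list(se = stats::setNames(sqrt(s2 * diag(inv)), colnames(J)),
       diagnostic = NULL)
}

#' Fit the exponential enzyme law
#'
#' Minimizes sum (y - alpha exp(b x))^2 on the raw response scale by
#' Levenberg-Marquardt least squares. The starting point comes from ordinary
#' least squares of log y on x (alpha0 = exp(intercept), b0 = slope), and a
#' deterministic grid of multiplicative perturbations of that start (derived
#' from `seed`) guards against local minima. Non-convergence after all starts
#' is flagged in the result (`converged = FALSE`), never silently dropped.
#'
#' @param series A `response_series`; a warning is issued (not an error) when
#'   `predictor_kind` is not `"enzyme_activity"`.
#' @param seed Integer seed for the deterministic restart sequence.
#' @param n_restarts Number of perturbed restarts beyond the log-linear start.
#' @return An `edm_fit` with `model_kind = "exponential"`.
#' @examples
#' s <- response_series(0:4, 2 * exp(0.5 * (0:4)))
#' fit_exponential(s)$params
#' @export
fit_exponential <- function(series, seed = 1L, n_restarts = 8L) {
  check_series(series, min_n = 3L)
  if (series$predictor_kind != "enzyme_activity") {
    warning("fitting the enzyme law to a series whose predictor is not an ",
            "enzyme activity", call. = FALSE)
  }
  x <- series$x
  y <- series$y
  n <- length(x)

  ols <- stats::lm.fit(cbind(1, x), log(y))
  start0 <- c(alpha = exp(ols$coefficients[[1]]), b = ols$coefficients[[2]])
  fac <- restart_factors(n_restarts, 2L, seed)
  starts <- rbind(start0,
                  t(apply(fac, 1L, function(f) {
                    c(start0[1] * f[1],
                      # b may be near 0 or negative: perturb additively on a
                      # scale set by the data range as well as multiplicatively
                      start0[2] * f[2] + (f[1] - 1) / max(diff(range(x)), 1))
                  })))

  best <- NULL
  best_start <- NULL
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                     maxiter = 200)
  for (i in seq_len(nrow(starts))) {
    st <- list(alpha = starts[i, 1], b = starts[i, 2])
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ alpha * exp(b * x),
        data = data.frame(x = x, y = y),
        start = st, control = ctrl)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12 * (1 + best$rss)) {
      best <- list(fit = fit, rss = rss,
                   converged = isTRUE(fit$convInfo$isConv))
      best_start <- st
    }
  }

  if (is.null(best)) {
    # degenerate series: return the start as a non-converged result
    params <- exponential_params(max(start0[[1]], 1e-12), start0[[2]])
    rss <- sum((y - predict_exponential(params, x))^2)
    converged <- FALSE
    best_start <- as.list(start0)
  } else {
    cf <- stats::coef(best$fit)
    params <- exponential_params(cf[["alpha"]], cf[["b"]])
    rss <- best$rss
    converged <- best$converged
  }

  tss <- sum((y - mean(y))^2)
  ic <- fit_criteria(rss, n, 3L)
  out <- new_edm_fit("exponential", params,
                     se = c(alpha = NA_real_, b = NA_real_),
                     n = n, k_model = 2L, rss = rss, tss = tss,
                     r_squared = 1 - rss / tss, aic = ic$aic, aicc = ic$aicc,
                     converged = converged, n_starts = nrow(starts),
                     best_start = best_start, scale = "raw",
                     series_id = series$series_id)
  se <- estimate_standard_errors(out, series)
  out$se <- se$se
  out$se_diagnostic <- se$diagnostic
  out
}

#' Fit the linear comparison model
#'
#' Ordinary least squares of the raw response on the predictor; closed form
#' and always converged. Provided as the alternative the exponential enzyme
#' law is compared against by AIC.
#'
#' @param series A `response_series`.
#' @return An `edm_fit` with `model_kind = "linear"`.
#' @export
fit_linear <- function(series) {
  check_series(series, min_n = 3L)
  x <- series$x
  y <- series$y
  n <- length(x)
  if (stats::sd(x) == 0) {
    edm_stop("Degenerate design: all `x` values identical (rank-deficient).",
             "edm_validation_error")
  }
  cf <- stats::lm.fit(cbind(1, x), y)$coefficients
  params <- linear_params(cf[[1]], cf[[2]])
  resid <- y - predict_linear(params, x)
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  ic <- fit_criteria(rss, n, 3L)
  out <- new_edm_fit("linear", params,
                     se = c(intercept = NA_real_, slope = NA_real_),
                     n = n, k_model = 2L, rss = rss, tss = tss,
                     r_squared = 1 - rss / tss, aic = ic$aic, aicc = ic$aicc,
                     converged = TRUE, n_starts = 1L,
                     best_start = as.list(cf), scale = "raw",
                     series_id = series$series_id)
  se <- estimate_standard_errors(out, series)
  out$se <- se$se
  out$se_diagnostic <- se$diagnostic
  out
}

# Profile RSS of the nitrogen-response model at fixed (R0, Kp): the model is
# linear in (ln_P_max, ln_P0) given the saturating regressor g = u/(Kp+u).
profile_node <- function(z, x, R0, Kp, reduced) {
  u <- x - R0
  g <- u / (Kp + u)
  if (reduced) {
    denom <- sum(g^2)
    if (denom <= 0) return(NULL)
    L <- sum(g * z) / denom
    p0 <- 0
  } else {
    X <- cbind(g, 1)
    cf <- tryCatch(stats::lm.fit(X, z)$coefficients,
                   error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) return(NULL)
    L <- cf[[1]]
    p0 <- cf[[2]]
  }
  if (!is.finite(L) || L <= 0) return(NULL)
  rss <- sum((z - (L * g + p0))^2)
  list(ln_P_max = L, Kp = Kp, R0 = R0, ln_P0 = p0, rss = rss)
}

#' Fit the log-scale nitrogen-response law
#'
#' Minimizes sum (ln y - [ln_P_max (x - R0)/(Kp + (x - R0)) + ln_P0])^2
#' subject to Kp > 0 and R0 <= min(x) - eps, with
#' eps = 1e-9 * range(x) so the effective resource stays nonnegative at every
#' observation (the bound is enforced by the optimizer, never by clipping
#' data). Initialization profiles a coarse (R0, Kp) grid, solving for
#' (ln_P_max, ln_P0) by linear least squares at each node since the model is
#' linear in those two; the best nodes seed bounded quasi-Newton refinement,
#' plus seeded perturbed restarts. R^2 is reported on the log scale.
#'
#' @param series A `response_series`; a warning is issued when
#'   `predictor_kind` is not `"leaf_N"`.
#' @param reduced Logical; `TRUE` fixes `ln_P0 = 0` (three curve parameters),
#'   `FALSE` estimates it (four).
#' @param seed Integer seed for the deterministic restart sequence.
#' @param n_restarts Perturbed restarts beyond the grid-profiled starts.
#' @return An `edm_fit` with `model_kind = "resource_response_full"` or
#'   `"resource_response_reduced"`.
#' @export
fit_resource_response <- function(series, reduced = FALSE, seed = 1L,
                                  n_restarts = 8L) {
  check_series(series, min_n = if (reduced) 3L else 4L)
  if (series$predictor_kind != "leaf_N") {
    warning("fitting the nitrogen-response law to a series whose predictor ",
            "is not a leaf N content", call. = FALSE)
  }
  x <- series$x
  z <- log(series$y)
  n <- length(x)
  rng <- max(diff(range(x)), .Machine$double.eps)
  eps <- 1e-9 * rng
  R0_max <- min(x) - eps

  # coarse profile grid
  R0_grid <- seq(min(x) - 2 * rng, R0_max, length.out = 7L)
  Kp_grid <- exp(seq(log(0.05 * rng), log(5 * rng), length.out = 12L))
  nodes <- list()
  for (R0 in R0_grid) {
    for (Kp in Kp_grid) {
      nd <- profile_node(z, x, R0, Kp, reduced)
      if (!is.null(nd)) nodes[[length(nodes) + 1L]] <- nd
    }
  }
  if (length(nodes) == 0) {
    edm_stop("No admissible starting point found for the nitrogen-response fit.",
             "edm_validation_error")
  }
  nodes <- nodes[order(vapply(nodes, `[[`, numeric(1), "rss"))]
  starts <- nodes[seq_len(min(3L, length(nodes)))]

  npar <- if (reduced) 3L else 4L
  fac <- restart_factors(n_restarts, 3L, seed)
  base <- starts[[1]]
  for (i in seq_len(nrow(fac))) {
    starts[[length(starts) + 1L]] <- list(
      ln_P_max = base$ln_P_max * fac[i, 1],
      Kp = base$Kp * fac[i, 2],
      R0 = R0_max - (R0_max - base$R0) * fac[i, 3],
      ln_P0 = base$ln_P0, rss = NA_real_)
  }

  resid_fn <- function(p) {
    u <- x - p[3]
    z - (p[1] * u / (p[2] + u) + if (reduced) 0 else p[4])
  }
  jac_fn <- function(p) {
    u <- x - p[3]
    d <- p[2] + u
    J <- cbind(-u / d, p[1] * u / d^2, p[1] * p[2] / d^2)
    if (!reduced) J <- cbind(J, -1)
    J
  }
  lower <- c(1e-10, 1e-10, -Inf, -Inf)[seq_len(npar)]
  upper <- c(Inf, Inf, R0_max, Inf)[seq_len(npar)]
  lm_ctrl <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                        gtol = 1e-15, maxiter = 500)

  best <- NULL
  best_start <- NULL
  for (st in starts) {
    p0 <- c(max(st$ln_P_max, 1e-8), max(st$Kp, 1e-8), min(st$R0, R0_max))
    if (!reduced) p0 <- c(p0, st$ln_P0)
    opt <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fn, jac = jac_fn, control = lm_ctrl),
      error = function(e) NULL)
    if (is.null(opt)) next
    val <- sum(resid_fn(opt$par)^2)
    conv <- opt$info %in% 1:3  # ftol/ptol convergence codes
    if (is.null(best) || val < best$value - 1e-14 * (1 + best$value)) {
      best <- list(par = opt$par, value = val,
                   convergence = if (conv) 0L else 1L)
      best_start <- st[c("ln_P_max", "Kp", "R0", "ln_P0")]
    }
  }
  if (is.null(best)) {
    best <- list(par = c(base$ln_P_max, base$Kp, base$R0,
                         base$ln_P0)[seq_len(npar)],
                 value = base$rss, convergence = 1L)
    best_start <- base[c("ln_P_max", "Kp", "R0", "ln_P0")]
  }

  p <- best$par
  params <- resource_params(ln_P_max = p[1], Kp = p[2], R0 = p[3],
                            ln_P0 = if (reduced) 0 else p[4],
                            reduced = reduced)
  rss <- best$value
  tss <- sum((z - mean(z))^2)
  kind <- if (reduced) "resource_response_reduced" else "resource_response_full"
  ic <- fit_criteria(rss, n, npar + 1L)
  out <- new_edm_fit(kind, params, se = NULL, n = n, k_model = npar,
                     rss = rss, tss = tss, r_squared = 1 - rss / tss,
                     aic = ic$aic, aicc = ic$aicc,
                     converged = best$convergence == 0L,
                     n_starts = length(starts), best_start = best_start,
                     scale = "log", series_id = series$series_id)
  se <- estimate_standard_errors(out, series)
  out$se <- se$se
  out$se_diagnostic <- se$diagnostic
  out
}
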