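# Model comparison: exponential vs linear enzyme law (and full vs reduced
# nitrogen-response variants) by AIC, with Akaike weights and a regression
# F-test of the preferred model against the intercept-only model.

AIC_TIE_TOL <- 1e-9

akaike_weights <- function(aic) {
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w / sum(w)
}

fit_by_kind <- function(series, kind, seed = 1L) {
  switch(kind,
         exponential = fit_exponential(series, seed = seed),
         linear = fit_linear(series),
         resource_response_full =
           fit_resource_response(series, reduced = FALSE, seed = seed),
         resource_response_reduced =
           fit_resource_response(series, reduced = TRUE, seed = seed),
         edm_stop(sprintf("Unknown model kind '%s'.", kind),
                  "edm_validation_error"))
}

#' Regression F-test against the intercept-only model
#'
#' Tests whether the fitted model explains more variance than a constant:
#' F = [(TSS - RSS)/(k_model - 1)] / [RSS/(n - k_model)] on the model's own
#' fitting scale, referred to an F(k_model - 1, n - k_model) distribution.
#' This is the package's significance test for a fitted relationship (the
#' regression analogue of a one-way analysis of variance on the trend). An
#' exact fit (zero residual variance) reports the limiting p-value 0 with
#' `exact_fit = TRUE`.
#'
#' @param fit A converged `edm_fit`.
#' @param series The series the fit was computed on.
#' @return List with `f_statistic`, `f_pvalue`, `df1`, `df2`, `exact_fit`.
#' @export
regression_f_test <- function(fit, series) {
  stopifnot(inherits(fit, "edm_fit"))
  check_series(series)
  n <- fit$n
  k <- fit$k_model
  if (n <= k) {
    edm_stop("F-test requires n > k_model.", "edm_validation_error")
  }
  rss <- fit$rss
  tss <- fit$tss
  df1 <- k - 1L
  df2 <- n - k
  if (rss <= .Machine$double.eps * tss) {
    return(list(f_statistic = Inf, f_pvalue = 0, df1 = df1, df2 = df2,
                exact_fit = TRUE))
  }
  f <- ((tss - rss) / df1) / (rss / df2)
  list(f_statistic = f,
       f_pvalue = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, exact_fit = FALSE)
}

#' Compare model families on one series by AIC
#'
#' Fits each requested model kind to the same points, then reports AIC
#' differences, Akaike weights w_i = exp(-D_i/2) / sum_j exp(-D_j/2), the
#' preferred model (minimum AIC; ties within 1e-9 resolved toward the model
#' with fewer parameters, the parsimony rule), and the regression F-test of
#' the preferred model. When the canonical pairs are present, `delta_aic` is
#' reported with the conventional sign: linear minus exponential, or full
#' minus reduced. Any non-converged member fit sets `caveat = TRUE`; the
#' comparison is still emitted, never silently dropped.
#'
#' @param series A `response_series`.
#' @param kinds Character vector of at least two of `"exponential"`,
#'   `"linear"`, `"resource_response_full"`, `"resource_response_reduced"`.
#' @param seed Seed forwarded to the multi-start fitters.
#' @return An object of class `edm_comparison`.
#' @examples
#' s <- response_series(seq(10, 100, length.out = 12),
#'                      17 * exp(0.02 * seq(10, 100, length.out = 12)))
#' compare_models(s)
#' @export
compare_models <- function(series, kinds = c("exponential", "linear"),
                           seed = 1L) {
  check_series(series)
  kinds <- unique(kinds)
  if (length(kinds) < 2L) {
    edm_stop("At least two model kinds are required for a comparison.",
             "edm_validation_error")
  }
  fits <- lapply(kinds, function(k) fit_by_kind(series, k, seed = seed))
  names(fits) <- kinds

  aic <- vapply(fits, `[[`, numeric(1), "aic")
  kmod <- vapply(fits, `[[`, integer(1), "k_model")
  w <- akaike_weights(aic)

  # preferred: minimal AIC, ties toward fewer parameters
  cand <- which(aic <= min(aic) + AIC_TIE_TOL)
  preferred <- kinds[cand[which.min(kmod[cand])]]

  delta_aic <- NA_real_
  if (all(c("exponential", "linear") %in% kinds)) {
    delta_aic <- aic[["linear"]] - aic[["exponential"]]
  } else if (all(c("resource_response_full",
                   "resource_response_reduced") %in% kinds)) {
    delta_aic <- aic[["resource_response_full"]] -
      aic[["resource_response_reduced"]]
  }

  ftest <- regression_f_test(fits[[preferred]], series)
  structure(
    list(series_id = series$series_id, fits = fits,
         delta_aic = delta_aic,
         akaike_weights = stats::setNames(w, kinds),
         preferred = preferred,
         f_statistic = ftest$f_statistic, f_pvalue = ftest$f_pvalue,
         exact_fit = ftest$exact_fit,
         caveat = any(!vapply(fits, `[[`, logical(1), "converged"))),
    class = "edm_comparison"
  )
}

#' @export
print.edm_comparison <- function(x, ...) {
  cat(sprintf("<edm_comparison> series '%s'\n", x$series_id))
  aic <- vapply(x$fits, `[[`, numeric(1), "aic")
  r2 <- vapply(x$fits, `[[`, numeric(1), "r_squared")
  tab <- data.frame(AIC = round(aic, 3), R2 = round(r2, 4),
                    weight = round(x$akaike_weights, 4))
  print(tab)
  cat(sprintf("  preferred: %s (F = %.4g, p = %.3g%s)\n", x$preferred,
              x$f_statistic, x$f_pvalue,
              if (x$exact_fit) ", exact fit" else ""))
  if (x$caveat) cat("  CAVEAT: at least one member fit did not converge\n")
  invisible(x)
}
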