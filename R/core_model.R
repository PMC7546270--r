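# Domain types and closed-form predictions of the enzyme-driven model (EDM).
#
# Two laws are implemented:
#   * an exponential enzyme law, P = alpha * exp(b * vp), linking net CO2
#     assimilation P (umol CO2 m-2 s-1) to the activity vp of a rate-limiting
#     photosynthetic enzyme (umol m-2 s-1);
#   * a saturating resource law on the log scale,
#     ln P = ln_P_max * (R - R0) / (Kp + (R - R0)) + ln_P0,
#     a Michaelis-Menten-type response of ln P to effective leaf nitrogen
#     R - R0 above a storage baseline R0, with half-saturation constant Kp.

#' Construct a digitized predictor/response point series
#'
#' A `response_series` is the universal input of the package: one series of
#' (predictor, response) points digitized from a published figure or table,
#' together with the metadata needed to interpret it. The predictor is either
#' an enzyme activity or a leaf nitrogen content; the response is a
#' photosynthetic or CO2 assimilation rate, which must be strictly positive
#' because the nitrogen-response law is fitted on the log scale.
#'
#' @param x Numeric vector of predictor values (finite; duplicates allowed).
#' @param y Numeric vector of response values, strictly positive, same length
#'   as `x`.
#' @param species Species label, e.g. `"Triticum aestivum"`.
#' @param pathway Photosynthetic pathway, `"C3"` or `"C4"`.
#' @param predictor_kind `"enzyme_activity"` or `"leaf_N"`.
#' @param predictor_name Free-text predictor label, e.g. `"Rubisco"` or
#'   `"leaf N per area"`.
#' @param co2_partial_pressure_Pa Optional CO2 partial pressure (Pa) at which
#'   the series was measured; `NA` when not applicable.
#' @param x_units,y_units Unit strings carried as metadata and never converted.
#' @param source_ref Free-text provenance (citation or preset name).
#' @param series_id Optional identifier; defaults to a slug built from the
#'   metadata.
#'
#' @return An object of class `response_series`.
#' @examples
#' s <- response_series(x = 0:4, y = 2 * exp(0.5 * (0:4)),
#'                      species = "Triticum aestivum", pathway = "C3",
#'                      predictor_kind = "enzyme_activity",
#'                      predictor_name = "Rubisco")
#' s
#' @export
response_series <- function(x, y,
                            species = "unspecified",
                            pathway = c("C3", "C4"),
                            predictor_kind = c("enzyme_activity", "leaf_N"),
                            predictor_name = "",
                            co2_partial_pressure_Pa = NA_real_,
                            x_units = "umol m-2 s-1",
                            y_units = "umol CO2 m-2 s-1",
                            source_ref = "",
                            series_id = NULL) {
  pathway <- match.arg(pathway)
  predictor_kind <- match.arg(predictor_kind)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    edm_stop("`x` and `y` must have the same length.", "edm_validation_error")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    edm_stop("All `x` values must be finite.", "edm_validation_error")
  }
  if (anyNA(y) || any(!is.finite(y)) || any(y <= 0)) {
    edm_stop(paste("All `y` values must be finite and strictly positive:",
                   "responses are log-transformed before the saturation fit."),
             "edm_validation_error")
  }
  if (!is.na(co2_partial_pressure_Pa) && co2_partial_pressure_Pa < 0) {
    edm_stop("`co2_partial_pressure_Pa` must be nonnegative.",
             "edm_validation_error")
  }
  if (is.null(series_id)) {
    series_id <- tolower(gsub("[^A-Za-z0-9]+", "_",
                              paste(species, predictor_name, sep = "_")))
  }
  structure(
    list(x = x, y = y, species = species, pathway = pathway,
         predictor_kind = predictor_kind, predictor_name = predictor_name,
         co2_partial_pressure_Pa = as.numeric(co2_partial_pressure_Pa),
         x_units = x_units, y_units = y_units, source_ref = source_ref,
         series_id = series_id),
    class = "response_series"
  )
}

#' @export
print.response_series <- function(x, ...) {
  cat(sprintf("<response_series> %s\n", x$series_id))
  cat(sprintf("  %s (%s), predictor: %s [%s], n = %d points\n",
              x$species, x$pathway, x$predictor_name, x$predictor_kind,
              length(x$x)))
  if (!is.na(x$co2_partial_pressure_Pa)) {
    cat(sprintf("  CO2 partial pressure: %g Pa\n", x$co2_partial_pressure_Pa))
  }
  cat(sprintf("  x [%s]: %s\n", x$x_units,
              paste(signif(utils::head(x$x, 6), 4), collapse = ", ")))
  cat(sprintf("  y [%s]: %s\n", x$y_units,
              paste(signif(utils::head(x$y, 6), 4), collapse = ", ")))
  invisible(x)
}

check_series <- function(series, min_n = 3L) {
  if (!inherits(series, "response_series")) {
    edm_stop("`series` must be a response_series object.",
             "edm_validation_error")
  }
  if (length(series$x) < min_n) {
    edm_stop(sprintf("At least %d points are required; series has %d.",
                     min_n, length(series$x)),
             "edm_insufficient_data")
  }
  invisible(series)
}

#' Parameters of the exponential enzyme law
#'
#' Holds `alpha` (the assimilation rate at zero enzyme activity, in response
#' units) and `b` (the activity coefficient, reciprocal predictor units) of
#' the law P = alpha * exp(b * vp).
#'
#' @param alpha Positive scale, same units as the response.
#' @param b Rate coefficient per unit enzyme activity; any finite real.
#' @return Object of class `exponential_params`.
#' @examples
#' exponential_params(alpha = 17.37, b = 0.0203)
#' @export
exponential_params <- function(alpha, b) {
  check_finite_scalar(alpha, "alpha")
  check_finite_scalar(b, "b")
  if (alpha <= 0) {
    edm_stop("`alpha` must be strictly positive.", "edm_validation_error")
  }
  structure(list(alpha = alpha, b = b), class = "exponential_params")
}

#' Parameters of the linear comparison model
#'
#' The straight-line alternative against which the exponential enzyme law is
#' compared by AIC.
#'
#' @param intercept Intercept in response units.
#' @param slope Slope in response units per predictor unit.
#' @return Object of class `linear_params`.
#' @export
linear_params <- function(intercept, slope) {
  check_finite_scalar(intercept, "intercept")
  check_finite_scalar(slope, "slope")
  structure(list(intercept = intercept, slope = slope),
            class = "linear_params")
}

#' Parameters of the log-scale nitrogen-response law
#'
#' Holds the four parameters of
#' ln P = ln_P_max * (R - R0) / (Kp + (R - R0)) + ln_P0:
#' the log-scale asymptote `ln_P_max`, the half-saturation constant `Kp`
#' (predictor units), the resource offset `R0` below which no effective
#' resource is available, and the storage baseline `ln_P0` (the log
#' assimilation rate sustained at zero effective resource). The reduced
#' variant fixes `ln_P0 = 0` and drops it from the parameter count, matching
#' analyses that ignore the storage baseline.
#'
#' @param ln_P_max Positive log-scale asymptote.
#' @param Kp Positive half-saturation constant, predictor units.
#' @param R0 Resource offset, predictor units.
#' @param ln_P0 Storage baseline on the log scale; forced to 0 when
#'   `reduced = TRUE`.
#' @param reduced Logical; `TRUE` for the three-parameter variant with
#'   `ln_P0` fixed at 0.
#' @return Object of class `resource_params`.
#' @examples
#' resource_params(ln_P_max = 4.72, Kp = 29.19, R0 = 0, reduced = TRUE)
#' @export
resource_params <- function(ln_P_max, Kp, R0 = 0, ln_P0 = 0,
                            reduced = FALSE) {
  check_finite_scalar(ln_P_max, "ln_P_max")
  check_finite_scalar(Kp, "Kp")
  check_finite_scalar(R0, "R0")
  if (ln_P_max <= 0) {
    edm_stop("`ln_P_max` must be strictly positive.", "edm_validation_error")
  }
  if (Kp <= 0) {
    edm_stop("`Kp` must be strictly positive.", "edm_validation_error")
  }
  if (reduced) {
    ln_P0 <- 0
  } else {
    check_finite_scalar(ln_P0, "ln_P0")
  }
  structure(list(ln_P_max = ln_P_max, Kp = Kp, R0 = R0, ln_P0 = ln_P0,
                 reduced = isTRUE(reduced)),
            class = "resource_params")
}

#' Predict assimilation rate from enzyme activity
#'
#' Evaluates the exponential enzyme law P = alpha * exp(b * vp).
#'
#' @param params An [exponential_params()] object.
#' @param vp Enzyme activity (finite numeric, vectorized).
#' @return Predicted assimilation rate(s), strictly positive.
#' @examples
#' predict_exponential(exponential_params(17.37, 0.0203), vp = 50)
#' @export
predict_exponential <- function(params, vp) {
  stopifnot(inherits(params, "exponential_params"))
  if (anyNA(vp) || any(!is.finite(vp))) {
    edm_stop("`vp` must be finite.", "edm_validation_error")
  }
  params$alpha * exp(params$b * vp)
}

#' Predict the linear comparison model
#'
#' @param params A [linear_params()] object.
#' @param x Predictor (finite numeric, vectorized).
#' @return `intercept + slope * x`.
#' @export
predict_linear <- function(params, x) {
  stopifnot(inherits(params, "linear_params"))
  if (anyNA(x) || any(!is.finite(x))) {
    edm_stop("`x` must be finite.", "edm_validation_error")
  }
  params$intercept + params$slope * x
}

#' Predict log assimilation rate from leaf nitrogen
#'
#' Evaluates the saturating nitrogen-response law on the log scale,
#' ln P = ln_P_max * (R - R0) / (Kp + (R - R0)) + ln_P0. The prediction is
#' nondecreasing in R and approaches ln_P0 + ln_P_max as R grows; at
#' R = R0 + Kp it sits exactly halfway, ln_P0 + ln_P_max / 2.
#'
#' @param params A [resource_params()] object.
#' @param R Leaf nitrogen content (predictor units, vectorized); every value
#'   must satisfy `R >= R0`.
#' @return Predicted ln P value(s).
#' @examples
#' p <- resource_params(ln_P_max = 4.72, Kp = 29.19, R0 = 0, reduced = TRUE)
#' predict_resource_response(p, R = 29.19)  # half-saturation: 2.36
#' @export
predict_resource_response <- function(params, R) {
  stopifnot(inherits(params, "resource_params"))
  if (anyNA(R) || any(!is.finite(R))) {
    edm_stop("`R` must be finite.", "edm_validation_error")
  }
  if (any(R < params$R0)) {
    edm_stop(paste("`R` below `R0`: the effective resource R - R0 must be",
                   "nonnegative at every observation."),
             "edm_domain_error")
  }
  u <- R - params$R0
  params$ln_P_max * u / (params$Kp + u) + params$ln_P0
}

#' Half-saturation resource level
#'
#' The leaf nitrogen content at which ln P (above the storage baseline
#' ln_P0) reaches half its asymptote: R = R0 + Kp.
#'
#' @param params A [resource_params()] object.
#' @return The half-saturation resource level, predictor units.
#' @examples
#' half_saturation(resource_params(4.72, Kp = 29.19, R0 = 0, reduced = TRUE))
#' @export
half_saturation <- function(params) {
  stopifnot(inherits(params, "resource_params"))
  params$R0 + params$Kp
}

#' Photosynthetic nitrogen use efficiency
#'
#' PNUE is the CO2 assimilation rate per unit leaf nitrogen content, the
#' standard efficiency measure separating C4 from C3 leaves.
#'
#' @param P Assimilation rate (response units), nonnegative.
#' @param N Leaf nitrogen content, strictly positive.
#' @return `P / N`, vectorized.
#' @examples
#' pnue(P = 10, N = 2)
#' @export
pnue <- function(P, N) {
  if (anyNA(N) || any(!is.finite(N)) || any(N <= 0)) {
    edm_stop("`N` must be finite and strictly positive.",
             "edm_validation_error")
  }
  if (anyNA(P) || any(!is.finite(P)) || any(P < 0)) {
    edm_stop("`P` must be finite and nonnegative.", "edm_validation_error")
  }
  P / N
}

#' Implied maximum enzyme capacity ratio
#'
#' The two laws are linked through ln_P_max = b * V_max, so the ratio
#' ln_P_max / b has the units of an enzyme activity and can be read as an
#' implied maximum capacity V_max. Because b and ln_P_max are estimated from
#' different predictor axes (enzyme activity vs leaf nitrogen), the ratio is
#' exposed as a descriptive convenience only and is not asserted to equal any
#' published value.
#'
#' @param ln_P_max Positive log-scale asymptote from the nitrogen law.
#' @param b Activity coefficient from the enzyme law; must be nonzero.
#' @return `ln_P_max / b`.
#' @export
implied_vmax <- function(ln_P_max, b) {
  check_finite_scalar(ln_P_max, "ln_P_max")
  check_finite_scalar(b, "b")
  if (b == 0) {
    edm_stop("`b` must be nonzero to imply a V_max.", "edm_validation_error")
  }
  ln_P_max / b
}
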