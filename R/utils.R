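# Internal helpers shared across modules.

edm_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "edm_error")))
}

check_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    edm_stop(sprintf("`%s` must be a single finite number.", name),
             "edm_validation_error")
  }
  invisible(x)
}

# Deterministic multiplicative perturbation factors for multi-start fits.
# One row per restart; values in [0.7, 1.3] so starts stay in the basin of a
# sensible initial guess while still probing it.
restart_factors <- function(n_restarts, n_par, seed) {
  if (n_restarts < 1L) {
    return(matrix(numeric(0), nrow = 0L, ncol = n_par))
  }
  withr::with_seed(seed, {
    matrix(stats::runif(n_restarts * n_par, 0.7, 1.3),
           nrow = n_restarts, ncol = n_par)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
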