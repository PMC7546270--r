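# Independent oracles and shared fixtures, built in code.

# Fixed 5-point toy enzyme series (hand-picked, roughly exponential).
toy_exp_series <- function() {
  response_series(x = 0:4, y = c(2.0, 3.1, 5.4, 8.7, 15.1),
                  species = "toy", predictor_name = "toy enzyme",
                  series_id = "toy_exp")
}

# Brute-force 2-D grid oracle for the exponential law: exhaustive search over
# (alpha, b) with iterative grid shrinkage. Independent of the package's
# optimizer; returns the best RSS found.
grid_oracle_exponential <- function(x, y, n_grid = 41L, n_iter = 6L) {
  a_rng <- c(0.1 * min(y), 2 * max(y))
  b_rng <- c(-2, 2)
  best <- list(rss = Inf)
  for (it in seq_len(n_iter)) {
    a_grid <- seq(a_rng[1], a_rng[2], length.out = n_grid)
    b_grid <- seq(b_rng[1], b_rng[2], length.out = n_grid)
    for (a in a_grid) {
      for (b in b_grid) {
        rss <- sum((y - a * exp(b * x))^2)
        if (rss < best$rss) best <- list(alpha = a, b = b, rss = rss)
      }
    }
    a_step <- diff(a_rng) / (n_grid - 1)
    b_step <- diff(b_rng) / (n_grid - 1)
    a_rng <- c(best$alpha - 2 * a_step, best$alpha + 2 * a_step)
    b_rng <- c(best$b - 2 * b_step, best$b + 2 * b_step)
  }
  best
}

# Normal-equations OLS oracle (closed form, no lm()).
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  rss <- sum((y - intercept - slope * x)^2)
  list(intercept = intercept, slope = slope, rss = rss)
}

# Fixed 6-point toy nitrogen series on the ln scale.
toy_mm_series <- function() {
  x <- c(4, 10, 20, 40, 70, 110)
  lnp <- c(0.9, 1.7, 2.4, 3.1, 3.5, 3.7)
  response_series(x = x, y = exp(lnp), species = "toy",
                  predictor_kind = "leaf_N",
                  predictor_name = "leaf N per area", series_id = "toy_mm")
}

# Brute-force grid + shrinkage oracle for the (reduced or full)
# nitrogen-response law: coarse exhaustive grid over all curve parameters,
# then iterative refinement around the incumbent.
grid_oracle_resource <- function(x, z, reduced = TRUE, n_grid = 13L,
                                 n_iter = 7L) {
  rng <- diff(range(x))
  L_rng <- c(0.1, 4) * max(abs(z))
  K_rng <- c(0.02 * rng, 6 * rng)
  R0_rng <- c(min(x) - 2 * rng, min(x) - 1e-9 * rng)
  p0_rng <- if (reduced) c(0, 0) else range(z) + c(-2, 2)
  best <- list(rss = Inf)
  for (it in seq_len(n_iter)) {
    Ls <- seq(L_rng[1], L_rng[2], length.out = n_grid)
    Ks <- seq(K_rng[1], K_rng[2], length.out = n_grid)
    R0s <- seq(R0_rng[1], R0_rng[2], length.out = n_grid)
    p0s <- if (reduced) 0 else seq(p0_rng[1], p0_rng[2], length.out = n_grid)
    for (L in Ls) for (K in Ks) for (R0 in R0s) for (p0 in p0s) {
      if (L <= 0 || K <= 0) next
      u <- x - R0
      rss <- sum((z - (L * u / (K + u) + p0))^2)
      if (rss < best$rss) best <- list(L = L, K = K, R0 = R0, p0 = p0,
                                       rss = rss)
    }
    shrink <- function(rng, centre, n) {
      step <- diff(rng) / (n - 1)
      c(centre - 1.5 * step, centre + 1.5 * step)
    }
    L_rng <- pmax(shrink(L_rng, best$L, n_grid), 1e-8)
    K_rng <- pmax(shrink(K_rng, best$K, n_grid), 1e-8)
    R0_rng <- c(shrink(R0_rng, best$R0, n_grid)[1],
                min(shrink(R0_rng, best$R0, n_grid)[2],
                    min(x) - 1e-9 * rng))
    if (!reduced) p0_rng <- shrink(p0_rng, best$p0, n_grid)
  }
  best
}

# Identifiable reparameterization of the full nitrogen-response law: any two
# parameter sets predicting identically share these three combinations.
resource_identifiable <- function(ln_P_max, Kp, R0, ln_P0) {
  c(asymptote = ln_P_max + ln_P0, product = ln_P_max * Kp, shift = R0 - Kp)
}
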