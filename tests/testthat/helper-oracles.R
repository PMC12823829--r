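# Independent oracles and shared fixtures for the test suite.

# The four-municipality study cohort, constructed in code (same rows as the
# bundled CSV fixture).
study_cohort <- function() {
  municipality_cohort(
    name = c("Bergen", "Tokke", "Lurøy", "Sørfold"),
    category = c("big city", "mountain", "island", "rural"),
    response_min = c(10.2, 16.6, 32.8, 22.6)
  )
}

# Brute-force survival at integer minutes: multiply (1 - r) k times.
survival_by_loop <- function(s0, r, k) {
  s <- s0
  for (i in seq_len(k)) s <- s * (1 - r)
  s
}

# Sort-based percentile with linear interpolation between order statistics
# (independent re-derivation of the type-7 definition).
percentile_by_sort <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo + 1 >= n) return(x[n])
  x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
}

# Loop re-implementation of the Monte Carlo summary, consuming draws in the
# same per-grid-point order so a shared seed must reproduce simulate_curve().
mc_summary_by_loop <- function(params, t_grid, n_iter, sigma, seed,
                               interval = c(2.5, 97.5)) {
  set.seed(seed)
  det <- params$s0 * (1 - params$r)^(t_grid - params$t0)
  out <- matrix(NA_real_, nrow = length(t_grid), ncol = 3)
  for (j in seq_along(t_grid)) {
    draws <- det[j] + rnorm(n_iter, 0, sigma)
    draws <- pmin(pmax(draws, 0), 1)
    out[j, ] <- c(mean(draws),
                  percentile_by_sort(draws, interval[1] / 100),
                  percentile_by_sort(draws, interval[2] / 100))
  }
  out
}
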