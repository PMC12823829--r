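#' Monte Carlo configuration
#'
#' Settings for stochastic propagation of Gaussian noise through the
#' survival function. Noise has mean zero; its scale `noise_sigma` is a
#' modelling choice (the study design fixes only the mean), applied by
#' default on the probability scale. `noise_mode = "time"` instead perturbs
#' the delay `t` by the same sigma (in minutes), an alternative reading of
#' "noise around the deterministic curve".
#'
#' @param n_iter Number of Monte Carlo iterations; positive integer,
#'   default 10000.
#' @param noise_sigma Standard deviation of the additive noise; >= 0.
#'   Default 0.02 on the survival-probability scale.
#' @param noise_mode `"probability"` (default) adds noise to S(t);
#'   `"time"` adds noise to t before evaluating S.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param interval Lower/upper percentile pair of the simulation interval,
#'   default `c(2.5, 97.5)` (the central 95\% band).
#' @return A list of class `mc_config`.
#' @export
mc_config <- function(n_iter = 10000, noise_sigma = 0.02,
                      noise_mode = c("probability", "time"),
                      seed = NULL, interval = c(2.5, 97.5)) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(is.numeric(n_iter), length(n_iter) == 1L,
            is.numeric(noise_sigma), length(noise_sigma) == 1L,
            is.numeric(interval), length(interval) == 2L)
  n_iter <- as.integer(n_iter)
  if (is.na(n_iter) || n_iter < 1L) {
    stop("`n_iter` must be a positive integer", call. = FALSE)
  }
  if (is.na(noise_sigma) || noise_sigma < 0) {
    stop("`noise_sigma` must be non-negative", call. = FALSE)
  }
  if (anyNA(interval) || interval[1] < 0 || interval[2] > 100 ||
      interval[1] >= interval[2]) {
    stop("`interval` must satisfy 0 <= lower < upper <= 100", call. = FALSE)
  }
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    seed <- as.integer(seed)
  }
  structure(
    list(n_iter = n_iter, noise_sigma = noise_sigma, noise_mode = noise_mode,
         seed = seed, interval = interval),
    class = "mc_config"
  )
}

# Run `expr` under a temporary seed, restoring the caller's RNG state.
with_mc_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Monte Carlo survival curve with simulation intervals
#'
#' For each grid point, draws `n_iter` noisy survival values, clips each
#' draw to \[0, 1\], and reports the mean together with the configured
#' percentile interval (default 2.5th--97.5th, the 95\% simulation
#' interval). Grid points consume random draws in grid order, so a fixed
#' seed yields identical output for any grid prefix.
#'
#' Clipping to \[0, 1\] happens before summarizing; it biases the mean
#' toward the interior when the deterministic value is within about
#' 3 sigma of a boundary.
#'
#' Percentiles are computed by linear interpolation between order
#' statistics ([stats::quantile()] type 7), so results are reproducible
#' bit for bit given a seed.
#'
#' @param params A [decay_params()] object.
#' @param t_grid Strictly increasing, non-negative delays in minutes.
#' @param cfg An [mc_config()] object.
#' @return A tibble of class `mc_summary` with columns `t_min`, `mean`,
#'   `lower`, `upper`; the configuration is attached as attribute
#'   `config` and the generator name as `rng_kind`.
#' @examples
#' s <- simulate_curve(decay_params(), seq(0, 40, 5),
#'                     mc_config(n_iter = 1000, seed = 1))
#' @export
simulate_curve <- function(params, t_grid, cfg = mc_config()) {
  params <- as_decay_params(params)
  check_t_grid(t_grid)
  if (!inherits(cfg, "mc_config")) cfg <- do.call(mc_config, cfg)

  det <- survival_at(params, t_grid)
  n_t <- length(t_grid)
  probs <- cfg$interval / 100

  draw_summaries <- with_mc_seed(cfg$seed, {
    vapply(seq_len(n_t), function(j) {
      eps <- stats::rnorm(cfg$n_iter, mean = 0, sd = cfg$noise_sigma)
      draws <- if (cfg$noise_mode == "probability") {
        det[j] + eps
      } else {
        survival_at(params, pmax(t_grid[j] + eps, 0))
      }
      draws <- pmin(pmax(draws, 0), 1)
      c(mean(draws), stats::quantile(draws, probs, names = FALSE, type = 7))
    }, numeric(3))
  })

  out <- tibble::tibble(
    t_min = t_grid,
    mean = draw_summaries[1, ],
    lower = draw_summaries[2, ],
    upper = draw_summaries[3, ]
  )
  structure(out,
            config = cfg,
            params = params,
            rng_kind = RNGkind()[1],
            class = c("mc_summary", class(out)))
}

#' Monte Carlo summary of one earlier-call scenario
#'
#' Applies [simulate_curve()] at the single effective delay
#' `max(response_min - delta, 0)` of a municipality's scenario. With
#' noise, the mean converges to the deterministic [scenario_survival()]
#' value as `n_iter` grows (away from the clipping boundaries).
#'
#' @inheritParams scenario_survival
#' @param delta Call advance in minutes, scalar >= 0.
#' @param cfg An [mc_config()] object.
#' @return A one-row `mc_summary` tibble with additional columns
#'   `municipality` and `delta_min`.
#' @export
simulate_scenario <- function(muni, params, delta, cfg = mc_config()) {
  stopifnot(is.numeric(delta), length(delta) == 1L)
  det <- scenario_survival(muni, params, delta)
  eff <- det$effective_time_min
  sim <- simulate_curve(params, eff, cfg)
  out <- tibble::tibble(
    municipality = det$municipality,
    delta_min = delta,
    t_min = sim$t_min,
    mean = sim$mean,
    lower = sim$lower,
    upper = sim$upper
  )
  structure(out,
            config = attr(sim, "config"),
            params = attr(sim, "params"),
            rng_kind = attr(sim, "rng_kind"),
            class = c("mc_summary", class(out)))
}
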