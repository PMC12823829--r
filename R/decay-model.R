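#' Survival decay model parameters
#'
#' Constructs and validates the parameter set of the exponential survival
#' decay model \deqn{S(t) = S_0 (1 - r)^{t - t_0}}{S(t) = s0 * (1 - r)^(t - t0)}
#' where `r` is the fraction by which survival probability falls for each
#' additional minute of treatment delay.
#'
#' The default configuration (`s0 = 1`, `t0 = 0`) expresses survival as an
#' absolute probability of the full delay `t`: a municipality with mean
#' ambulance response time `T` minutes has baseline survival `(1 - r)^T`.
#' Users who prefer a relative parameterization -- survival expressed around
#' a municipality-specific reference time -- can set `t0` to that reference
#' and `s0` to the survival observed there; the two readings coincide when
#' `s0 = (1 - r)^t0`.
#'
#' @param s0 Baseline survival fraction at `t0`; must lie in (0, 1].
#' @param r Per-minute decline rate as a fraction; must lie in \[0, 1).
#'   Literature reports 5--12\% per minute for out-of-hospital cardiac
#'   arrest; the default 0.07 is the midpoint of that range.
#' @param t0 Reference time in minutes (>= 0) at which survival equals `s0`.
#'
#' @return An object of class `decay_params`: a named list with elements
#'   `s0`, `r`, `t0`.
#' @examples
#' p <- decay_params()          # s0 = 1, r = 0.07, t0 = 0
#' survival_at(p, 10.2)         # ~0.477: Bergen's baseline survival
#' @export
decay_params <- function(s0 = 1, r = 0.07, t0 = 0) {
  stopifnot(is.numeric(s0), length(s0) == 1L, is.finite(s0),
            is.numeric(r), length(r) == 1L, is.finite(r),
            is.numeric(t0), length(t0) == 1L, is.finite(t0))
  if (s0 <= 0 || s0 > 1) {
    stop("`s0` must lie in (0, 1], got ", s0, call. = FALSE)
  }
  if (r < 0 || r >= 1) {
    stop("`r` must lie in [0, 1), got ", r, call. = FALSE)
  }
  if (t0 < 0) {
    stop("`t0` must be non-negative, got ", t0, call. = FALSE)
  }
  structure(list(s0 = s0, r = r, t0 = t0), class = "decay_params")
}

#' @export
print.decay_params <- function(x, ...) {
  cat(sprintf("Survival decay parameters: s0 = %g, r = %g per minute, t0 = %g min\n",
              x$s0, x$r, x$t0))
  invisible(x)
}

as_decay_params <- function(params) {
  if (inherits(params, "decay_params")) return(params)
  do.call(decay_params, as.list(params))
}

#' Survival probability at a given treatment delay
#'
#' Evaluates `S(t) = s0 * (1 - r)^(t - t0)`, the exponential decay of
#' survival probability with delay to treatment.
#'
#' @param params A [decay_params()] object.
#' @param t Delay in minutes; numeric vector, all values >= 0.
#' @return Numeric vector of survival fractions, same length as `t`.
#' @examples
#' survival_at(decay_params(), c(10.2, 16.6, 22.6, 32.8))
#' @export
survival_at <- function(params, t) {
  params <- as_decay_params(params)
  stopifnot(is.numeric(t))
  if (length(t) == 0L) return(numeric(0))
  if (anyNA(t) || any(t < 0)) {
    stop("`t` must be non-negative and free of missing values", call. = FALSE)
  }
  params$s0 * (1 - params$r)^(t - params$t0)
}

#' Survival under an earlier-call scenario
#'
#' Computes survival for a municipality when the emergency call is placed
#' `delta` minutes earlier than observed, shifting the effective delay to
#' `max(response_min - delta, 0)`. A shift at least as large as the response
#' time pins the effective delay at zero (survival `s0`) and is flagged as
#' `capped`, since a call cannot precede the collapse.
#'
#' @param muni A single municipality: a one-row data frame with columns
#'   `name` and `response_min` (as returned by [municipality_cohort()] or
#'   [read_municipalities()]).
#' @param params A [decay_params()] object.
#' @param delta Call advance in minutes; numeric vector of shifts >= 0.
#' @return A tibble with one row per `delta` and columns `municipality`,
#'   `delta_min`, `effective_time_min`, `survival`, `gain_pp` (percentage
#'   points over the `delta = 0` baseline), and `capped`.
#' @examples
#' bergen <- municipality_cohort("Bergen", "big city", 10.2)
#' scenario_survival(bergen, decay_params(), c(0, 1, 5, 10))
#' @export
scenario_survival <- function(muni, params, delta) {
  params <- as_decay_params(params)
  muni <- validate_cohort(muni)
  if (nrow(muni) != 1L) {
    stop("`muni` must describe exactly one municipality; got ", nrow(muni),
         " rows", call. = FALSE)
  }
  stopifnot(is.numeric(delta), length(delta) >= 1L)
  if (anyNA(delta) || any(delta < 0)) {
    stop("`delta` must be non-negative and free of missing values",
         call. = FALSE)
  }
  t_resp <- muni$response_min
  eff <- pmax(t_resp - delta, 0)
  s <- survival_at(params, eff)
  s_base <- survival_at(params, t_resp)
  tibble::tibble(
    municipality = muni$name,
    delta_min = delta,
    effective_time_min = eff,
    survival = s,
    gain_pp = 100 * (s - s_base),
    capped = delta >= t_resp
  )
}

#' Deterministic survival curve over a time grid
#'
#' @param params A [decay_params()] object.
#' @param t_grid Strictly increasing, non-negative vector of delays (minutes).
#' @return A tibble with columns `t_min` and `survival`.
#' @examples
#' survival_curve(decay_params(), seq(0, 40, by = 1))
#' @export
survival_curve <- function(params, t_grid) {
  check_t_grid(t_grid)
  tibble::tibble(t_min = t_grid, survival = survival_at(params, t_grid))
}

check_t_grid <- function(t_grid) {
  stopifnot(is.numeric(t_grid))
  if (length(t_grid) == 0L) {
    stop("`t_grid` must be non-empty", call. = FALSE)
  }
  if (anyNA(t_grid) || any(t_grid < 0)) {
    stop("`t_grid` must be non-negative and free of missing values",
         call. = FALSE)
  }
  if (is.unsorted(t_grid, strictly = TRUE)) {
    stop("`t_grid` must be strictly increasing", call. = FALSE)
  }
  invisible(t_grid)
}

#' Round half away from zero
#'
#' Rounds with ties going away from zero (so 0.05 -> 0.1 at one decimal),
#' the convention used when rendering survival percentages. Base R's
#' [round()] rounds ties to even, which would disagree with printed tables
#' in boundary cases.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector of rounded values.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
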