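#' Scenario table of survival under earlier-call shifts
#'
#' Evaluates, for every municipality in a cohort, the baseline survival at
#' its mean response time and the survival when the emergency call is
#' placed each `delta` minutes earlier. With the defaults (s0 = 1, t0 = 0,
#' r = 0.07, deltas 1/5/10) this reproduces the published four-municipality
#' comparison table.
#'
#' @param cohort A municipality cohort (see [municipality_cohort()]). An
#'   empty cohort yields an empty table.
#' @param params A [decay_params()] object.
#' @param deltas Numeric vector of call advances in minutes, all >= 0.
#' @return A tibble of class `scenario_table`: columns `name`, `category`,
#'   `response_min`, `survival_0` (baseline) and one `survival_d<delta>`
#'   column per shift, all as fractions. The decay parameters and delta
#'   list are attached as attributes `params` and `deltas`.
#' @examples
#' build_scenario_table(example_municipalities())
#' @export
build_scenario_table <- function(cohort, params = decay_params(),
                                 deltas = c(1, 5, 10)) {
  params <- as_decay_params(params)
  cohort <- validate_cohort(cohort)
  stopifnot(is.numeric(deltas))
  if (anyNA(deltas) || any(deltas < 0)) {
    stop("`deltas` must be non-negative", call. = FALSE)
  }
  tab <- cohort
  tab$survival_0 <- if (nrow(cohort)) {
    survival_at(params, cohort$response_min)
  } else {
    numeric(0)
  }
  for (d in deltas) {
    tab[[delta_col(d)]] <- if (nrow(cohort)) {
      survival_at(params, pmax(cohort$response_min - d, 0))
    } else {
      numeric(0)
    }
  }
  structure(tab, params = params, deltas = deltas,
            class = c("scenario_table", class(tab)))
}

delta_col <- function(d) paste0("survival_d", format(d, trim = TRUE))

#' Percentage-point and relative gains from a scenario table
#'
#' @param table A `scenario_table` from [build_scenario_table()].
#' @return A long tibble with one row per (municipality, delta):
#'   `name`, `delta_min`, `survival`, `gain_pp` (absolute gain over the
#'   baseline in percentage points) and `gain_rel_pct` (relative gain in
#'   percent of the baseline).
#' @examples
#' compute_gains(build_scenario_table(example_municipalities()))
#' @export
compute_gains <- function(table) {
  if (!inherits(table, "scenario_table")) {
    stop("`table` must be a scenario_table from build_scenario_table()",
         call. = FALSE)
  }
  deltas <- attr(table, "deltas")
  if (!"survival_0" %in% names(table)) {
    stop("scenario table has no baseline column", call. = FALSE)
  }
  rows <- lapply(deltas, function(d) {
    s <- table[[delta_col(d)]]
    tibble::tibble(
      name = table$name,
      delta_min = rep_len(d, nrow(table)),
      survival = s,
      gain_pp = 100 * (s - table$survival_0),
      gain_rel_pct = 100 * (s - table$survival_0) / table$survival_0
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$name, out$delta_min), ]
}

#' Sensitivity of scenario survival to the decline rate
#'
#' Re-evaluates baseline and scenario survival over a grid of per-minute
#' decline rates (default 5\%--12\%, the range reported in the
#' resuscitation literature). The slice at any single `r` equals the
#' corresponding [build_scenario_table()] output cell for cell.
#'
#' @param cohort A municipality cohort.
#' @param r_grid Numeric vector of decline rates, each in \[0, 1).
#' @param deltas Numeric vector of call advances in minutes.
#' @param s0,t0 Baseline survival and reference time passed to
#'   [decay_params()].
#' @return A long tibble of class `sensitivity_grid` with columns `name`,
#'   `response_min`, `r`, `delta_min` (0 = baseline) and `survival`.
#' @examples
#' sensitivity_over_r(example_municipalities(), r_grid = c(0.05, 0.07, 0.12))
#' @export
sensitivity_over_r <- function(cohort, r_grid = seq(0.05, 0.12, by = 0.01),
                               deltas = c(1, 5, 10), s0 = 1, t0 = 0) {
  cohort <- validate_cohort(cohort)
  stopifnot(is.numeric(r_grid), length(r_grid) >= 1L)
  if (anyNA(r_grid) || any(r_grid < 0 | r_grid >= 1)) {
    stop("all `r_grid` values must lie in [0, 1)", call. = FALSE)
  }
  all_deltas <- c(0, deltas)
  grid <- expand.grid(i = seq_len(nrow(cohort)), r = r_grid,
                      delta_min = all_deltas, KEEP.OUT.ATTRS = FALSE)
  out <- tibble::tibble(
    name = cohort$name[grid$i],
    response_min = cohort$response_min[grid$i],
    r = grid$r,
    delta_min = grid$delta_min
  )
  out$survival <- vapply(seq_len(nrow(out)), function(k) {
    p <- decay_params(s0 = s0, r = out$r[k], t0 = t0)
    survival_at(p, max(out$response_min[k] - out$delta_min[k], 0))
  }, numeric(1))
  structure(out, class = c("sensitivity_grid", class(out)))
}

#' Render a scenario table with percentages at one decimal
#'
#' Human-readable twin of [build_scenario_table()]'s fractional output:
#' survival columns become percent strings rounded half away from zero to
#' one decimal (e.g. `"47.7%"`), matching the convention of published
#' response-time tables.
#'
#' @param table A `scenario_table`.
#' @return A tibble with the same layout, survival columns as character.
#' @export
format_scenario_table <- function(table) {
  if (!inherits(table, "scenario_table")) {
    stop("`table` must be a scenario_table from build_scenario_table()",
         call. = FALSE)
  }
  out <- tibble::as_tibble(table)
  surv_cols <- c("survival_0", vapply(attr(table, "deltas"), delta_col, ""))
  for (col in surv_cols) {
    out[[col]] <- sprintf("%.1f%%", round_half_up(100 * out[[col]], 1))
  }
  out
}
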