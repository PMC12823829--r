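#' Build a municipality cohort
#'
#' A cohort is a tibble with one row per geographic unit: a unique `name`,
#' a free-text `category` (e.g. "big city", "mountain", "island", "rural"),
#' and the mean ambulance response time in minutes.
#'
#' @param name Character vector of municipality names; non-empty, unique.
#' @param category Character vector of geography labels (recycled if scalar).
#' @param response_min Numeric vector of mean response times, minutes > 0.
#' @return A tibble with columns `name`, `category`, `response_min`.
#' @examples
#' municipality_cohort(
#'   name = c("Bergen", "Tokke", "Lurøy", "Sørfold"),
#'   category = c("big city", "mountain", "island", "rural"),
#'   response_min = c(10.2, 16.6, 32.8, 22.6)
#' )
#' @export
municipality_cohort <- function(name, category = "unspecified", response_min) {
  stopifnot(is.character(name), is.character(category), is.numeric(response_min))
  cohort <- tibble::tibble(
    name = name,
    category = rep_len(category, length(name)),
    response_min = response_min
  )
  validate_cohort(cohort)
}

validate_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  required <- c("name", "response_min")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"category" %in% names(cohort)) cohort$category <- "unspecified"
  if (nrow(cohort) == 0L) return(cohort[, c("name", "category", "response_min")])
  if (anyNA(cohort$name) || any(!nzchar(cohort$name))) {
    stop("municipality names must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(cohort$name)) {
    dup <- unique(cohort$name[duplicated(cohort$name)])
    stop("duplicate municipality name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(cohort$response_min) || any(cohort$response_min <= 0)) {
    stop("`response_min` must be positive for every municipality",
         call. = FALSE)
  }
  cohort[, c("name", "category", "response_min")]
}

#' The four-municipality example cohort
#'
#' Reads the bundled response-time table for Bergen (big city, 10.2 min),
#' Tokke (mountain, 16.6 min), Lurøy (island, 32.8 min) and Sørfold
#' (rural, 22.6 min) -- official municipality-level mean ambulance response
#' times from the Norwegian emergency medical communication centers (AMK).
#'
#' @return A four-row municipality cohort tibble.
#' @examples
#' example_municipalities()
#' @export
example_municipalities <- function() {
  path <- system.file("extdata", "municipalities.csv", package = "ohcasim",
                      mustWork = TRUE)
  read_municipalities(path)
}
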