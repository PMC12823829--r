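#' Read a municipality response-time table
#'
#' Parses a delimited text file with columns `name`, `type` (or
#' `category`) and `response_min` (aliases `response_time`, `response`
#' accepted). The delimiter is auto-detected among comma, semicolon and
#' tab unless given explicitly, and decimal commas are accepted ("10,2"
#' parses as 10.2 -- Norwegian tables print decimal commas), so both CSV
#' dialects work unchanged.
#'
#' @param path Path to the file.
#' @param delim Field delimiter; `NULL` (default) auto-detects from the
#'   header line.
#' @return A validated municipality cohort tibble.
#' @examples
#' read_municipalities(system.file("extdata", "municipalities.csv",
#'                                 package = "ohcasim"))
#' @export
read_municipalities <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    stop("municipality file not found: ", path, call. = FALSE)
  }
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  if (is.null(delim)) {
    delim <- if (grepl(";", header)) {
      ";"
    } else if (grepl("\t", header)) {
      "\t"
    } else {
      ","
    }
  }
  raw <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8",
                           check.names = FALSE)
  names(raw) <- tolower(trimws(names(raw)))

  pick <- function(aliases, required_name) {
    hit <- intersect(aliases, names(raw))
    if (length(hit) == 0L) {
      stop("municipality file is missing column `", required_name, "` (",
           path, ")", call. = FALSE)
    }
    trimws(raw[[hit[1]]])
  }
  name <- pick(c("name", "municipality"), "name")
  category <- if (any(c("type", "category") %in% names(raw))) {
    pick(c("type", "category"), "type")
  } else {
    rep("unspecified", nrow(raw))
  }
  resp_chr <- pick(c("response_min", "response_time", "response"),
                   "response_min")

  resp <- suppressWarnings(as.numeric(gsub(",", ".", resp_chr, fixed = TRUE)))
  bad <- which(is.na(resp))
  if (length(bad) > 0L) {
    stop("unparseable response time in row ", bad[1], ": \"",
         resp_chr[bad[1]], "\"", call. = FALSE)
  }
  municipality_cohort(name = name, category = category, response_min = resp)
}

#' Write scenario and simulation outputs to a directory
#'
#' Emits the standard result set of a run: `scenario_table.csv` (percent
#' strings at one decimal), `scenario_table.json` (unrounded fractions),
#' one `curve_<name>.csv` per Monte Carlo summary (columns `t_min`,
#' `mean`, `lower`, `upper`), and `run_metadata.json` recording every
#' setting needed to reproduce the run (decay parameters, deltas, MC
#' configuration incl. seed and RNG kind, cohort, package version). With
#' `plots = TRUE` (and ggplot2 installed) a PDF of each simulated curve is
#' added.
#'
#' @param table A `scenario_table` from [build_scenario_table()].
#' @param summaries Named list of `mc_summary` objects (names become file
#'   names); may be empty.
#' @param dir Output directory; created if needed.
#' @param plots Write curve plots as PDFs? Default `FALSE` so the core
#'   pipeline has no graphics dependency.
#' @return Character vector manifest of every file written (invisibly).
#' @export
write_outputs <- function(table, summaries = list(), dir, plots = FALSE) {
  if (!inherits(table, "scenario_table")) {
    stop("`table` must be a scenario_table", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir,
                             call. = FALSE)
  manifest <- character(0)

  tab_csv <- file.path(dir, "scenario_table.csv")
  utils::write.csv(format_scenario_table(table), tab_csv, row.names = FALSE,
                   fileEncoding = "UTF-8")
  manifest <- c(manifest, tab_csv)

  tab_json <- file.path(dir, "scenario_table.json")
  jsonlite::write_json(tibble::as_tibble(table), tab_json, digits = NA,
                       pretty = TRUE)
  manifest <- c(manifest, tab_json)

  for (nm in names(summaries)) {
    s <- summaries[[nm]]
    curve_csv <- file.path(dir, paste0("curve_", sanitize_name(nm), ".csv"))
    utils::write.csv(tibble::as_tibble(s)[, c("t_min", "mean", "lower", "upper")],
                     curve_csv, row.names = FALSE, fileEncoding = "UTF-8")
    manifest <- c(manifest, curve_csv)
    if (isTRUE(plots)) {
      plot_file <- file.path(dir, paste0("curve_", sanitize_name(nm), ".pdf"))
      p <- plot_mc_curve(s, title = nm)
      ggplot2::ggsave(plot_file, p, width = 6, height = 4)
      manifest <- c(manifest, plot_file)
    }
  }

  params <- attr(table, "params")
  cfg <- if (length(summaries)) attr(summaries[[1]], "config") else NULL
  meta <- list(
    package = "ohcasim",
    version = as.character(utils::packageVersion("ohcasim")),
    params = list(s0 = params$s0, r = params$r, t0 = params$t0),
    deltas = attr(table, "deltas"),
    mc = if (!is.null(cfg)) {
      list(n_iter = cfg$n_iter, sigma = cfg$noise_sigma,
           mode = cfg$noise_mode, seed = cfg$seed,
           interval = cfg$interval,
           rng_kind = attr(summaries[[1]], "rng_kind"))
    },
    t_grid = if (length(summaries)) summaries[[1]]$t_min,
    cohort = tibble::as_tibble(table)[, c("name", "category", "response_min")]
  )
  meta_json <- file.path(dir, "run_metadata.json")
  jsonlite::write_json(meta, meta_json, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  manifest <- c(manifest, meta_json)
  invisible(manifest)
}

sanitize_name <- function(x) gsub("[^[:alnum:]._-]+", "_", x)

#' Re-run an analysis from its emitted metadata
#'
#' Reads a `run_metadata.json` written by [write_outputs()] and repeats
#' the run: same cohort, decay parameters, deltas, and (if the original
#' run simulated) the same Monte Carlo configuration and seed, giving an
#' identical scenario table and identical simulation summaries.
#'
#' @param metadata_path Path to `run_metadata.json`.
#' @return A list with elements `table` (scenario_table) and `summaries`
#'   (named list of `mc_summary`, empty if the original run had none).
#' @export
replay_run <- function(metadata_path) {
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  cohort <- municipality_cohort(
    name = meta$cohort$name,
    category = meta$cohort$category,
    response_min = meta$cohort$response_min
  )
  params <- decay_params(s0 = meta$params$s0, r = meta$params$r,
                         t0 = meta$params$t0)
  if (is.null(meta$mc)) {
    return(run_analysis(cohort, params, meta$deltas))
  }
  cfg <- mc_config(
    n_iter = meta$mc$n_iter, noise_sigma = meta$mc$sigma,
    noise_mode = meta$mc$mode, seed = meta$mc$seed,
    interval = meta$mc$interval
  )
  run_analysis(cohort, params, meta$deltas, t_grid = meta$t_grid,
               mc_cfg = cfg)
}
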