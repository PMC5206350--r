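obs_required_cols <- c("treatment", "chamber", "tiller_id", "day", "rank", "distance")
dis_required_cols <- c("treatment", "chamber", "tiller_id", "rank",
                       "blade", "sheath", "internode", "phytomer_length", "maturity")

validate_table <- function(df, required, optional, what,
                           resolution = NULL, length_cols = character()) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, ": missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(df), c(required, optional))
  if (length(unknown)) {
    warning(what, ": ignoring unknown column(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  for (cl in intersect(length_cols, names(df))) {
    if (!is.numeric(df[[cl]]) || nrow(df) == 0L) next
    bad <- which(!is.na(df[[cl]]) & df[[cl]] < 0)
    if (length(bad)) {
      stop(what, ": negative ", cl, " at row(s) ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    }
    if (!is.null(resolution) && resolution > 0) {
      off <- which(!is.na(df[[cl]]) &
                     abs(df[[cl]] / resolution - round(df[[cl]] / resolution)) > 1e-6)
      if (length(off)) {
        warning(what, ": ", length(off), " ", cl,
                " value(s) off the ", resolution, " mm grid (first at row ",
                off[1], ")", call. = FALSE)
      }
    }
  }
  invisible(df)
}

#' Read and write the pipeline tables
#'
#' Plain comma-separated text with a header row. Reading validates the
#' schema: missing required columns are an error, unknown columns a warning,
#' negative lengths an error, and distances off the measurement grid a
#' warning. A write followed by a read round-trips losslessly.
#'
#' @param path File path.
#' @param resolution Expected measurement grid in mm for validation
#'   (default 0.5; use 0 to skip the grid check).
#' @return A validated tibble.
#' @export
read_observations <- function(path, resolution = 0.5) {
  if (!file.exists(path)) stop("observation file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_table(df, obs_required_cols,
                 c("reference_rank", "ligule_visible", "n_tillers"),
                 "observations", resolution = resolution, length_cols = "distance")
}

#' @rdname read_observations
#' @export
read_dissection <- function(path, resolution = 0.5) {
  if (!file.exists(path)) stop("dissection file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_table(df, dis_required_cols, character(),
                 "dissection", resolution = resolution,
                 length_cols = c("blade", "sheath", "internode", "phytomer_length"))
}

#' @rdname read_observations
#' @param df Table to write.
#' @export
write_table_csv <- function(df, path) {
  readr::write_csv(df, path)
  invisible(path)
}

#' Serialize a generator configuration to JSON (and back)
#'
#' The config echo written next to every simulated data set; a run is fully
#' reproducible from this file alone.
#'
#' @param config A [generator_config()].
#' @param path File path.
#' @return `path` invisibly / the restored `generator_config`.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  out <- unclass(config)
  out$thresholds <- unclass(out$thresholds)
  if (!is.null(out$treatments)) out$treatments <- as.data.frame(out$treatments)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$thresholds <- do.call(partition_thresholds, raw$thresholds)
  if (!is.null(raw$treatments)) raw$treatments <- tibble::as_tibble(raw$treatments)
  do.call(generator_config, raw)
}

#' Simulate an experiment and write its tables
#'
#' Runs [generate_experiment()] and writes `observations.csv`,
#' `dissection.csv`, `truth.csv` and `config.json` into `out_dir`.
#'
#' @param config A [generator_config()] (or path to a config JSON).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress the log line.
#' @return The `phyto_experiment`, invisibly.
#' @export
run_simulation <- function(config = generator_config(), out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_generator_config(config)
  stopifnot(inherits(config, "generator_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  exp <- generate_experiment(config)
  write_table_csv(exp$observations, file.path(out_dir, "observations.csv"))
  write_table_csv(exp$dissection, file.path(out_dir, "dissection.csv"))
  write_table_csv(exp$truth, file.path(out_dir, "truth.csv"))
  write_generator_config(config, file.path(out_dir, "config.json"))
  if (!quiet) {
    message(sprintf("simulated %d tillers (seed %d): %d observation rows, %d dissected phytomers",
                    dplyr::n_distinct(exp$truth$tiller_id), config$seed,
                    nrow(exp$observations), nrow(exp$dissection)))
  }
  invisible(exp)
}

#' Analyze an experiment directory
#'
#' Reads the observation and dissection tables, runs
#' [reconstruct_experiment()], fits the complete time course and the
#' coordination curves, summarizes tillers and treatments, and writes
#' `timecourse.csv`, `coordination_within.csv`, `coordination_between.csv`,
#' `tiller_summaries.csv`, `treatment_means.csv` and `fit_report.json` to
#' `out_dir`.
#'
#' @param in_dir Directory holding `observations.csv` and `dissection.csv`
#'   (as written by [run_simulation()]).
#' @param out_dir Output directory (default `in_dir`).
#' @param ... Passed to [reconstruct_experiment()].
#' @param quiet Suppress log lines.
#' @return A list with the reconstruction, fits, summaries and treatment
#'   table, invisibly.
#' @export
run_analysis <- function(in_dir, out_dir = in_dir, ..., quiet = FALSE) {
  obs <- read_observations(file.path(in_dir, "observations.csv"))
  dis <- read_dissection(file.path(in_dir, "dissection.csv"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  recon <- reconstruct_experiment(obs, dis, ...)

  fits <- list(timecourse = fit_sigmoid2(recon$timecourse, x = age, y = f_L))
  coord <- recon$coordination_within
  fits$blade <- tryCatch(fit_sigmoid3(coord, x = f_L, y = blade_f),
                         error = function(e) NULL)
  fits$sheath <- tryCatch(fit_sigmoid3(coord, x = f_L, y = sheath_f),
                          error = function(e) NULL)
  fits$internode <- tryCatch(fit_linear(coord, x = f_L, y = internode_f),
                             error = function(e) NULL)
  if (nrow(recon$coordination_between)) {
    fits$between <- tryCatch(fit_sigmoid3(recon$coordination_between,
                                          x = f_older, y = f_younger),
                             error = function(e) NULL)
  }
  fits <- Filter(Negate(is.null), fits)

  summaries <- summarize_tillers(recon, obs)
  tmeans <- treatment_means(summaries)

  write_table_csv(recon$timecourse, file.path(out_dir, "timecourse.csv"))
  write_table_csv(recon$coordination_within, file.path(out_dir, "coordination_within.csv"))
  write_table_csv(recon$coordination_between, file.path(out_dir, "coordination_between.csv"))
  write_table_csv(summaries, file.path(out_dir, "tiller_summaries.csv"))
  write_table_csv(tmeans, file.path(out_dir, "treatment_means.csv"))
  write_fit_report(fits, file.path(out_dir, "fit_report.json"))
  if (!quiet) {
    tc <- fits$timecourse
    message(sprintf("complete time course: x0 = %.2f d, b = %.2f d (R^2 = %.3f, n = %d)",
                    tc$curve$x0, tc$curve$b, tc$r_squared, tc$n_points))
  }
  invisible(list(reconstruction = recon, fits = fits,
                 summaries = summaries, treatment_means = tmeans))
}
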