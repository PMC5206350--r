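#' Round half-up
#'
#' Rounds halves away from zero (12.5 -> 13, -12.5 -> -13), the convention
#' used for reported percents and table values, unlike base [round()] which
#' rounds halves to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Per-tiller growth and developmental parameters
#'
#' Collapses the reconstruction outputs to one row per tiller: phyllochron,
#' visible growth duration (tip emergence to cessation, averaged over the
#' monitored ranks), the mean number of visibly growing phytomers and the
#' mean number of (emerged) phytomers over the observation window, the
#' recorded tiller count, and the mean final length of mature phytomers.
#'
#' @param recon A `phyto_reconstruction` from [reconstruct_experiment()].
#' @param observations The observation table the reconstruction was run on.
#' @param duration_ranks Ranks entering the visible-growth-duration mean
#'   (default: the reconstruction's monitored ranks).
#' @return A tibble with one row per tiller.
#' @export
summarize_tillers <- function(recon, observations, duration_ranks = NULL) {
  stopifnot(inherits(recon, "phyto_reconstruction"))
  ids <- id_cols_of(observations)
  duration_ranks <- duration_ranks %||% recon$monitored_ranks

  durations <- recon$events |>
    dplyr::filter(.data$reliable, .data$rank %in% duration_ranks) |>
    dplyr::inner_join(recon$cessation |> dplyr::filter(.data$mature) |>
                        dplyr::select(dplyr::all_of(c("tiller_id", "rank", "cessation_day"))),
                      by = c("tiller_id", "rank")) |>
    dplyr::group_by(.data$tiller_id) |>
    dplyr::summarise(visible_growth_duration =
                       mean(.data$cessation_day - .data$emergence_day),
                     .groups = "drop")

  ## daily counts: phytomers listed that day (= emerged), of which "growing"
  ## are those whose detected cessation lies in the future (or not yet seen)
  counts <- observations |>
    dplyr::left_join(recon$cessation |>
                       dplyr::select(dplyr::all_of(c("tiller_id", "rank", "cessation_day"))),
                     by = c("tiller_id", "rank")) |>
    dplyr::group_by(.data$tiller_id, .data$day) |>
    dplyr::summarise(n_emerged = dplyr::n_distinct(.data$rank),
                     n_growing = sum(is.na(.data$cessation_day) |
                                       .data$cessation_day > .data$day),
                     .groups = "drop") |>
    dplyr::group_by(.data$tiller_id) |>
    dplyr::summarise(n_phytomers = mean(.data$n_emerged),
                     n_visibly_growing = mean(.data$n_growing),
                     .groups = "drop")

  lengths <- recon$dissection |>
    dplyr::filter(.data$maturity == "mature") |>
    dplyr::group_by(.data$tiller_id) |>
    dplyr::summarise(mean_final_phytomer_length = mean(.data$phytomer_length),
                     .groups = "drop")

  base <- observations |>
    dplyr::distinct(dplyr::across(dplyr::all_of(ids)),
                    n_tillers = if ("n_tillers" %in% names(observations))
                      .data$n_tillers else NA_real_)

  base |>
    dplyr::left_join(recon$phyllochron |>
                       dplyr::select(dplyr::all_of(c("tiller_id", "phyllochron"))),
                     by = "tiller_id") |>
    dplyr::left_join(durations, by = "tiller_id") |>
    dplyr::left_join(counts, by = "tiller_id") |>
    dplyr::left_join(lengths, by = "tiller_id")
}

#' Treatment means and standard errors
#'
#' Mean and standard error (sd/sqrt(n)) of each per-tiller parameter in each
#' treatment cell, in long format, plus the grand mean computed as the
#' unweighted average of the cell means.
#'
#' @param summaries Per-tiller summaries from [summarize_tillers()], with a
#'   `treatment` column (and optionally `nitrogen`, `vpd` factor columns —
#'   reconstructed from the treatment label `N?V?` when absent).
#' @param parameters Character vector of summary columns to tabulate
#'   (default: all numeric parameters present).
#' @return A tibble of class `treatment_table`: `parameter`, `treatment`,
#'   `nitrogen`, `vpd`, `mean`, `se`, `n`, with attribute `grand_means`.
#' @export
treatment_means <- function(summaries, parameters = NULL) {
  stopifnot("treatment" %in% names(summaries))
  default_pars <- c("phyllochron", "visible_growth_duration", "n_phytomers",
                    "n_visibly_growing", "n_tillers", "mean_final_phytomer_length")
  parameters <- parameters %||% intersect(default_pars, names(summaries))
  if (!length(parameters)) stop("no summary parameters found", call. = FALSE)
  has_cell <- summaries |>
    dplyr::count(.data$treatment)
  if (any(has_cell$n < 2)) stop("each treatment cell needs >= 2 tillers", call. = FALSE)
  if (!"nitrogen" %in% names(summaries)) {
    summaries$nitrogen <- sub("^(N[0-9]+).*$", "\\1", summaries$treatment)
  }
  if (!"vpd" %in% names(summaries)) {
    summaries$vpd <- sub("^.*?(V[0-9]+)$", "\\1", summaries$treatment)
  }
  long <- summaries |>
    tidyr::pivot_longer(dplyr::all_of(parameters),
                        names_to = "parameter", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$parameter, .data$treatment, .data$nitrogen, .data$vpd) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = stats::sd(.data$value) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  grand <- long |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(grand_mean = mean(.data$mean), .groups = "drop")
  structure(long, grand_means = grand, class = c("treatment_table", class(long)))
}

#' Grand means of a treatment table
#'
#' @param table A `treatment_table`.
#' @return Tibble of `parameter`, `grand_mean` (unweighted over the cells).
#' @export
grand_means <- function(table) {
  gm <- attr(table, "grand_means")
  gm %||% (table |>
             dplyr::group_by(.data$parameter) |>
             dplyr::summarise(grand_mean = mean(.data$mean), .groups = "drop"))
}

#' Percent effect of a treatment factor
#'
#' 100 x (mean at the high level - mean at the low level) / mean at the low
#' level, where each level's mean averages the cell means over the other
#' factor, or is taken within a stated conditioning level of the other
#' factor. Returned unrounded; reported values use half-up integer rounding
#' (see [round_half_up()]).
#'
#' @param table A `treatment_table` (from [treatment_means()] or built from
#'   published cell means).
#' @param parameter Parameter name.
#' @param factor `"nitrogen"` or `"vpd"`.
#' @param conditioning Optional named value of the other factor, e.g.
#'   `c(vpd = "V1")`.
#' @param from,to The low and high factor levels (default: sorted levels).
#' @return Percent change (scalar).
#' @export
percent_effect <- function(table, parameter, factor = c("nitrogen", "vpd"),
                           conditioning = NULL, from = NULL, to = NULL) {
  factor <- match.arg(factor)
  d <- dplyr::filter(table, .data$parameter == !!parameter)
  if (nrow(d) == 0L) stop("parameter not found: ", parameter, call. = FALSE)
  if (!is.null(conditioning)) {
    other <- names(conditioning)[1]
    d <- dplyr::filter(d, .data[[other]] == conditioning[[1]])
  }
  lv <- sort(unique(d[[factor]]))
  from <- from %||% lv[1]
  to <- to %||% lv[length(lv)]
  m_low <- mean(d$mean[d[[factor]] == from])
  m_high <- mean(d$mean[d[[factor]] == to])
  if (!is.finite(m_low) || m_low == 0) stop("low-level mean is zero or missing", call. = FALSE)
  100 * (m_high - m_low) / m_low
}

#' Published treatment-level reference means
#'
#' Loads the packaged table of treatment-cell means and standard errors of
#' the growth and developmental parameters of the growth-chamber study this
#' package models (phyllochron, visible growth duration, numbers of
#' phytomers, visibly growing phytomers and tillers), as a
#' `treatment_table` usable with [grand_means()] and [percent_effect()].
#'
#' @return A `treatment_table` tibble.
#' @export
reference_treatment_means <- function() {
  path <- system.file("extdata", "reference_treatment_means.csv",
                      package = "phytodev", mustWork = TRUE)
  d <- readr::read_csv(path, show_col_types = FALSE)
  d$nitrogen <- sub("^(N[0-9]+).*$", "\\1", d$treatment)
  d$vpd <- sub("^.*?(V[0-9]+)$", "\\1", d$treatment)
  grand <- d |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(grand_mean = mean(.data$mean), .groups = "drop")
  structure(d, grand_means = grand, class = c("treatment_table", class(d)))
}
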