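## Identity columns carried through every reconstruction table when present.
id_cols_of <- function(df) intersect(c("treatment", "chamber", "tiller_id"), names(df))

#' Estimate tip-emergence times from daily observations
#'
#' A phytomer tip may emerge between two daily visits, so its first recorded
#' distance overestimates zero. The time lag between true emergence and the
#' first observation is estimated as first distance divided by the elongation
#' rate just following emergence (the first one-day increment, or the mean of
#' the first two when `rate_increments = 2`), and subtracted from the first
#' observation day.
#'
#' Events are flagged unreliable when the rate is non-positive or when the
#' implied lag exceeds `max_lag` (phytomers that emerged long before
#' observation started extrapolate poorly); unreliable events are excluded
#' downstream with a warning.
#'
#' @param observations Observation table with columns `tiller_id`, `rank`,
#'   `day`, `distance` (and optionally `treatment`, `chamber`).
#' @param max_lag Maximum credible lag in days (default 1.5).
#' @param rate_increments Number of initial one-day increments averaged for
#'   the post-emergence rate (default 1).
#' @return A tibble with one row per (tiller, rank): first observation day
#'   and distance, `rate` (mm/day), `lag` (days), `emergence_day`, and a
#'   `reliable` flag.
#' @export
estimate_emergence <- function(observations, max_lag = 1.5, rate_increments = 1) {
  stopifnot(all(c("tiller_id", "rank", "day", "distance") %in% names(observations)))
  ids <- id_cols_of(observations)
  observations |>
    dplyr::arrange(.data$tiller_id, .data$rank, .data$day) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(ids, "rank")))) |>
    dplyr::summarise(
      first_observation_day = .data$day[1],
      first_distance = .data$distance[1],
      n_obs = dplyr::n(),
      rate = {
        k <- min(rate_increments, dplyr::n() - 1L)
        if (k < 1L) NA_real_
        else mean((.data$distance[2:(k + 1L)] - .data$distance[1:k]) /
                    (.data$day[2:(k + 1L)] - .data$day[1:k]))
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      lag = dplyr::case_when(
        .data$first_distance == 0 ~ 0,
        is.na(.data$rate) | .data$rate <= 0 ~ NA_real_,
        TRUE ~ .data$first_distance / .data$rate
      ),
      emergence_day = .data$first_observation_day - .data$lag,
      reliable = !is.na(.data$lag) & .data$lag <= max_lag
    )
}

#' Per-tiller phyllochron
#'
#' Mean interval between the estimated tip emergences of successive
#' phytomers, computed from reliable emergence events within a rank window.
#' Differences across missing ranks are normalized by the rank gap.
#'
#' @param events Output of [estimate_emergence()].
#' @param rank_window Ranks entering the phyllochron estimate
#'   (default `c(7, 16)`).
#' @return A tibble with one row per tiller: `phyllochron` (days) and
#'   `n_events`. Tillers with fewer than two usable events get `NA` with a
#'   warning.
#' @export
compute_phyllochron <- function(events, rank_window = c(7, 16)) {
  stopifnot(all(c("tiller_id", "rank", "emergence_day") %in% names(events)))
  ids <- id_cols_of(events)
  use <- events |>
    dplyr::filter(.data$reliable,
                  .data$rank >= rank_window[1], .data$rank <= rank_window[2])
  if (nrow(use) == 0L) stop("no reliable emergence events in the rank window", call. = FALSE)
  out <- use |>
    dplyr::arrange(.data$tiller_id, .data$rank) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(ids))) |>
    dplyr::summarise(
      n_events = dplyr::n(),
      phyllochron = if (dplyr::n() < 2L) NA_real_ else {
        mean(diff(.data$emergence_day) / diff(.data$rank))
      },
      .groups = "drop"
    )
  if (anyNA(out$phyllochron)) {
    warning(sum(is.na(out$phyllochron)),
            " tiller(s) with < 2 reliable emergence events; phyllochron set to NA",
            call. = FALSE)
  }
  out
}

#' Detect cessation of elongation
#'
#' A phytomer is flagged fully expanded on the first day after which its
#' tip-to-ligule distance stays strictly below one resolution step of change
#' per day (i.e. a recorded change of zero on a 0.5 mm ruler) for `k`
#' consecutive daily intervals. Series still changing when observation ends
#' are flagged immature.
#'
#' @param observations Observation table.
#' @param k Consecutive stable intervals required (default 2).
#' @param stability_threshold Change threshold in mm/day (default 0.5, one
#'   ruler step).
#' @return One row per (tiller, rank): `cessation_day` (NA while immature)
#'   and `mature` flag.
#' @export
detect_full_expansion <- function(observations, k = 2, stability_threshold = 0.5) {
  stopifnot(all(c("tiller_id", "rank", "day", "distance") %in% names(observations)))
  if (stability_threshold <= 0) stability_threshold <- 0.5
  ids <- id_cols_of(observations)
  observations |>
    dplyr::arrange(.data$tiller_id, .data$rank, .data$day) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(ids, "rank")))) |>
    dplyr::summarise(
      cessation_day = {
        d <- .data$distance; dy <- .data$day
        ch <- abs(diff(d)) / diff(dy)
        stable <- ch < stability_threshold - 1e-9
        res <- NA_real_
        if (length(stable) >= k) {
          runs <- which(vapply(seq_len(length(stable) - k + 1L),
                               function(i) all(stable[i:(i + k - 1L)]), logical(1)))
          if (length(runs)) res <- dy[runs[1]]
        }
        res
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(mature = !is.na(.data$cessation_day))
}

#' Predict the final length of a still-growing phytomer
#'
#' Final phytomer length declines roughly linearly with rank beyond the
#' plateau, so a per-tiller ordinary least-squares line of mature final
#' length against rank, extrapolated upward, predicts the final length of
#' the tiller's immature phytomers. The fit uses only that same tiller's
#' mature phytomers at ranks >= `fit_min_rank`.
#'
#' @param dissection Dissection records of one tiller (columns `rank`,
#'   `phytomer_length`, `maturity`).
#' @param target_rank Rank(s) at which to predict.
#' @param fit_min_rank Lowest rank entering the fit (default 8, the start of
#'   the decline).
#' @return Predicted final length(s) in mm.
#' @export
predict_final_length <- function(dissection, target_rank, fit_min_rank = 8) {
  stopifnot(all(c("rank", "phytomer_length", "maturity") %in% names(dissection)))
  mat <- dplyr::filter(dissection, .data$maturity == "mature",
                       .data$rank >= fit_min_rank)
  if (nrow(mat) < 3L) {
    stop("need >= 3 mature phytomers at ranks >= ", fit_min_rank,
         " to extrapolate final length", call. = FALSE)
  }
  fit <- stats::lm(phytomer_length ~ rank, data = mat)
  pred <- unname(stats::predict(fit, newdata = data.frame(rank = target_rank)))
  if (any(pred <= 0)) stop("non-positive predicted final length", call. = FALSE)
  pred
}

#' Fraction of final length
#'
#' The normalization at the heart of the analysis: actual length divided by
#' (predicted) final length. Component variants divide blade, sheath or
#' internode length by the same final *phytomer* length.
#'
#' @param actual_length Actual length(s), mm, >= 0.
#' @param final_length Predicted or measured final length(s), mm, > 0.
#' @return `actual_length / final_length`.
#' @export
fraction_of_final <- function(actual_length, final_length) {
  stopifnot(is.numeric(actual_length), is.numeric(final_length))
  if (any(final_length <= 0)) stop("final length must be > 0", call. = FALSE)
  if (any(actual_length < 0)) stop("actual length must be >= 0", call. = FALSE)
  actual_length / final_length
}

#' Add final-length predictions and fractions to a dissection table
#'
#' For every dissected phytomer: mature phytomers keep their measured length
#' as final length (fraction exactly 1); immature phytomers get the
#' per-tiller rank extrapolation of [predict_final_length()]. Tillers with
#' too few mature phytomers are dropped with a warning.
#'
#' @param dissection Multi-tiller dissection table.
#' @param fit_min_rank Lowest rank entering the per-tiller fit (default 8).
#' @return The dissection table with columns `final_length`, `f_L`, and
#'   component fractions `blade_f`, `sheath_f`, `internode_f`.
#' @export
add_final_length_predictions <- function(dissection, fit_min_rank = 8) {
  ids <- id_cols_of(dissection)
  dropped <- character()
  out <- dissection |>
    dplyr::group_by(dplyr::across(dplyr::all_of(ids))) |>
    dplyr::group_modify(function(d, g) {
      imm <- d$maturity == "immature"
      lp <- d$phytomer_length
      if (any(imm)) {
        pred <- tryCatch(predict_final_length(d, d$rank[imm], fit_min_rank),
                         error = function(e) NULL)
        if (is.null(pred)) {
          dropped <<- c(dropped, g$tiller_id)
          return(d[0, ])
        }
        lp[imm] <- pred
      }
      d$final_length <- lp
      d
    }) |>
    dplyr::ungroup()
  if (length(dropped)) {
    warning("dropped ", length(dropped),
            " tiller(s) without enough mature phytomers for extrapolation",
            call. = FALSE)
  }
  out |>
    dplyr::mutate(
      f_L = fraction_of_final(.data$phytomer_length, .data$final_length),
      blade_f = .data$blade / .data$final_length,
      sheath_f = .data$sheath / .data$final_length,
      internode_f = .data$internode / .data$final_length
    )
}

#' Reconstruct the visible phase of the time course
#'
#' For phytomers monitored from tip emergence to full expansion (by default
#' ranks 12-13) whose final length was measured at dissection, daily actual
#' lengths are reconstructed backwards from the final length by subtracting
#' the daily elongation increments of the tip-to-ligule distance. Each day
#' contributes a point (age = day - emergence day, fraction of final
#' length). Increments measured across a change of reference ligule (or
#' across a > 1 day gap) are replaced by linear interpolation of the
#' neighbouring rates, with a logged warning.
#'
#' @param observations Observation table.
#' @param dissection Dissection table (for measured final lengths).
#' @param events Output of [estimate_emergence()].
#' @param cessation Output of [detect_full_expansion()].
#' @param ranks Monitored ranks (default `12:14`).
#' @return A tibble of time-course points with `phase = "visible"`.
#' @export
build_visible_timecourse <- function(observations, dissection, events,
                                     cessation = detect_full_expansion(observations),
                                     ranks = 12:14) {
  ids <- id_cols_of(observations)
  eligible <- events |>
    dplyr::filter(.data$reliable, .data$rank %in% ranks) |>
    dplyr::inner_join(
      cessation |> dplyr::filter(.data$mature) |>
        dplyr::select(dplyr::all_of(c("tiller_id", "rank", "cessation_day"))),
      by = c("tiller_id", "rank")
    ) |>
    dplyr::inner_join(
      dissection |> dplyr::filter(.data$maturity == "mature") |>
        dplyr::select(dplyr::all_of(c("tiller_id", "rank", "phytomer_length"))),
      by = c("tiller_id", "rank")
    ) |>
    dplyr::rename(final_length = "phytomer_length")
  if (nrow(eligible) == 0L) {
    warning("no phytomer was monitored from emergence to full expansion", call. = FALSE)
    return(tibble::tibble())
  }
  n_interp <- 0L
  out <- eligible |>
    dplyr::rowwise() |>
    dplyr::group_map(function(ev, ...) {
      ser <- observations |>
        dplyr::filter(.data$tiller_id == ev$tiller_id, .data$rank == ev$rank) |>
        dplyr::arrange(.data$day)
      inc <- diff(ser$distance)
      ok <- diff(ser$day) == 1
      if ("reference_rank" %in% names(ser)) {
        same_ref <- {
          r <- ser$reference_rank
          (r[-1] == r[-length(r)]) | (is.na(r[-1]) & is.na(r[-length(r)]))
        }
        ok <- ok & same_ref
      }
      if (any(!ok)) {
        n_interp <<- n_interp + sum(!ok)
        idx <- seq_along(inc)
        if (sum(ok) >= 2L) {
          inc[!ok] <- stats::approx(idx[ok], inc[ok], xout = idx[!ok], rule = 2)$y
        }
      }
      actual <- ev$final_length - rev(cumsum(rev(c(inc, 0))))
      tibble::tibble(
        !!!stats::setNames(as.list(ev[ids]), ids),
        rank = ev$rank, day = ser$day,
        age = ser$day - ev$emergence_day,
        f_L = actual / ev$final_length,
        phase = "visible"
      )
    }) |>
    dplyr::bind_rows()
  if (n_interp > 0L) {
    message("build_visible_timecourse: interpolated ", n_interp,
            " increment(s) across gaps or reference changes")
  }
  out
}

#' Date immature phytomers by phyllochron offsets
#'
#' The invisible (pre-emergence) phase cannot be observed directly. For each
#' tiller, one immature phytomer that has reached 60-80 % of its final
#' length (typically the second oldest immature one) is anchored on the
#' fitted visible time course: its age is the curve's inverse at its
#' fraction. Among several candidates the one closest to the middle of the
#' anchor window is used: noisy final-length predictions can push phytomers
#' across the window edges, and mid-window candidates are robust to that. Every younger phytomer is then dated by
#' subtracting one phyllochron per rank step, giving (age, fraction) points
#' for the initial phase of development.
#'
#' @param dissection_f Dissection table with fractions (from
#'   [add_final_length_predictions()]).
#' @param visible_curve A fitted [sigmoid_curve()] for the visible phase
#'   (may be a named list per treatment).
#' @param phyllochron Per-tiller phyllochron table from
#'   [compute_phyllochron()], or a single number.
#' @param anchor_window Fraction window for the anchor (default
#'   `c(0.60, 0.80)`).
#' @return A tibble of time-course points with `phase = "initial"`.
#' @export
assign_invisible_ages <- function(dissection_f, visible_curve, phyllochron,
                                  anchor_window = c(0.60, 0.80)) {
  stopifnot(all(c("tiller_id", "rank", "f_L", "maturity") %in% names(dissection_f)))
  ids <- id_cols_of(dissection_f)
  phy_lookup <- if (is.numeric(phyllochron)) NULL else phyllochron
  skipped <- 0L
  out <- dissection_f |>
    dplyr::filter(.data$maturity == "immature") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(ids))) |>
    dplyr::group_modify(function(d, g) {
      d <- dplyr::arrange(d, .data$rank)
      cand <- which(d$f_L >= anchor_window[1] & d$f_L <= anchor_window[2])
      if (!length(cand)) { skipped <<- skipped + 1L; return(d[0, c("rank", "f_L")]) }
      a <- cand[which.min(abs(d$f_L[cand] - mean(anchor_window)))]
      crv <- if (inherits(visible_curve, "sigmoid_curve")) visible_curve
             else visible_curve[[g$treatment]]
      if (!inherits(crv, "sigmoid_curve")) {   # no visible fit for this treatment
        skipped <<- skipped + 1L
        return(d[0, c("rank", "f_L")])
      }
      p <- if (is.null(phy_lookup)) phyllochron else {
        v <- phy_lookup$phyllochron[phy_lookup$tiller_id == g$tiller_id]
        if (length(v) == 1L && is.finite(v)) v else mean(phy_lookup$phyllochron, na.rm = TRUE)
      }
      anchor_age <- invert_sigmoid(crv, d$f_L[a])
      keep <- seq(a, nrow(d))
      tibble::tibble(rank = d$rank[keep], f_L = d$f_L[keep],
                     age = anchor_age - (d$rank[keep] - d$rank[a]) * p)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(phase = "initial")
  if (skipped > 0L) {
    warning(skipped, " tiller(s) skipped (no anchor candidate or no visible-phase curve)",
            call. = FALSE)
  }
  out
}

#' Coordination tables
#'
#' Builds the two tables that summarize elongation coordination at
#' dissection: the within-phytomer table (component fractions of final
#' phytomer length vs the phytomer's own fraction) and the between-phytomer
#' table (fractions of successive phytomers, ordered older to younger, for
#' pairs whose younger member is still immature).
#'
#' @param dissection_f Dissection table with fractions.
#' @return A list with tibbles `within` and `between`.
#' @export
build_coordination_tables <- function(dissection_f) {
  stopifnot(all(c("tiller_id", "rank", "f_L") %in% names(dissection_f)))
  ids <- id_cols_of(dissection_f)
  within <- dissection_f |>
    dplyr::select(dplyr::all_of(c(ids, "rank", "maturity", "f_L",
                                  "blade_f", "sheath_f", "internode_f")))
  between <- dissection_f |>
    dplyr::arrange(.data$tiller_id, .data$rank) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(ids))) |>
    dplyr::reframe({
      d <- dplyr::pick(dplyr::everything())
      i <- which(diff(d$rank) == 1L)
      keep <- i[d$maturity[i + 1L] == "immature"]
      tibble::tibble(rank_older = d$rank[keep], rank_younger = d$rank[keep + 1L],
                     f_older = d$f_L[keep], f_younger = d$f_L[keep + 1L])
    }) |>
    dplyr::ungroup()
  list(within = within, between = between)
}

#' Run the full reconstruction pipeline
#'
#' Chains emergence estimation, phyllochron computation, cessation
#' detection, final-length extrapolation, the visible and initial phases of
#' the time course (with treatment-specific visible-phase curve fits used to
#' anchor the initial phase), and the coordination tables.
#'
#' @param observations,dissection The two measurement tables.
#' @param monitored_ranks Ranks eligible for the visible time course
#'   (default `12:14`; which rank is actually covered from emergence to
#'   cessation inside the observation window depends on the phyllochron).
#' @param rank_window Rank window for the phyllochron (default `c(7, 16)`).
#' @param max_lag Reliability bound for emergence events, days.
#' @param stability_threshold Cessation threshold, mm/day (see
#'   [detect_full_expansion()]).
#' @param anchor_window Anchor fraction window for the initial phase.
#' @param fit_min_rank Lowest rank in the final-length extrapolation.
#' @return A list of class `phyto_reconstruction` with all intermediate and
#'   final tables, including the combined `timecourse`.
#' @export
reconstruct_experiment <- function(observations, dissection,
                                   monitored_ranks = 12:14,
                                   rank_window = c(7, 16),
                                   max_lag = 1.5,
                                   stability_threshold = 0.5,
                                   anchor_window = c(0.60, 0.80),
                                   fit_min_rank = 8) {
  events <- estimate_emergence(observations, max_lag = max_lag)
  phyllo <- compute_phyllochron(events, rank_window = rank_window)
  cess <- detect_full_expansion(observations,
                                stability_threshold = stability_threshold)
  dis_f <- add_final_length_predictions(dissection, fit_min_rank = fit_min_rank)
  visible <- build_visible_timecourse(observations, dissection, events,
                                      cessation = cess, ranks = monitored_ranks)
  ## treatment-specific visible-phase curves anchor the initial phase
  trts <- if ("treatment" %in% names(visible)) unique(visible$treatment) else NULL
  curves <- NULL
  if (!is.null(trts) && nrow(visible)) {
    curves <- lapply(stats::setNames(trts, trts), function(tr) {
      pts <- dplyr::filter(visible, .data$treatment == tr)
      ft <- fit_sigmoid2(pts, x = age, y = f_L)
      ft$curve
    })
  } else if (nrow(visible)) {
    curves <- fit_sigmoid2(visible, x = age, y = f_L)$curve
  }
  initial <- if (!is.null(curves)) {
    assign_invisible_ages(dis_f, curves,
                          phyllochron = phyllo, anchor_window = anchor_window)
  } else tibble::tibble()
  timecourse <- dplyr::bind_rows(visible, initial)
  coord <- build_coordination_tables(dis_f)
  structure(list(events = events, phyllochron = phyllo, cessation = cess,
                 dissection = dis_f, visible = visible, initial = initial,
                 timecourse = timecourse, visible_curves = curves,
                 coordination_within = coord$within,
                 coordination_between = coord$between,
                 monitored_ranks = monitored_ranks),
            class = "phyto_reconstruction")
}

#' @export
print.phyto_reconstruction <- function(x, ...) {
  cat("<phyto_reconstruction>\n")
  cat(sprintf("  %d emergence events (%d reliable), %d time-course points (%d visible / %d initial)\n",
              nrow(x$events), sum(x$events$reliable), nrow(x$timecourse),
              nrow(x$visible), nrow(x$initial)))
  invisible(x)
}
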