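#' Default treatment structure
#'
#' The 2 x 2 nitrogen x vapour-pressure-deficit design emulated by the
#' generator: two N levels crossed with two VPD levels, two growth chambers
#' per cell and eight tillers per chamber. Per-treatment phyllochrons and the
#' low-VPD length response follow the study conditions; tiller counts enter
#' only as per-treatment summary constants (tillering dynamics are out of
#' scope).
#'
#' @return A tibble with one row per treatment cell.
#' @export
default_treatments <- function() {
  tibble::tibble(
    treatment         = c("N1V1", "N1V2", "N2V1", "N2V2"),
    nitrogen          = c("N1", "N1", "N2", "N2"),
    vpd               = c("V1", "V2", "V1", "V2"),
    phyllochron       = c(2.4, 2.4, 2.1, 2.4),
    plateau_length    = c(100, 100, 108, 100),
    tiller_count_mean = c(19.7, 17.6, 24.0, 21.7),
    tiller_count_sd   = c(7.2, 4.0, 4.4, 6.4)
  )
}

#' Generator configuration
#'
#' Study conditions for the forward simulator: the developmental clock
#' (phyllochron and complete-time-course sigmoid), the rank profile of final
#' lengths (plateau then ~4 %-of-plateau decline per rank from rank 8), the
#' enclosing-whorl geometry that censors young phytomers, the two measurement
#' instruments (daily ruler reads at 0.5 mm resolution over days 24-37;
#' destructive dissection at day 37 keeping phytomers > 4 mm), and the noise
#' model (lognormal final lengths, Gaussian initiation-time jitter).
#'
#' @param n_tillers Tillers per chamber (default 8).
#' @param n_chambers Chambers per treatment cell (default 2).
#' @param phyllochron Days between successive tip emergences (default 2.3;
#'   overridden per treatment by `treatments$phyllochron`).
#' @param timecourse_x0,timecourse_b Parameters of the complete time course
#'   of phytomer development, fraction of final length vs days after tip
#'   emergence (defaults 1.82 and 1.81 days).
#' @param plateau_length Final phytomer length at the plateau ranks, mm
#'   (default 100).
#' @param decline_start_rank Rank after which final length declines
#'   (default 8).
#' @param decline_per_rank Linear decline, fraction of the plateau per rank
#'   (default 0.04, i.e. rank 13 is 80 % of rank 8).
#' @param rank_range Integer range of simulated ranks (default 1-18).
#' @param thresholds A [partition_thresholds()] for component allocation.
#' @param whorl_fraction Height of the enclosing whorl (pseudostem) above a
#'   phytomer's insertion node, as a fraction of the *enclosing* phytomer's
#'   final length (default 0.236). This sets the tip-emergence censoring:
#'   with the default rank decline it places zero-noise emergence at ~26-27 %
#'   of final length over the observed ranks, i.e. at age 0 of the complete
#'   time course.
#' @param emergence_offset Day offset of the emergence clock: rank r emerges
#'   (nominal) at `emergence_offset + r * phyllochron` (default -5.0, which
#'   places the full visible phase of a monitored rank (12 or 13, depending
#'   on the phyllochron) inside the day 24-37 observation window).
#' @param length_cv Total lognormal coefficient of variation of final
#'   lengths (default 0.10; 0 disables).
#' @param tiller_size_share Fraction of the length variance shared by all
#'   phytomers of a tiller (default 0.8). Plant-to-plant size heterogeneity
#'   (which the fraction-of-final-length normalization exists to absorb) is
#'   much larger than the within-tiller scatter around the smooth rank
#'   profile, so most of the noise is a common tiller-level factor.
#' @param timing_sd Gaussian jitter, days, on each phytomer's clock offset
#'   (default 0.2; 0 disables).
#' @param curve_jitter_sd Lognormal jitter on each phytomer's time-course
#'   scale `b` (default 0, i.e. a shared curve).
#' @param measurement_resolution Ruler resolution, mm; observations are
#'   rounded half-up to multiples of this (default 0.5; 0 records exact
#'   distances).
#' @param observation_window Integer days of daily ruler observation
#'   (default `c(24, 37)`).
#' @param dissection_day Day of destructive harvest (default 37).
#' @param min_dissect_length Phytomers with total length <= this (mm) are
#'   not recorded at dissection (default 4).
#' @param maturity_fraction Fraction of final length defining cessation of
#'   elongation (default 0.99).
#' @param seed Integer root seed; identical seed and config give identical
#'   output tables.
#' @param treatments Tibble of treatment cells as in [default_treatments()],
#'   or `NULL` for a single unlabelled cell using the base parameters.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_tillers = 8,
                             n_chambers = 2,
                             phyllochron = 2.3,
                             timecourse_x0 = 1.82,
                             timecourse_b = 1.81,
                             plateau_length = 100,
                             decline_start_rank = 8,
                             decline_per_rank = 0.04,
                             rank_range = c(1L, 18L),
                             thresholds = partition_thresholds(),
                             whorl_fraction = 0.236,
                             emergence_offset = -5.0,
                             length_cv = 0.10,
                             tiller_size_share = 0.8,
                             timing_sd = 0.2,
                             curve_jitter_sd = 0,
                             measurement_resolution = 0.5,
                             observation_window = c(24L, 37L),
                             dissection_day = 37,
                             min_dissect_length = 4,
                             maturity_fraction = 0.99,
                             seed = 1L,
                             treatments = default_treatments()) {
  cfg <- list(
    n_tillers = n_tillers, n_chambers = n_chambers,
    phyllochron = phyllochron,
    timecourse_x0 = timecourse_x0, timecourse_b = timecourse_b,
    plateau_length = plateau_length,
    decline_start_rank = decline_start_rank,
    decline_per_rank = decline_per_rank,
    rank_range = as.integer(rank_range),
    thresholds = thresholds,
    whorl_fraction = whorl_fraction,
    emergence_offset = emergence_offset,
    length_cv = length_cv, tiller_size_share = tiller_size_share,
    timing_sd = timing_sd,
    curve_jitter_sd = curve_jitter_sd,
    measurement_resolution = measurement_resolution,
    observation_window = as.integer(observation_window),
    dissection_day = dissection_day,
    min_dissect_length = min_dissect_length,
    maturity_fraction = maturity_fraction,
    seed = as.integer(seed),
    treatments = treatments
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

#' @rdname generator_config
#' @param config A list to validate.
#' @export
validate_generator_config <- function(config) {
  with(config, {
    if (!is.numeric(n_tillers) || n_tillers < 1) stop("n_tillers must be >= 1", call. = FALSE)
    if (phyllochron <= 0) stop("phyllochron must be > 0", call. = FALSE)
    if (timecourse_b <= 0) stop("timecourse_b must be > 0", call. = FALSE)
    if (plateau_length <= 0) stop("plateau_length must be > 0", call. = FALSE)
    if (length_cv < 0 || timing_sd < 0 || curve_jitter_sd < 0)
      stop("noise parameters must be >= 0", call. = FALSE)
    if (tiller_size_share < 0 || tiller_size_share >= 1)
      stop("tiller_size_share must be in [0, 1)", call. = FALSE)
    if (measurement_resolution < 0) stop("measurement_resolution must be >= 0", call. = FALSE)
    if (whorl_fraction <= 0 || whorl_fraction >= 1)
      stop("whorl_fraction must be in (0, 1)", call. = FALSE)
    if (length(rank_range) != 2L || rank_range[1] < 1L || rank_range[2] <= rank_range[1])
      stop("rank_range must be an increasing pair of positive integers", call. = FALSE)
    if (length(observation_window) != 2L || observation_window[2] < observation_window[1])
      stop("observation_window must be an increasing pair of days", call. = FALSE)
    if (dissection_day < observation_window[1])
      stop("dissection_day must not precede the observation window", call. = FALSE)
    lp_min <- plateau_length * (1 - decline_per_rank * max(0, rank_range[2] - decline_start_rank))
    if (lp_min <= 0) stop("decline leaves non-positive final lengths at the top rank", call. = FALSE)
    if (!is.null(treatments)) {
      need <- c("treatment", "nitrogen", "vpd", "phyllochron", "plateau_length")
      if (!all(need %in% names(treatments)))
        stop("treatments table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
    }
    invisible(TRUE)
  })
  invisible(config)
}

## Rank profile of final lengths: plateau, then linear decline.
rank_profile <- function(rank, plateau, decline_start, decline_per_rank) {
  plateau * (1 - decline_per_rank * pmax(0, rank - decline_start))
}

## Round half-up (away from the IEEE half-even rule) to a multiple of `res`.
## res = 0 means no rounding.
round_to_resolution <- function(x, res) {
  if (res <= 0) return(x)
  floor(x / res + 0.5 + 1e-9) * res
}

#' Simulate one tiller
#'
#' Forward-simulates every phytomer of a tiller: rank r's development follows
#' the complete-time-course sigmoid shifted so that nominal tip emergence
#' falls at `emergence_offset + r * phyllochron` (plus Gaussian jitter), its
#' final length comes from the rank profile times lognormal noise, and its
#' component lengths follow [partition_components()]. True tip emergence is
#' then computed from the 1-D height model (nodes stacked on internodes,
#' tips rising past the highest visible ligule), and true cessation as the
#' crossing of `maturity_fraction`.
#'
#' @param config A [generator_config()]. Random draws come from the current
#'   RNG state; see [generate_experiment()] for the seeded entry point.
#' @param phyllochron,plateau_length Optional overrides of the config values
#'   (used for per-treatment conditions).
#' @return A list of class `tiller_sim` with `$phytomers`, a tibble with one
#'   row per rank (`rank`, `final_length`, `offset`, `b`, `emergence_day`,
#'   `cessation_day`), and the config as an attribute.
#' @export
simulate_tiller <- function(config, phyllochron = NULL, plateau_length = NULL) {
  stopifnot(inherits(config, "generator_config"))
  p  <- phyllochron %||% config$phyllochron
  pl <- plateau_length %||% config$plateau_length
  ranks <- seq.int(config$rank_range[1], config$rank_range[2])
  n <- length(ranks)

  lp0 <- rank_profile(ranks, pl, config$decline_start_rank, config$decline_per_rank)
  if (config$length_cv > 0) {
    ## split the variance into a common tiller-size factor and a
    ## per-phytomer residual around the smooth rank profile
    cv_t <- config$length_cv * sqrt(config$tiller_size_share)
    cv_p <- config$length_cv * sqrt(1 - config$tiller_size_share)
    sd_t <- sqrt(log(1 + cv_t^2)); sd_p <- sqrt(log(1 + cv_p^2))
    size <- if (cv_t > 0) stats::rlnorm(1, meanlog = -sd_t^2 / 2, sdlog = sd_t) else 1
    lp <- lp0 * size *
      (if (cv_p > 0) stats::rlnorm(n, meanlog = -sd_p^2 / 2, sdlog = sd_p) else 1)
  } else lp <- lp0
  offset <- config$emergence_offset + ranks * p +
    (if (config$timing_sd > 0) stats::rnorm(n, 0, config$timing_sd) else 0)
  b <- if (config$curve_jitter_sd > 0) {
    config$timecourse_b * stats::rlnorm(n, meanlog = -config$curve_jitter_sd^2 / 2,
                                        sdlog = config$curve_jitter_sd)
  } else rep(config$timecourse_b, n)

  phy <- tibble::tibble(rank = ranks, final_length = lp, offset = offset, b = b)
  phy$emergence_day <- true_emergence_days(phy, config)
  phy$cessation_day <- offset + config$timecourse_x0 -
    b * log(1 / config$maturity_fraction - 1)

  structure(list(phytomers = phy), class = "tiller_sim", config = config)
}

## Developmental fraction of each rank at each time: S(t - offset) with the
## shared midpoint x0 and per-phytomer scale b. Rows = times, cols = ranks.
fraction_matrix <- function(phy, config, times) {
  x <- outer(times, phy$offset, "-")
  1 / (1 + exp((config$timecourse_x0 - x) / rep(phy$b, each = length(times))))
}

## Full height-model state at the given times. Heights in mm above the tiller
## base: node of rank r sits on the internodes of ranks <= r; a phytomer's
## tip is its insertion node (node of r-1) plus its own length; a ligule,
## once its sheath has ceased (f >= internode_onset), sits `whorl_fraction`
## of the phytomer's final length above the insertion node of the *next*
## rank, i.e. node_r + whorl_fraction * Lp_r.
tiller_state <- function(phy, config, times) {
  nt <- length(times); nr <- nrow(phy)
  f <- fraction_matrix(phy, config, times)
  comp <- partition_components(as.vector(f), config$thresholds)
  lpm <- matrix(phy$final_length, nt, nr, byrow = TRUE)
  blade     <- matrix(comp$blade,     nt, nr) * lpm
  sheath    <- matrix(comp$sheath,    nt, nr) * lpm
  internode <- matrix(comp$internode, nt, nr) * lpm
  total <- blade + sheath + internode
  node <- t(apply(internode, 1L, cumsum))
  if (nt == 1L) node <- matrix(node, 1L, nr)
  base <- cbind(0, node[, -nr, drop = FALSE])     # insertion node of each rank
  tip <- base + total
  ligule <- node + config$whorl_fraction * lpm
  visible <- f >= config$thresholds$internode_onset
  ## growing whorl: the sheath top rises in proportion to sheath growth and
  ## tops out at the full whorl height once the sheath ceases
  sheath_final_share <- config$thresholds$internode_onset -
    config$thresholds$blade_final_fraction
  whorl <- node + config$whorl_fraction * lpm *
    pmin(1, sheath / (sheath_final_share * lpm))
  list(times = times, f = f, total = total, blade = blade, sheath = sheath,
       internode = internode, node = node, base = base, tip = tip,
       ligule = ligule, visible = visible, whorl = whorl)
}

## True tip-emergence day of every rank: first time the tip exceeds the top
## of the enclosing whorl (the tallest older sheath top, growing or ceased).
## Grid scan plus linear refinement.
true_emergence_days <- function(phy, config, step = 0.05) {
  times <- seq(min(phy$offset) - 6, max(phy$offset) + 6, by = step)
  st <- tiller_state(phy, config, times)
  nr <- nrow(phy)
  ## tallest whorl top among ranks < r, per time
  cmax <- t(apply(st$whorl, 1L, cummax))
  if (nrow(phy) == 1L) cmax <- matrix(cmax, ncol = 1L)
  whorl_top <- cbind(0, cmax[, -nr, drop = FALSE])
  g <- st$tip - whorl_top
  ## Emergence = the last upcrossing of g: the sigmoid's tails give every
  ## phytomer an infinitesimal positive length long before the whorl has
  ## grown, so the first sign change is degenerate; what matters is the time
  ## after which the tip stays above the whorl for good.
  vapply(seq_len(nr), function(j) {
    below <- which(g[, j] <= 0)
    if (!length(below)) return(times[1])
    i <- max(below)
    if (i == length(times)) return(NA_real_)
    t0 <- times[i]; t1 <- times[i + 1L]
    g0 <- g[i, j];  g1 <- g[i + 1L, j]
    t0 + (t1 - t0) * (-g0) / (g1 - g0)
  }, numeric(1))
}

#' True per-day phytomer trajectories
#'
#' Ground-truth daily lengths of every phytomer of a simulated tiller:
#' total length and its exact blade/sheath/internode partition (components
#' sum to the total exactly), plus the developmental fraction.
#'
#' @param tiller A `tiller_sim` from [simulate_tiller()].
#' @param days Numeric vector of days (default: the observation window).
#' @return A tibble with columns `day`, `rank`, `f`, `total`, `blade`,
#'   `sheath`, `internode`.
#' @export
trajectory_table <- function(tiller, days = NULL) {
  stopifnot(inherits(tiller, "tiller_sim"))
  config <- attr(tiller, "config")
  days <- days %||% seq(config$observation_window[1], config$observation_window[2])
  st <- tiller_state(tiller$phytomers, config, days)
  tibble::tibble(
    day = rep(days, times = nrow(tiller$phytomers)),
    rank = rep(tiller$phytomers$rank, each = length(days)),
    f = as.vector(st$f),
    total = as.vector(st$total),
    blade = as.vector(st$blade),
    sheath = as.vector(st$sheath),
    internode = as.vector(st$internode)
  )
}

#' Emulate daily ruler observations
#'
#' Reproduces the field protocol: each day of the observation window, for
#' every emerged phytomer, the distance from its tip to the next older
#' visible ligule is read off and rounded half-up to the measurement
#' resolution. A ligule becomes visible once its sheath has ceased
#' elongating; a phytomer appears in the table only from its true emergence
#' day (growth before that is hidden inside the whorl). When no older ligule
#' is visible the distance is measured from the tiller base.
#'
#' @param tiller A `tiller_sim`.
#' @param config The generator configuration (defaults to the one stored in
#'   `tiller`).
#' @return A tibble with columns `day`, `rank`, `distance`,
#'   `reference_rank` (NA when measured from the base), `ligule_visible`.
#' @export
emulate_observations <- function(tiller, config = NULL) {
  stopifnot(inherits(tiller, "tiller_sim"))
  config <- config %||% attr(tiller, "config")
  phy <- tiller$phytomers
  if (nrow(phy) == 0L) stop("empty trajectory list", call. = FALSE)
  days <- seq(config$observation_window[1], config$observation_window[2])
  st <- tiller_state(phy, config, days)
  nr <- nrow(phy)
  out <- vector("list", length(days))
  for (i in seq_along(days)) {
    d <- days[i]
    emerged <- which(!is.na(phy$emergence_day) & phy$emergence_day <= d)
    if (!length(emerged)) next
    vis <- which(st$visible[i, ])
    rows <- lapply(emerged, function(j) {
      older_vis <- vis[vis < j]
      if (length(older_vis)) {
        ref <- max(older_vis)
        dist <- st$tip[i, j] - st$ligule[i, ref]
        ref_rank <- phy$rank[ref]
      } else {
        dist <- st$tip[i, j]
        ref_rank <- NA_integer_
      }
      tibble::tibble(day = d, rank = phy$rank[j],
                     distance = round_to_resolution(max(dist, 0), config$measurement_resolution),
                     reference_rank = ref_rank,
                     ligule_visible = st$visible[i, j])
    })
    out[[i]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(out)
}

#' Emulate a destructive dissection
#'
#' Snapshot of blade, sheath and internode lengths of every phytomer at the
#' harvest day, each rounded to the measurement resolution, with the phytomer
#' length recorded as the sum of its components. Phytomers with total length
#' at or below `min_dissect_length` (the shoot apex region) are dropped.
#' Maturity is flagged at `maturity_fraction` of final length.
#'
#' @param tiller A `tiller_sim`.
#' @param day Dissection day (default from the config).
#' @param config Generator configuration (default: stored in `tiller`).
#' @return A tibble with columns `rank`, `blade`, `sheath`, `internode`,
#'   `phytomer_length`, `maturity`.
#' @export
emulate_dissection <- function(tiller, day = NULL, config = NULL) {
  stopifnot(inherits(tiller, "tiller_sim"))
  config <- config %||% attr(tiller, "config")
  day <- day %||% config$dissection_day
  if (day < 0 || day > config$dissection_day + 30)
    stop("dissection day outside the simulated range", call. = FALSE)
  phy <- tiller$phytomers
  st <- tiller_state(phy, config, day)
  res <- config$measurement_resolution
  blade <- round_to_resolution(st$blade[1, ], res)
  sheath <- round_to_resolution(st$sheath[1, ], res)
  internode <- round_to_resolution(st$internode[1, ], res)
  tibble::tibble(
    rank = phy$rank,
    blade = blade, sheath = sheath, internode = internode,
    phytomer_length = blade + sheath + internode,
    maturity = ifelse(st$f[1, ] >= config$maturity_fraction, "mature", "immature")
  ) |>
    dplyr::filter(.data$phytomer_length > config$min_dissect_length)
}

#' Generate a full synthetic experiment
#'
#' Simulates every tiller of the factorial design (treatment cells x
#' chambers x tillers per chamber) and applies both measurement instruments,
#' returning the daily observation table, the dissection table and the
#' ground-truth table. Fully reproducible: the same config and seed give
#' identical tables.
#'
#' @param config A [generator_config()].
#' @return A list of class `phyto_experiment` with tibbles `observations`,
#'   `dissection`, `truth`, and the `config`.
#' @examples
#' \donttest{
#' exp <- generate_experiment(generator_config(n_tillers = 2, seed = 42))
#' head(exp$observations)
#' }
#' @export
generate_experiment <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  set.seed(config$seed)
  trt <- config$treatments %||%
    tibble::tibble(treatment = "T1", nitrogen = NA_character_, vpd = NA_character_,
                   phyllochron = config$phyllochron,
                   plateau_length = config$plateau_length,
                   tiller_count_mean = NA_real_, tiller_count_sd = NA_real_)
  obs_l <- list(); dis_l <- list(); tru_l <- list()
  for (ti in seq_len(nrow(trt))) {
    for (ch in seq_len(config$n_chambers)) {
      chamber_id <- sprintf("%s_c%d", trt$treatment[ti], ch)
      for (pl in seq_len(config$n_tillers)) {
        tiller_id <- sprintf("%s_t%02d", chamber_id, pl)
        tl <- simulate_tiller(config,
                              phyllochron = trt$phyllochron[ti],
                              plateau_length = trt$plateau_length[ti])
        n_tillers <- if (is.finite(trt$tiller_count_mean[ti])) {
          max(1, round(stats::rnorm(1, trt$tiller_count_mean[ti],
                                    trt$tiller_count_sd[ti] %||% 0)))
        } else NA_real_
        id_cols <- tibble::tibble(treatment = trt$treatment[ti],
                                  chamber = chamber_id, tiller_id = tiller_id)
        obs <- emulate_observations(tl, config)
        if (nrow(obs)) obs_l[[tiller_id]] <- dplyr::bind_cols(
          id_cols[rep(1, nrow(obs)), ], obs, tibble::tibble(n_tillers = rep(n_tillers, nrow(obs))))
        dis <- emulate_dissection(tl, config$dissection_day, config)
        if (nrow(dis)) dis_l[[tiller_id]] <- dplyr::bind_cols(
          id_cols[rep(1, nrow(dis)), ], dis)
        phy <- tl$phytomers
        tru_l[[tiller_id]] <- dplyr::bind_cols(
          id_cols[rep(1, nrow(phy)), ], phy,
          tibble::tibble(n_tillers = rep(n_tillers, nrow(phy))))
      }
    }
  }
  structure(list(observations = dplyr::bind_rows(obs_l),
                 dissection = dplyr::bind_rows(dis_l),
                 truth = dplyr::bind_rows(tru_l),
                 config = config),
            class = "phyto_experiment")
}

#' @export
print.phyto_experiment <- function(x, ...) {
  cat("<phyto_experiment>\n")
  cat(sprintf("  %d tillers, %d observation rows, %d dissected phytomers (seed %d)\n",
              dplyr::n_distinct(x$truth$tiller_id), nrow(x$observations),
              nrow(x$dissection), x$config$seed))
  invisible(x)
}
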