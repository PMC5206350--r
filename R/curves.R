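#' Generalized logistic (sigmoid) growth curve
#'
#' Container for the three-parameter logistic
#' \deqn{y(x) = a / \{1 + \exp[(x_0 - x)/b]\}}
#' used throughout the package to describe phytomer elongation, either on a
#' days-after-tip-emergence axis (the complete time course) or on a
#' fraction-of-final-length axis (within- and between-phytomer coordination).
#'
#' @param a Amplitude (upper asymptote), > 0. Dimensionless for normalized
#'   curves.
#' @param x0 Midpoint, in the units of the abscissa (days or fraction of
#'   final length). `y(x0) = a/2`.
#' @param b Scale (inverse steepness), > 0, same units as the abscissa.
#' @return An object of class `sigmoid_curve`.
#' @examples
#' crv <- sigmoid_curve(1, 1.82, 1.81)
#' eval_sigmoid(crv, 2)
#' @export
sigmoid_curve <- function(a, x0, b) {
  if (!is.numeric(a) || !is.numeric(x0) || !is.numeric(b) ||
      length(a) != 1L || length(x0) != 1L || length(b) != 1L) {
    stop("`a`, `x0` and `b` must be single numbers", call. = FALSE)
  }
  if (!is.finite(a) || a <= 0) stop("invalid curve: amplitude `a` must be > 0", call. = FALSE)
  if (!is.finite(b) || b <= 0) stop("invalid curve: scale `b` must be > 0", call. = FALSE)
  structure(list(a = as.numeric(a), x0 = as.numeric(x0), b = as.numeric(b)),
            class = "sigmoid_curve")
}

#' @export
print.sigmoid_curve <- function(x, ...) {
  cat(sprintf("<sigmoid_curve>  y = %.4g / {1 + exp[(%.4g - x)/%.4g]}\n",
              x$a, x$x0, x$b))
  invisible(x)
}

#' Straight-line curve
#'
#' Ordinary straight line `y = slope * x + intercept`, used for the internode
#' contribution to final phytomer length, which rises only slowly and
#' near-linearly with the fraction of final phytomer length.
#'
#' @param slope,intercept Line coefficients.
#' @return An object of class `linear_curve`.
#' @export
linear_curve <- function(slope, intercept) {
  stopifnot(is.numeric(slope), is.numeric(intercept),
            length(slope) == 1L, length(intercept) == 1L)
  structure(list(slope = as.numeric(slope), intercept = as.numeric(intercept)),
            class = "linear_curve")
}

#' @export
print.linear_curve <- function(x, ...) {
  cat(sprintf("<linear_curve>  y = %.4g * x + %.4g\n", x$slope, x$intercept))
  invisible(x)
}

#' Evaluate a sigmoid curve
#'
#' @param curve A [sigmoid_curve()].
#' @param x Numeric vector of abscissa values.
#' @return `a / (1 + exp((x0 - x)/b))`, strictly inside `(0, a)` for finite
#'   `x`.
#' @examples
#' eval_sigmoid(sigmoid_curve(1, 1.82, 1.81), c(0, 2))
#' @export
eval_sigmoid <- function(curve, x) {
  stopifnot(inherits(curve, "sigmoid_curve"), is.numeric(x))
  curve$a / (1 + exp((curve$x0 - x) / curve$b))
}

#' @rdname eval_sigmoid
#' @export
eval_linear <- function(curve, x) {
  stopifnot(inherits(curve, "linear_curve"), is.numeric(x))
  curve$slope * x + curve$intercept
}

#' Invert a sigmoid curve
#'
#' Closed-form inverse of [eval_sigmoid()]: the abscissa at which the curve
#' attains ordinate `y`. Used to date an immature phytomer (assign its age in
#' days after tip emergence) from its fraction of final length.
#'
#' @param curve A [sigmoid_curve()].
#' @param y Numeric vector, strictly between 0 and the curve amplitude.
#' @return `x0 - b * log(a/y - 1)`.
#' @examples
#' invert_sigmoid(sigmoid_curve(1, 1.82, 1.81), 0.5)
#' @export
invert_sigmoid <- function(curve, y) {
  stopifnot(inherits(curve, "sigmoid_curve"), is.numeric(y))
  if (any(!is.finite(y)) || any(y <= 0) || any(y >= curve$a)) {
    stop("`y` out of range: must satisfy 0 < y < a", call. = FALSE)
  }
  curve$x0 - curve$b * log(curve$a / y - 1)
}

#' Component-partition thresholds
#'
#' The narrative rule for how an elongating phytomer's length is divided
#' among blade, sheath and internode as it advances from 0 to 1 of its final
#' length: growth is all blade until `sheath_onset`; the blade then finishes
#' at `blade_final_fraction` of final phytomer length by the time the
#' phytomer reaches `blade_stop_phytomer_fraction`; the sheath completes at
#' `internode_onset`, after which all further growth is internode.
#'
#' @param sheath_onset Fraction of final phytomer length at which sheath
#'   elongation begins (default 0.50).
#' @param blade_stop_phytomer_fraction Phytomer fraction at which the blade
#'   stops elongating (default 0.75).
#' @param blade_final_fraction Final blade share of phytomer length
#'   (default 0.66).
#' @param internode_onset Phytomer fraction at which internode elongation
#'   begins and the sheath stops (default 0.80); the final sheath share is
#'   `internode_onset - blade_final_fraction`.
#' @return A list of class `partition_thresholds`.
#' @export
partition_thresholds <- function(sheath_onset = 0.50,
                                 blade_stop_phytomer_fraction = 0.75,
                                 blade_final_fraction = 0.66,
                                 internode_onset = 0.80) {
  ok <- sheath_onset > 0 && sheath_onset < blade_stop_phytomer_fraction &&
    blade_stop_phytomer_fraction < internode_onset && internode_onset < 1 &&
    blade_final_fraction < blade_stop_phytomer_fraction &&
    blade_final_fraction > sheath_onset
  if (!ok) {
    stop("invalid thresholds: need 0 < sheath_onset < blade_stop < internode_onset < 1 ",
         "and sheath_onset < blade_final_fraction < blade_stop", call. = FALSE)
  }
  structure(list(sheath_onset = sheath_onset,
                 blade_stop_phytomer_fraction = blade_stop_phytomer_fraction,
                 blade_final_fraction = blade_final_fraction,
                 internode_onset = internode_onset),
            class = "partition_thresholds")
}

#' Partition phytomer length into blade, sheath and internode
#'
#' Piecewise-linear, exactly conserving allocation of a phytomer's current
#' fraction of final length `f` to its components. With the default
#' thresholds: all blade up to f = 0.50; blade rises linearly from 0.50 to
#' 0.66 while f goes 0.50 to 0.75 (sheath takes the rest); blade fixed and
#' sheath growing for 0.75 < f <= 0.80; thereafter blade 0.66, sheath 0.14
#' and internode f - 0.80. The three components sum to `f` exactly at every
#' `f`, so the final shares are blade 0.66, sheath 0.14, internode 0.20.
#'
#' @param f Numeric vector of fractions of final phytomer length in `[0, 1]`.
#' @param thresholds A [partition_thresholds()].
#' @return A tibble with columns `f`, `blade`, `sheath`, `internode`.
#' @examples
#' partition_components(c(0.25, 0.75, 1))
#' @export
partition_components <- function(f, thresholds = partition_thresholds()) {
  stopifnot(inherits(thresholds, "partition_thresholds"), is.numeric(f))
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1)) {
    stop("`f` must lie in [0, 1]", call. = FALSE)
  }
  th <- thresholds
  blade_slope <- (th$blade_final_fraction - th$sheath_onset) /
    (th$blade_stop_phytomer_fraction - th$sheath_onset)
  blade <- ifelse(f <= th$sheath_onset, f,
           ifelse(f <= th$blade_stop_phytomer_fraction,
                  th$sheath_onset + blade_slope * (f - th$sheath_onset),
                  th$blade_final_fraction))
  internode <- pmax(0, f - th$internode_onset)
  sheath <- f - blade - internode
  tibble::tibble(f = f, blade = blade, sheath = sheath, internode = internode)
}

#' Thermal time (degree days)
#'
#' Linear thermal-time accumulation at constant air temperature:
#' `duration * max(air_temperature - base_temperature, 0)`. The growth
#' chambers emulated here ran at a constant 25 degrees C, so no sub-daily
#' integration is needed.
#'
#' @param duration Duration in days, >= 0.
#' @param air_temperature Constant air temperature, degrees C.
#' @param base_temperature Base temperature below which no thermal time
#'   accumulates, degrees C.
#' @return Thermal time in degree days.
#' @examples
#' thermal_time(37, 25, 0)     # 925 degree days
#' thermal_time(13, 25, 10.8)  # ~185 degree days
#' @export
thermal_time <- function(duration, air_temperature = 25, base_temperature = 0) {
  stopifnot(is.numeric(duration), is.numeric(air_temperature),
            is.numeric(base_temperature))
  if (any(duration < 0)) stop("`duration` must be >= 0", call. = FALSE)
  duration * pmax(air_temperature - base_temperature, 0)
}

#' Reference coordination rule set
#'
#' The fitted curves that summarize the coordination of elongation within and
#' between phytomers, plus the complete time course of phytomer development:
#' * `blade`: blade contribution vs fraction of final phytomer length,
#'   sigmoid (0.73, 0.37, 0.17);
#' * `sheath`: sheath contribution, sigmoid (0.46, 0.94, 0.13);
#' * `internode`: internode contribution, line 0.04 x - 0.0063;
#' * `between`: fraction of the next younger phytomer vs fraction of the
#'   older one, sigmoid (1.34, 0.91, 0.24) — an empirical regression valid
#'   on abscissa `[0, 1]` only (its amplitude exceeds 1);
#' * `timecourse`: fraction of final length vs days after tip emergence,
#'   two-parameter sigmoid (1, 1.82, 1.81).
#'
#' @return A named list of class `coordination_rules`.
#' @export
coordination_rules <- function() {
  structure(list(
    blade      = sigmoid_curve(0.73, 0.37, 0.17),
    sheath     = sigmoid_curve(0.46, 0.94, 0.13),
    internode  = linear_curve(0.04, -0.0063),
    between    = sigmoid_curve(1.34, 0.91, 0.24),
    timecourse = sigmoid_curve(1, 1.82, 1.81)
  ), class = "coordination_rules")
}

#' @export
print.coordination_rules <- function(x, ...) {
  cat("<coordination_rules>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-10s ", nm)); print(x[[nm]])
  }
  invisible(x)
}

#' Serialize curve parameter sets to and from JSON
#'
#' Flat key-value representation: each curve is keyed by name with fields
#' `a`, `x0`, `b` (sigmoid) or `slope`, `intercept` (line).
#'
#' @param rules A named list of `sigmoid_curve` / `linear_curve` objects.
#' @param path File path to write to / read from.
#' @return `write_curves()` returns `path` invisibly; `read_curves()` returns
#'   a named list of curve objects.
#' @export
write_curves <- function(rules, path) {
  stopifnot(is.list(rules), !is.null(names(rules)))
  out <- lapply(rules, function(crv) {
    if (inherits(crv, "sigmoid_curve")) {
      list(type = "sigmoid", a = crv$a, x0 = crv$x0, b = crv$b)
    } else if (inherits(crv, "linear_curve")) {
      list(type = "linear", slope = crv$slope, intercept = crv$intercept)
    } else stop("unknown curve type", call. = FALSE)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(raw, function(el) {
    if (identical(el$type, "sigmoid")) sigmoid_curve(el$a, el$x0, el$b)
    else if (identical(el$type, "linear")) linear_curve(el$slope, el$intercept)
    else stop("unknown curve type in file", call. = FALSE)
  })
  names(out) <- names(raw)
  out
}
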