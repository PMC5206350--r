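## Data-driven starting values for sigmoid fits: x0 from the first crossing
## of half the observed range, b from the central-quartile slope.
sigmoid_start <- function(x, y, a) {
  o <- order(x); x <- x[o]; y <- y[o]
  half <- min(y) + (max(y) - min(y)) / 2
  i <- which(y >= half)[1]
  x0 <- if (is.na(i) || i == 1L) stats::median(x) else {
    x[i - 1L] + (x[i] - x[i - 1L]) * (half - y[i - 1L]) / (y[i] - y[i - 1L])
  }
  mid <- y > 0.25 * a & y < 0.75 * a
  b <- if (sum(mid) >= 2L && diff(range(x[mid])) > 0) {
    sl <- stats::coef(stats::lm(y[mid] ~ x[mid]))[2]
    if (is.finite(sl) && sl > 0) a / (4 * sl) else diff(range(x)) / 4
  } else max(diff(range(x)) / 4, 1e-3)
  list(x0 = x0, b = max(b, 1e-3))
}

new_phyto_fit <- function(curve, fitted, y, n_par, converged, iterations, data) {
  ssr <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  structure(list(
    curve = curve,
    r_squared = if (sst > 0) max(0, 1 - ssr / sst) else NA_real_,
    residual_standard_error = sqrt(ssr / max(length(y) - n_par, 1L)),
    ssr = ssr, n_points = length(y),
    converged = converged, iterations = iterations,
    data = data
  ), class = "phyto_fit")
}

#' Fit a two-parameter logistic curve
#'
#' Least-squares fit of `y = 1 / {1 + exp[(x0 - x)/b]}` (amplitude fixed at
#' 1, as appropriate for fractions of final length) by Levenberg-Marquardt,
#' with `b` log-parameterized to stay positive.
#'
#' @param data A data frame of points.
#' @param x,y Columns holding abscissa and ordinate (bare names; defaults
#'   `x` and `y`).
#' @return An object of class `phyto_fit` holding the fitted
#'   [sigmoid_curve()], `r_squared`, `residual_standard_error`, `ssr`,
#'   `n_points`, `converged` and `iterations`. Use [tidy()] / [glance()] for
#'   tabular views.
#' @examples
#' pts <- data.frame(x = seq(-4, 12, 0.5))
#' pts$y <- eval_sigmoid(sigmoid_curve(1, 1.82, 1.81), pts$x)
#' fit_sigmoid2(pts)
#' @export
fit_sigmoid2 <- function(data, x = x, y = y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 4L) stop("need at least 4 points", call. = FALSE)
  if (stats::sd(yv) == 0) stop("non-convergence: constant ordinate", call. = FALSE)
  st <- sigmoid_start(xv, yv, 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yv ~ 1 / (1 + exp((x0 - xv) / exp(logb))),
      start = list(x0 = st$x0, logb = log(st$b)),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10, ptol = 1e-10)
    ),
    error = function(e) stop("non-convergence: ", conditionMessage(e), call. = FALSE)
  )
  cf <- stats::coef(fit)
  curve <- sigmoid_curve(1, cf[["x0"]], exp(cf[["logb"]]))
  new_phyto_fit(curve, stats::fitted(fit), yv, 2L,
                fit$convInfo$isConv %||% TRUE, fit$convInfo$finIter %||% NA_integer_,
                tibble::tibble(x = xv, y = yv))
}

#' Fit a three-parameter logistic curve
#'
#' As [fit_sigmoid2()] but with the amplitude `a` also estimated
#' (log-parameterized, initialized at 1.05 times the maximum ordinate).
#'
#' @inheritParams fit_sigmoid2
#' @return A `phyto_fit`.
#' @export
fit_sigmoid3 <- function(data, x = x, y = y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 5L) stop("need at least 5 points", call. = FALSE)
  if (stats::sd(yv) == 0) stop("non-convergence: constant ordinate", call. = FALSE)
  a0 <- 1.05 * max(yv)
  st <- sigmoid_start(xv, yv, a0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yv ~ exp(loga) / (1 + exp((x0 - xv) / exp(logb))),
      start = list(loga = log(a0), x0 = st$x0, logb = log(st$b)),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10, ptol = 1e-10)
    ),
    error = function(e) stop("non-convergence: ", conditionMessage(e), call. = FALSE)
  )
  cf <- stats::coef(fit)
  curve <- sigmoid_curve(exp(cf[["loga"]]), cf[["x0"]], exp(cf[["logb"]]))
  new_phyto_fit(curve, stats::fitted(fit), yv, 3L,
                fit$convInfo$isConv %||% TRUE, fit$convInfo$finIter %||% NA_integer_,
                tibble::tibble(x = xv, y = yv))
}

#' Fit a straight line
#'
#' Ordinary least squares, wrapped in the same fit-result container as the
#' sigmoid fits (used for the internode contribution).
#'
#' @inheritParams fit_sigmoid2
#' @return A `phyto_fit` holding a [linear_curve()].
#' @export
fit_linear <- function(data, x = x, y = y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(unique(xv)) < 2L) stop("need at least 2 distinct abscissa values", call. = FALSE)
  fit <- stats::lm(yv ~ xv)
  cf <- stats::coef(fit)
  curve <- linear_curve(unname(cf[2]), unname(cf[1]))
  new_phyto_fit(curve, stats::fitted(fit), yv, 2L, TRUE, 0L,
                tibble::tibble(x = xv, y = yv))
}

#' @export
print.phyto_fit <- function(x, ...) {
  cat("<phyto_fit>\n  ")
  print(x$curve)
  cat(sprintf("  R^2 = %.3f, RSE = %.4g, n = %d, converged: %s\n",
              x$r_squared, x$residual_standard_error, x$n_points, x$converged))
  invisible(x)
}

#' Tidy a phytomer curve fit
#'
#' @param x A `phyto_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter; `glance()`: one row of fit
#'   statistics.
#' @exportS3Method broom::tidy
tidy.phyto_fit <- function(x, ...) {
  crv <- x$curve
  if (inherits(crv, "sigmoid_curve")) {
    tibble::tibble(term = c("a", "x0", "b"),
                   estimate = c(crv$a, crv$x0, crv$b))
  } else {
    tibble::tibble(term = c("slope", "intercept"),
                   estimate = c(crv$slope, crv$intercept))
  }
}

#' @rdname tidy.phyto_fit
#' @exportS3Method broom::glance
glance.phyto_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared,
                 sigma = x$residual_standard_error,
                 ssr = x$ssr,
                 nobs = x$n_points,
                 converged = x$converged,
                 iterations = x$iterations)
}

#' Serialize a set of curve fits to a JSON report
#'
#' @param fits Named list of `phyto_fit` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fits, path) {
  out <- lapply(fits, function(ft) {
    pars <- as.list(stats::setNames(tidy(ft)$estimate, tidy(ft)$term))
    c(pars, list(r_squared = ft$r_squared,
                 residual_standard_error = ft$residual_standard_error,
                 n = ft$n_points, converged = ft$converged))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
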