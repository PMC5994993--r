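#' Reconstruct the insulin time series from glucose data
#'
#' A state observer for the unmeasured insulin: the copy of the insulin
#' equation driven by the measured glucose,
#' \deqn{d\hat I/dt = I_{max} G_{data}(t)^2/(\alpha + G_{data}(t)^2)
#'   - k_I \hat I,}
#' converges exponentially to the true insulin, because the error
#' \eqn{e \equiv I - \hat I} obeys \eqn{\dot e = -k_I e} whenever the data
#' equal the true glucose. The estimate therefore needs no knowledge of the
#' food intake at all; only the initial transient, with time constant
#' `1/kI`, is unreliable, and `3/kI` minutes is flagged as the horizon after
#' which the estimate can be trusted.
#'
#' Between samples the glucose record is interpolated with a monotone
#' piecewise cubic by default (no overshoot between 15-min samples); linear
#' interpolation is available. Gaps longer than `max_gap` minutes are not
#' silently interpolated: the record is split at each such gap and the
#' observer restarted, with a warning.
#'
#' @param data A [cgm_series()] (or any tibble with `time_min`, `glucose`).
#' @param params A [cgm_parameters()] bundle.
#' @param I0 Initial insulin estimate, uU/ml. Defaults to the bundle's
#'   laboratory fasting insulin `Iss`.
#' @param interp `"monotone"` (default) or `"linear"` interpolation of the
#'   glucose samples.
#' @param max_gap Largest tolerated sampling gap, minutes (default 60).
#' @param rtol,atol Integrator tolerances.
#' @return A tibble of class `cgm_observer` with columns `time_min`,
#'   `glucose`, `I_hat`, `in_transient` (logical: within `3/kI` of a window
#'   start) and `window`. The error time constant `1/kI` is stored in the
#'   `"transient_horizon"` attribute (minutes).
#' @export
#' @examples
#' day <- reference_day("non_diabetic")
#' obs <- insulin_observer(day$cgm_true, day$scenario$params)
#' head(obs)
insulin_observer <- function(data, params, I0 = NULL,
                             interp = c("monotone", "linear"),
                             max_gap = 60, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "cgm_parameters"))
  interp <- match.arg(interp)
  if (!all(c("time_min", "glucose") %in% names(data))) {
    abort("`data` must have columns `time_min` and `glucose`.")
  }
  if (nrow(data) < 2) abort("Need at least two glucose samples.")
  I0 <- I0 %||% params$Iss
  if (I0 < 0) abort("`I0` must be >= 0.")

  gaps <- diff(data$time_min)
  breaks <- which(gaps > max_gap)
  if (length(breaks)) {
    warn(sprintf(
      "%d gap(s) longer than %g min: observer restarted per window.",
      length(breaks), max_gap
    ))
  }
  win_id <- cumsum(c(1L, as.integer(seq_along(gaps) %in% breaks)))

  run_window <- function(df, w) {
    g_fun <- if (interp == "monotone") {
      splinefun(df$time_min, df$glucose, method = "monoH.FC")
    } else {
      approxfun(df$time_min, df$glucose, rule = 2)
    }
    rhs <- function(t, y, p) {
      G <- g_fun(t)
      list(params$Imax * G^2 / (params$alpha + G^2) - params$kI * y)
    }
    sol <- deSolve::ode(
      y = c(I_hat = I0), times = df$time_min, func = rhs, parms = NULL,
      method = "lsoda", rtol = rtol, atol = atol
    )
    horizon <- 3 / params$kI
    tibble(
      time_min = df$time_min, glucose = df$glucose,
      I_hat = unclass(sol)[, 2L],
      in_transient = df$time_min - df$time_min[1] < horizon,
      window = w
    )
  }

  out <- dplyr::bind_rows(lapply(unique(win_id), function(w) {
    run_window(as_tibble(data)[win_id == w, c("time_min", "glucose")], w)
  }))
  structure(out,
    class = c("cgm_observer", class(tibble())),
    transient_horizon = 1 / params$kI, params = params
  )
}

#' Reconstruct the rate of appearance of glucose due to food
#'
#' An input observer: given the glucose record and the observer's insulin
#' estimate, the glucose balance equation is inverted pointwise for the
#' exogenous forcing,
#' \deqn{R_a = dG_{data}/dt - R_0 + (E_{G0} + S_I \hat I)\, G_{data}.}
#' The derivative of the sampled record is taken from a smoothing-spline fit
#' (smoothing chosen by generalized cross-validation unless `spar` is
#' given), which suppresses the noise amplification of naive finite
#' differences. On fasting steady segments the reconstruction is zero up to
#' noise; after a meal it tracks the true gut outflow `kgut * qgut`.
#'
#' @param data A [cgm_series()].
#' @param insulin The matching [insulin_observer()] output (same grid).
#' @param params A [cgm_parameters()] bundle.
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()]; `NULL` (default) selects it by GCV.
#' @param use_smoothed Use the spline-smoothed glucose (default) or the raw
#'   samples in the algebraic part of the inversion.
#' @return A tibble of class `cgm_ra` with columns `time_min`, `glucose`,
#'   `I_hat`, `ra` (mg dl^-1 min^-1) and `edge` (logical: first/last two
#'   samples of a window, where the one-sided derivative is
#'   low-confidence). The spline's smoothing parameter is recorded in the
#'   `"smoothing"` attribute.
#' @export
#' @examples
#' day <- reference_day("non_diabetic")
#' obs <- insulin_observer(day$cgm_true, day$scenario$params)
#' ra <- ra_observer(day$cgm_true, obs, day$scenario$params)
ra_observer <- function(data, insulin, params, spar = NULL,
                        use_smoothed = TRUE) {
  stopifnot(inherits(params, "cgm_parameters"))
  if (!all(c("time_min", "glucose") %in% names(data))) {
    abort("`data` must have columns `time_min` and `glucose`.")
  }
  if (nrow(data) != nrow(insulin) ||
    max(abs(data$time_min - insulin$time_min)) > 1e-8) {
    abort("`insulin` must be aligned with `data` (same time grid).")
  }
  if (nrow(data) < 8) {
    abort("Too few samples for a stable smoothing-spline derivative (< 8).")
  }
  # all.knots: knot thinning would bias the derivative at sharp meal onsets
  fit <- if (is.null(spar)) {
    smooth.spline(data$time_min, data$glucose, cv = FALSE, all.knots = TRUE)
  } else {
    smooth.spline(data$time_min, data$glucose, spar = spar, all.knots = TRUE)
  }
  dG <- predict(fit, data$time_min, deriv = 1)$y
  g_level <- if (use_smoothed) {
    predict(fit, data$time_min)$y
  } else {
    data$glucose
  }
  ra <- dG - params$R0 + (params$EG0 + params$SI * insulin$I_hat) * g_level
  n <- nrow(data)
  win <- insulin$window %||% rep(1L, n)
  edge <- unlist(lapply(split(seq_len(n), win), function(idx) {
    k <- length(idx)
    seq_len(k) <= 2 | seq_len(k) > k - 2
  }), use.names = FALSE)
  structure(
    tibble(
      time_min = data$time_min, glucose = data$glucose,
      I_hat = insulin$I_hat, ra = ra, edge = edge
    ),
    class = c("cgm_ra", class(tibble())),
    smoothing = list(spar = fit$spar, lambda = fit$lambda, gcv = is.null(spar)),
    params = params
  )
}
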