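#' Power spectral density of a CGM record
#'
#' Multi-day CGM records carry a strong circadian rhythm, driven largely by
#' the day-to-day periodicity of food intake, visible as a dominant spectral
#' peak at a period of about 24 h. `psd_glucose()` estimates the spectrum
#' with a single-taper (Hann) periodogram whose normalisation is explicit:
#' with taper weights \eqn{w_j},
#' \deqn{P_k = \frac{\Delta t\, |\sum_j w_j x_j e^{-2\pi i jk/N}|^2}
#'   {N \sum_j w_j^2 / N},}
#' one-sided (positive frequencies doubled), so that
#' \eqn{\sum_k P_k \Delta f} matches the variance of the detrended series
#' (Parseval, up to taper-signal interaction).
#'
#' The series must be close to uniformly sampled: it is regridded to its
#' nominal cadence, with gaps up to `max_gap` minutes filled by linear
#' interpolation and longer gaps refused. The mean is removed before
#' tapering.
#'
#' @param data A [cgm_series()] spanning at least `min_days` days.
#' @param taper `"hann"` (default) or `"none"`.
#' @param max_gap Longest gap bridged by interpolation, minutes.
#' @param min_days Minimum record length required, days (default 2, below
#'   which the circadian band is unresolvable).
#' @return A tibble of class `cgm_spectrum` with columns
#'   `frequency_per_min` (cycles/min, positive frequencies only),
#'   `period_hours` and `power`. The frequency-bin width and sampling
#'   interval are stored as attributes `df_per_min` and `dt_min`.
#' @export
#' @examples
#' sc <- cgm_scenario(
#'   reference_parameters("non_diabetic"),
#'   tibble::tibble(clock_min = c(450, 780, 1200), amplitude = c(60, 150, 250),
#'     meal_class = "liquid"),
#'   n_days = 14, noise_cv = 0
#' )
#' spec <- psd_glucose(generate_cgm(sc)$cgm)
#' dominant_period(spec)
psd_glucose <- function(data, taper = c("hann", "none"), max_gap = 60,
                        min_days = 2) {
  taper <- match.arg(taper)
  if (!all(c("time_min", "glucose") %in% names(data))) {
    abort("`data` must have columns `time_min` and `glucose`.")
  }
  span <- diff(range(data$time_min))
  if (span < min_days * 1440) {
    abort(sprintf(
      "Record spans %.1f h; at least %g days are needed to resolve the circadian band.",
      span / 60, min_days
    ))
  }
  dt <- attr(data, "cadence_min") %||% median(diff(data$time_min))
  if (any(diff(data$time_min) > max_gap)) {
    abort(sprintf(
      "Sampling gap exceeds %g min; split the record at long gaps.", max_gap
    ))
  }
  grid <- seq(min(data$time_min), max(data$time_min), by = dt)
  x <- approx(data$time_min, data$glucose, xout = grid, rule = 2)$y
  x <- x - mean(x)
  n <- length(x)
  w <- if (taper == "hann") {
    0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  } else {
    rep(1, n)
  }
  X <- fft(w * x)
  # one-sided periodogram, power normalised by the taper's mean square
  kmax <- floor(n / 2)
  k <- seq_len(kmax)
  pw <- (abs(X[k + 1L])^2) * dt / (n * mean(w^2))
  two_sided_twin <- k < n / 2 # Nyquist bin (even n) has no mirror
  pw[two_sided_twin] <- 2 * pw[two_sided_twin]
  freq <- k / (n * dt)
  structure(
    tibble(
      frequency_per_min = freq,
      period_hours = 1 / freq / 60,
      power = pw
    ),
    class = c("cgm_spectrum", class(tibble())),
    df_per_min = 1 / (n * dt), dt_min = dt, n = n,
    variance = var(x) * (n - 1) / n, taper = taper
  )
}

#' Dominant spectral period within a band
#'
#' Locates the period of maximal power inside a band of periods (by default
#' 16-32 h, bracketing the circadian peak) and reports it together with its
#' resolution: the reported uncertainty is the local width of a frequency
#' bin converted to hours, the honest limit of a periodogram. A
#' peak-prominence ratio (peak power over the median power in the band)
#' below `prominence_threshold` flags series — e.g. white noise — whose
#' band maximum is not a real rhythm.
#'
#' @param spectrum A [psd_glucose()] result.
#' @param band_hours Length-2 numeric, the period band searched (hours).
#' @param prominence_threshold Ratio below which the peak is flagged
#'   non-prominent (default 10).
#' @return A one-row tibble: `period_hours`, `frequency_per_min`, `power`,
#'   `uncertainty_hours` (half bin width in period units), `prominence`
#'   and `prominent`.
#' @export
dominant_period <- function(spectrum, band_hours = c(16, 32),
                            prominence_threshold = 10) {
  stopifnot(inherits(spectrum, "cgm_spectrum"), length(band_hours) == 2)
  band_hours <- sort(band_hours)
  in_band <- spectrum$period_hours >= band_hours[1] &
    spectrum$period_hours <= band_hours[2]
  if (!any(in_band)) {
    abort("No resolved frequencies fall inside `band_hours`.")
  }
  sub <- spectrum[in_band, ]
  i <- which.max(sub$power)
  f <- sub$frequency_per_min[i]
  df <- attr(spectrum, "df_per_min")
  # bin width in period units at this frequency
  unc <- (1 / (f - df / 2) - 1 / (f + df / 2)) / 60 / 2
  prom <- sub$power[i] / median(sub$power)
  tibble(
    period_hours = sub$period_hours[i],
    frequency_per_min = f,
    power = sub$power[i],
    uncertainty_hours = unc,
    prominence = prom,
    prominent = prom >= prominence_threshold
  )
}
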