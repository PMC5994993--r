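#' Define a synthetic CGM scenario
#'
#' A scenario describes a virtual subject wearing a CGM sensor: a parameter
#' bundle, a daily meal schedule repeated for `n_days`, the sampling cadence
#' and a multiplicative sensor-noise level. Generated records emulate the
#' free-living setting the package targets — roughly two weeks of glucose
#' sampled every 15 minutes, with day-to-day periodicity driven by the meal
#' schedule.
#'
#' @param params A [cgm_parameters()] bundle.
#' @param schedule A tibble with columns `clock_min` (meal start, minutes
#'   after midnight, in `[0, 1440)`), `amplitude` and `meal_class`.
#' @param n_days Number of days to simulate.
#' @param sampling_interval CGM cadence in minutes (default 15).
#' @param noise_cv Coefficient of variation of multiplicative Gaussian
#'   sensor noise: observed glucose is `G * (1 + noise_cv * eps)` with
#'   `eps ~ N(0, 1)`. The default 0.05 is a conservative stand-in for
#'   reported sensor accuracy (a MARD around 11% mixes sensor and reference
#'   error).
#' @param meal_time_sd,meal_amp_cv Optional day-to-day jitter: SD of meal
#'   start times (min) and CV of amplitudes. Both 0 by default so fixtures
#'   are exact.
#' @param grid_step Dense simulation grid spacing, minutes; must divide
#'   `sampling_interval` so CGM samples lie exactly on the grid.
#' @return A list of class `cgm_scenario`.
#' @export
#' @examples
#' sc <- cgm_scenario(
#'   reference_parameters("non_diabetic"),
#'   schedule = tibble::tibble(
#'     clock_min = c(450, 780, 1200),
#'     amplitude = c(60, 150, 250),
#'     meal_class = c("liquid", "mixed", "mixed")
#'   ),
#'   n_days = 14
#' )
cgm_scenario <- function(params, schedule, n_days = 14,
                         sampling_interval = 15, noise_cv = 0.05,
                         meal_time_sd = 0, meal_amp_cv = 0, grid_step = 5) {
  stopifnot(inherits(params, "cgm_parameters"))
  if (!all(c("clock_min", "amplitude", "meal_class") %in% names(schedule))) {
    abort("`schedule` needs columns clock_min, amplitude, meal_class.")
  }
  if (any(schedule$clock_min < 0 | schedule$clock_min >= 1440)) {
    abort("`clock_min` must lie in [0, 1440).")
  }
  if (sampling_interval <= 0) abort("`sampling_interval` must be > 0.")
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.")
  if (sampling_interval %% grid_step != 0) {
    abort("`grid_step` must divide `sampling_interval`.")
  }
  structure(
    list(
      params = params, schedule = as_tibble(schedule), n_days = n_days,
      sampling_interval = sampling_interval, noise_cv = noise_cv,
      meal_time_sd = meal_time_sd, meal_amp_cv = meal_amp_cv,
      grid_step = grid_step
    ),
    class = "cgm_scenario"
  )
}

#' Generate a synthetic CGM record with full ground truth
#'
#' Repeats the scenario's daily meal schedule for `n_days`, simulates the
#' model on a dense grid, samples glucose at the CGM cadence and applies
#' seeded multiplicative sensor noise. Because the truth (dense trajectory,
#' insulin, rate of appearance, meal list) is returned alongside the noisy
#' record, generated data can validate fitting and the observers in a way
#' patient records never can.
#'
#' @param scenario A [cgm_scenario()].
#' @param seed Integer seed for the noise draw (and meal jitter, if any).
#'   The RNG state of the session is left untouched.
#' @return A list of class `cgm_truth` with elements `cgm` (noisy
#'   [cgm_series()]), `cgm_true` (noiseless series on the same timestamps),
#'   `trajectory` (dense [simulate_glucose()] output incl. insulin and
#'   `ra`), `meals` (the realised [meal_events()]), `diary` (tibble view of
#'   the meals) and `scenario`.
#' @export
generate_cgm <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "cgm_scenario"))
  sc <- scenario
  t_end <- sc$n_days * 1440

  realise <- function() {
    day <- rep(seq_len(sc$n_days) - 1L, each = nrow(sc$schedule))
    times <- day * 1440 + rep(sc$schedule$clock_min, sc$n_days)
    amps <- rep(sc$schedule$amplitude, sc$n_days)
    if (sc$meal_time_sd > 0) {
      times <- times + rnorm(length(times), 0, sc$meal_time_sd)
      times <- pmin(pmax(times, 0), t_end)
    }
    if (sc$meal_amp_cv > 0) {
      amps <- amps * pmax(1 + sc$meal_amp_cv * rnorm(length(amps)), 0)
    }
    meal_events(times, amps, rep(sc$schedule$meal_class, sc$n_days))
  }

  withr::with_seed(seed, {
    meals <- realise()
    traj <- simulate_glucose(sc$params, meals,
      t_end = t_end, grid_step = sc$grid_step
    )
    t_cgm <- seq(0, t_end - sc$sampling_interval, by = sc$sampling_interval)
    truth <- sample_trajectory(traj, t_cgm)
    eps <- rnorm(length(t_cgm))
    g_obs <- truth$G * (1 + sc$noise_cv * eps)
  })

  list2 <- list(
    cgm = cgm_series(t_cgm, pmax(g_obs, 1e-6), source = "synthetic"),
    cgm_true = cgm_series(t_cgm, truth$G, source = "synthetic"),
    trajectory = traj,
    meals = meals,
    diary = tibble(
      time_min = meals$time_min, meal_class = meals$meal_class,
      label = meals$label
    ),
    scenario = sc,
    seed = seed
  )
  structure(list2, class = "cgm_truth")
}

#' @export
print.cgm_truth <- function(x, ...) {
  cat(sprintf(
    "<cgm_truth> %d days, %d CGM samples (%g-min cadence), %d meals, CV %g\n",
    x$scenario$n_days, nrow(x$cgm), x$scenario$sampling_interval,
    nrow(x$meals), x$scenario$noise_cv
  ))
  invisible(x)
}

#' Canonical single-day fixtures for the two reference subjects
#'
#' Builds the documented one-day scenarios that accompany the reference
#' parameter bundles: the non-diabetic day has a liquid breakfast at 450 min
#' (amplitude 50) and two mixed meals at 1051 and 1260 min (amplitudes 177
#' and 316); the diabetic day has a single isolated liquid meal at 1200 min
#' (amplitude 230). Generated noiseless by default so the fixtures are exact
#' regression anchors.
#'
#' @param case `"non_diabetic"` or `"diabetic"`.
#' @param noise_cv Sensor-noise CV (default 0: noiseless fixture).
#' @param seed Seed passed to [generate_cgm()].
#' @return A `cgm_truth` bundle (see [generate_cgm()]).
#' @export
#' @examples
#' day <- reference_day("non_diabetic")
#' range(day$trajectory$I) # insulin stays in the physiological band
reference_day <- function(case = c("non_diabetic", "diabetic"),
                          noise_cv = 0, seed = 1L) {
  case <- match.arg(case)
  params <- reference_parameters(case)
  schedule <- if (case == "non_diabetic") {
    tibble(
      clock_min = c(450, 1051, 1260),
      amplitude = c(50, 177, 316),
      meal_class = c("liquid", "mixed", "mixed")
    )
  } else {
    tibble(clock_min = 1200, amplitude = 230, meal_class = "liquid")
  }
  sc <- cgm_scenario(params, schedule,
    n_days = 1, sampling_interval = 15,
    noise_cv = noise_cv, grid_step = 1
  )
  generate_cgm(sc, seed = seed)
}
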