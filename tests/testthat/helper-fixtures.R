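# Shared fixtures: parameter bundles and small synthetic scenarios built in
# code at test time.

nd_params <- function() reference_parameters("non_diabetic")
dia_params <- function() reference_parameters("diabetic")

# One-day, one-liquid-meal scenario (the landmark-pulse setting).
liquid_pulse_truth <- function(amplitude = 50, t_meal = 450,
                               sampling_interval = 15, noise_cv = 0,
                               seed = 1L, grid_step = 1) {
  sc <- cgm_scenario(
    nd_params(),
    tibble::tibble(
      clock_min = t_meal, amplitude = amplitude, meal_class = "liquid"
    ),
    n_days = 1, sampling_interval = sampling_interval,
    noise_cv = noise_cv, grid_step = grid_step
  )
  generate_cgm(sc, seed = seed)
}

# Three-meals-a-day schedule used for multi-day records.
daily_schedule <- function() {
  tibble::tibble(
    clock_min = c(450, 780, 1200),
    amplitude = c(60, 150, 250),
    meal_class = c("liquid", "mixed", "mixed")
  )
}

# Closed-form solution of the linear stomach/gut cascade after a single
# impulse A at t = 0 (independent oracle for the simulated compartments).
cascade_closed_form <- function(t, A, ksto, kgut) {
  qsto <- A * exp(-ksto * t)
  qgut <- A * ksto * (exp(-kgut * t) - exp(-ksto * t)) / (ksto - kgut)
  list(qsto = qsto, qgut = qgut)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
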