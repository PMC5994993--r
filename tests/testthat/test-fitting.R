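test_that("the cost is zero at the generating truth and obeys exact identities", {
  tb <- liquid_pulse_truth()
  p <- tb$scenario$params
  seg <- dplyr::filter(tibble::as_tibble(tb$cgm_true),
    time_min >= 300, time_min <= 900)
  data <- cgm_series(seg$time_min, seg$glucose, source = "synthetic")
  meals <- meal_events(450, 50, "liquid")

  c0 <- fit_cost(data, meals, p)
  expect_lt(c0, 1e-10)

  # constant offset: cost = c^2 * n under unit weights
  off <- 3
  data_off <- cgm_series(seg$time_min, seg$glucose + off,
    source = "synthetic")
  c_off <- fit_cost(data_off, meals, p)
  expect_equal(c_off, off^2 * nrow(seg), tolerance = 1e-6)

  # doubling one sample's weight adds exactly w * residual^2
  w <- rep(1, nrow(seg))
  j <- 25
  c1 <- fit_cost(data_off, meals, p, weights = w)
  w[j] <- 2
  c2 <- fit_cost(data_off, meals, p, weights = w)
  sim <- cgmpulse:::segment_simulation(data_off, meals, p)
  expect_equal(c2 - c1, (data_off$glucose[j] - sim$G[j])^2,
    tolerance = 1e-8)
})

test_that("a segment with no diary meals is refused", {
  tb <- liquid_pulse_truth()
  data <- tb$cgm_true
  expect_error(
    fit_segment(data, meal_events(numeric(), numeric()), nd_params()),
    "at least one"
  )
})

test_that("non-identifiable parameters cannot be freed", {
  tb <- liquid_pulse_truth()
  m <- meal_events(450, 50, "liquid")
  expect_error(
    fit_segment(tb$cgm_true, m, nd_params(), free = c("EG0", "SI")),
    "not identifiable"
  )
  expect_error(
    fit_segment(tb$cgm_true, m, nd_params(), free = "alpha"),
    "not identifiable"
  )
  expect_error(
    fit_segment(tb$cgm_true, m, dia_params(), free = "kgut_mixed"),
    "kgut_mixed"
  )
})

test_that("fitting tracks kI, improves on the start and is seed-deterministic", {
  tb <- liquid_pulse_truth()
  p <- tb$scenario$params
  seg <- dplyr::filter(tibble::as_tibble(tb$cgm_true),
    time_min >= 300, time_min <= 900)
  data <- cgm_series(seg$time_min, seg$glucose, source = "synthetic")
  start <- cgm_parameters(
    R0 = p$R0, EG0 = p$EG0, SI = p$SI * 1.4, alpha = p$alpha,
    Imax = p$Imax * 0.7, ksto = p$ksto, kgut_liquid = p$kgut_liquid,
    kgut_mixed = p$kgut_mixed, Gss = p$Gss, Iss = p$Iss
  )
  ctrl <- list(outer = 2L, hj_evals = 250L, rtol = 1e-6, atol = 1e-8)
  fit <- fit_segment(data, meal_events(450, 70, "liquid"), start,
    free = c("SI", "Imax"), seed = 7, control = ctrl
  )
  # kI tracks Imax through the steady-state identity, exactly
  expect_identical(
    fit$params$kI,
    infer_ki(fit$params$Imax, fit$params$alpha, fit$params$Gss,
      fit$params$Iss)
  )
  # monotone improvement over the starting point
  expect_lte(fit$cost, fit$cost_initial)
  # identical seed and problem give a bit-identical result
  fit2 <- fit_segment(data, meal_events(450, 70, "liquid"), start,
    free = c("SI", "Imax"), seed = 7, control = ctrl
  )
  expect_identical(tidy(fit), tidy(fit2))
  expect_identical(glance(fit), glance(fit2))
  # tidy/glance expose the fit in broom style
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "fixed") %in% names(td)))
  expect_false(td$fixed[td$term == "SI"])
  expect_true(td$fixed[td$term == "EG0"])
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("noisy replicate fits recover amplitudes with small bias", {
  p <- nd_params()
  truth_amp <- 50
  est <- purrr::map_dbl(1:8, function(r) {
    tb <- liquid_pulse_truth(noise_cv = 0.05, seed = 100 + r, grid_step = 5)
    seg <- dplyr::filter(tibble::as_tibble(tb$cgm), time_min >= 300,
      time_min <= 900)
    data <- cgm_series(seg$time_min, seg$glucose, source = "synthetic")
    fit <- fit_segment(data, meal_events(450, 70, "liquid"), p,
      free = c("SI", "Imax"), seed = r,
      control = list(outer = 2L, hj_evals = 200L, rtol = 1e-6, atol = 1e-8)
    )
    fit$meals$amplitude
  })
  bias <- abs(mean(est) - truth_amp) / truth_amp
  expect_lt(bias, 0.1)
})

test_that("night-segment decay fitting recovers the insulin-independent clearance", {
  eg0 <- 2.5e-3
  g_inf <- 150
  t <- seq(0, 420, by = 15)
  g <- g_inf + (230 - g_inf) * exp(-eg0 * t)
  est <- estimate_eg0_night(cgm_series(t, g, source = "synthetic"))
  expect_lt(abs(est$EG0 - eg0) / eg0, 0.02)

  # independent log-linear oracle on the shifted series (known plateau)
  k_ll <- -unname(coef(lm(log(g - g_inf) ~ t))[2])
  expect_lt(abs(est$EG0 - k_ll) / k_ll, 0.01)
})

test_that("non-decaying night segments are rejected", {
  t <- seq(0, 300, by = 15)
  expect_error(
    estimate_eg0_night(cgm_series(t, rep(120, length(t)),
      source = "synthetic")),
    "decay"
  )
  expect_error(
    estimate_eg0_night(cgm_series(t, 100 + 0.1 * t, source = "synthetic")),
    "decay"
  )
  expect_error(
    estimate_eg0_night(cgm_series(t[1:4], c(120, 118, 117, 116),
      source = "synthetic")),
    "6 samples"
  )
})
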