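test_that("the observer is invariant at the matching equilibrium", {
  p <- nd_params()
  ss <- fasting_steady_state(p)
  t <- seq(0, 1440, by = 15)
  data <- cgm_series(t, rep(ss$G_star, length(t)), source = "synthetic")
  obs <- insulin_observer(data, p, I0 = ss$I_star)
  expect_lt(diff(range(obs$I_hat)) / ss$I_star, 1e-8)
})

test_that("the observer error decays exactly like exp(-kI t)", {
  tb <- liquid_pulse_truth(sampling_interval = 1) # dense, noiseless record
  p <- tb$scenario$params
  traj <- tb$trajectory
  I_true <- traj$I[match(tb$cgm_true$time_min, traj$time_min)]
  e0 <- 4
  obs <- insulin_observer(tb$cgm_true, p, I0 = I_true[1] + e0)
  err <- obs$I_hat - I_true
  expected <- e0 * exp(-p$kI * (obs$time_min - obs$time_min[1]))
  expect_lt(max(abs(err - expected)), 1e-4)
})

test_that("with the laboratory-anchor initialization the estimate converges to the truth", {
  tb <- liquid_pulse_truth(sampling_interval = 1)
  p <- tb$scenario$params
  traj <- tb$trajectory
  I_true <- traj$I[match(tb$cgm_true$time_min, traj$time_min)]
  obs <- insulin_observer(tb$cgm_true, p) # I0 = Iss
  rel <- abs(obs$I_hat - I_true) / I_true
  # the ~33% initial mismatch between the laboratory anchor and the model's
  # resting insulin decays at rate kI: ~2% three time constants in, below
  # 1% from four onward
  expect_lt(max(rel[obs$time_min > 3 / p$kI]), 0.02)
  expect_lt(max(rel[obs$time_min > 4 / p$kI]), 0.01)
})

test_that("two initializations contract toward each other at rate kI", {
  tb <- liquid_pulse_truth()
  p <- tb$scenario$params
  a <- insulin_observer(tb$cgm_true, p, I0 = 2)
  b <- insulin_observer(tb$cgm_true, p, I0 = 14)
  gap <- b$I_hat - a$I_hat
  expected <- 12 * exp(-p$kI * (a$time_min - a$time_min[1]))
  # exact linear error dynamics, at integrator accuracy on the scale of the
  # initial gap (the gap itself decays below round-off over the record)
  expect_lt(max(abs(gap - expected)) / 12, 1e-6)
})

test_that("insulin excursions peak after the glucose peaks", {
  day <- reference_day("non_diabetic")
  obs <- insulin_observer(day$cgm_true, day$scenario$params)
  # first (liquid breakfast) excursion
  win <- obs$time_min >= 450 & obs$time_min <= 900
  t_g <- obs$time_min[win][which.max(obs$glucose[win])]
  t_i <- obs$time_min[win][which.max(obs$I_hat[win])]
  expect_gt(t_i, t_g)
})

test_that("long sampling gaps split the record instead of silent interpolation", {
  p <- nd_params()
  t <- c(seq(0, 300, by = 15), seq(500, 800, by = 15))
  data <- cgm_series(t, rep(70, length(t)), source = "synthetic")
  expect_warning(obs <- insulin_observer(data, p), "gap")
  expect_equal(sort(unique(obs$window)), c(1L, 2L))
})

test_that("the reconstructed rate of appearance vanishes on fasting data", {
  p <- nd_params()
  ss <- fasting_steady_state(p)
  t <- seq(0, 1440, by = 15)
  data <- cgm_series(t, rep(ss$G_star, length(t)), source = "synthetic")
  obs <- insulin_observer(data, p, I0 = ss$I_star)
  ra <- ra_observer(data, obs, p)
  expect_lt(max(abs(ra$ra)), 1e-2)
})

test_that("the input observer recovers the true forcing on noiseless data", {
  # 2-min cadence resolves the onset kink that limits spline derivatives
  tb <- liquid_pulse_truth(sampling_interval = 2)
  p <- tb$scenario$params
  ss <- fasting_steady_state(p)
  obs <- insulin_observer(tb$cgm_true, p, I0 = ss$I_star)
  ra <- ra_observer(tb$cgm_true, obs, p)
  truth <- tb$trajectory$ra[match(ra$time_min, tb$trajectory$time_min)]
  keep <- !ra$edge
  l2 <- sqrt(sum((ra$ra - truth)[keep]^2) / sum(truth[keep]^2))
  expect_lt(l2, 0.05)

  # mass conservation: the integral of Ra over the record returns the meal
  integ <- sum(diff(ra$time_min) * (head(ra$ra, -1) + tail(ra$ra, -1)) / 2)
  expect_lt(abs(integ - 50) / 50, 0.05)
})

test_that("spline smoothing beats raw finite differences under sensor noise", {
  tb <- liquid_pulse_truth(noise_cv = 0.05, seed = 3)
  p <- tb$scenario$params
  ss <- fasting_steady_state(p)
  obs <- insulin_observer(tb$cgm, p, I0 = ss$I_star)
  ra <- ra_observer(tb$cgm, obs, p)
  truth <- tb$trajectory$ra[match(ra$time_min, tb$trajectory$time_min)]

  # naive central differences on the noisy samples
  g <- tb$cgm$glucose
  t <- tb$cgm$time_min
  dG_fd <- c(NA, (g[-(1:2)] - g[1:(length(g) - 2)]) /
    (t[-(1:2)] - t[1:(length(t) - 2)]), NA)
  ra_fd <- dG_fd - p$R0 + (p$EG0 + p$SI * obs$I_hat) * g

  keep <- !ra$edge & !is.na(ra_fd)
  err_spline <- sum((ra$ra - truth)[keep]^2)
  err_fd <- sum((ra_fd - truth)[keep]^2)
  expect_lt(err_spline, err_fd)
})

test_that("too-short records are refused by the input observer", {
  p <- nd_params()
  t <- seq(0, 60, by = 15)
  data <- cgm_series(t, rep(70, 5), source = "synthetic")
  obs_ok <- insulin_observer(cgm_series(seq(0, 200, 15),
    rep(70, 14), source = "synthetic"), p)
  expect_error(
    ra_observer(data, obs_ok[1:5, ], p),
    "Too few samples"
  )
})
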