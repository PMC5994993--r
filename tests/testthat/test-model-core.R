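test_that("food cascade right-hand side matches its defining rates", {
  p <- nd_params()
  # empty system is at rest
  expect_equal(
    unname(food_rhs(c(qsto = 0, qgut = 0), p, "liquid")), c(0, 0)
  )
  # a full stomach empties at ksto and feeds the gut one-to-one
  d <- food_rhs(c(qsto = 100, qgut = 0), p, "liquid")
  expect_equal(unname(d), c(-3.6, 3.6))
  # meal class switches the gut rate
  d_l <- food_rhs(c(qsto = 0, qgut = 10), p, "liquid")
  d_m <- food_rhs(c(qsto = 0, qgut = 10), p, "mixed")
  expect_equal(d_l[["dqgut"]], -10 * p$kgut_liquid)
  expect_equal(d_m[["dqgut"]], -10 * p$kgut_mixed)
})

test_that("a mixed meal without a mixed-meal rate is a configuration error", {
  p <- dia_params()
  expect_null(p$kgut_mixed)
  expect_error(
    food_rhs(c(qsto = 1, qgut = 0), p, "mixed"),
    "kgut_mixed"
  )
  expect_error(
    simulate_glucose(p, meal_events(100, 50, "mixed"), t_end = 500),
    "kgut_mixed"
  )
})

test_that("glucose-insulin right-hand side encodes production, clearance and secretion", {
  p <- nd_params()
  # at the origin only basal production acts
  d0 <- glucose_insulin_rhs(c(qgut = 0, G = 0, I = 0), p)
  expect_equal(unname(d0), c(p$R0, 0))
  # secretion term at the laboratory fasting glucose
  d <- glucose_insulin_rhs(c(qgut = 0, G = 90, I = 0), p)
  expect_equal(d[["dI"]], 0.28 * 8100 / 18100)
  # the solved fasting state is an equilibrium of both equations
  ss <- fasting_steady_state(p)
  deq <- glucose_insulin_rhs(c(qgut = 0, G = ss$G_star, I = ss$I_star), p)
  expect_lt(max(abs(deq)), 1e-8)
})

test_that("simulated cascade matches the closed-form exponentials", {
  p <- nd_params()
  A <- 75
  traj <- simulate_glucose(p, meal_events(0, A, "liquid"),
    t_end = 400, grid_step = 1,
    init = c(qsto = 0, qgut = 0, G = 70, I = 9)
  )
  probe <- seq(40, 400, by = 40) # 10 time points past the impulse
  sim <- traj[match(probe, traj$time_min), ]
  cf <- cascade_closed_form(probe, A, p$ksto, p$kgut_liquid)
  expect_rel_equal(sim$qsto, cf$qsto, 1e-6)
  expect_rel_equal(sim$qgut, cf$qgut, 1e-6)
})

test_that("a meal-free run started at equilibrium stays there", {
  p <- nd_params()
  traj <- simulate_glucose(p, t_end = 2000, grid_step = 10)
  expect_lt(diff(range(traj$G)) / traj$G[1], 1e-6)
  expect_lt(diff(range(traj$I)) / traj$I[1], 1e-6)
})

test_that("cumulative glucose appearance equals the meal amplitudes (mass conservation)", {
  p <- nd_params()
  meals <- meal_events(
    c(100, 300, 500), c(50, 120, 80), c("liquid", "liquid", "mixed")
  )
  traj <- simulate_glucose(p, meals, t_end = 4000, grid_step = 1)
  absorbed <- sum(diff(traj$time_min) *
    (head(traj$ra, -1) + tail(traj$ra, -1)) / 2)
  expect_lt(abs(absorbed - sum(meals$amplitude)) / sum(meals$amplitude),
    0.001)
})

test_that("states stay non-negative and insulin stays below its secretion ceiling", {
  p <- nd_params()
  set.seed(11)
  for (rep in 1:4) {
    n <- sample(1:4, 1)
    meals <- meal_events(
      sort(runif(n, 0, 1200)), runif(n, 10, 300),
      sample(c("liquid", "mixed"), n, replace = TRUE)
    )
    I0 <- runif(1, 0, 30)
    traj <- simulate_glucose(p, meals,
      t_end = 1500,
      init = c(qsto = 0, qgut = 0, G = runif(1, 50, 200), I = I0)
    )
    expect_gt(min(traj$qsto, traj$qgut, traj$G, traj$I), -1e-8)
    expect_lte(max(traj$I), max(I0, p$Imax / p$kI) * (1 + 1e-8))
  }
})

test_that("glucose relaxes from the laboratory fasting point toward the model's resting value", {
  p <- nd_params()
  traj <- simulate_glucose(p,
    t_end = 3000, grid_step = 10,
    init = c(qsto = 0, qgut = 0, G = 90, I = 12.4)
  )
  G_final <- tail(traj$G, 1)
  expect_lt(abs(G_final - 70) / 70, 0.1)
})

test_that("trajectories export as tidy tables with exact meal-time grid points", {
  p <- nd_params()
  meals <- meal_events(c(447.5, 1051), c(50, 177), c("liquid", "mixed"))
  traj <- simulate_glucose(p, meals, t_end = 1440, grid_step = 5)
  expect_true(all(c("time_min", "qsto", "qgut", "G", "I", "ra") %in%
    names(traj)))
  expect_true(all(meals$time_min %in% traj$time_min))
  expect_true(!is.unsorted(traj$time_min, strictly = TRUE))
})
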