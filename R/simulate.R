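#' Right-hand side of the two-compartment food cascade
#'
#' Food enters the stomach compartment and is passed to the gut, from which
#' glucose is assimilated into the bloodstream:
#' \deqn{dq_{sto}/dt = -k_{sto} q_{sto}, \qquad
#'       dq_{gut}/dt = k_{sto} q_{sto} - k_{gut} q_{gut}.}
#'
#' @param state Named numeric vector or list with components `qsto`, `qgut`.
#' @param params A [cgm_parameters()] bundle.
#' @param meal_class `"liquid"` or `"mixed"`; selects the `kgut` rate.
#' @return Named numeric vector `c(dqsto, dqgut)`.
#' @export
#' @examples
#' p <- reference_parameters("non_diabetic")
#' food_rhs(c(qsto = 100, qgut = 0), p, "liquid")
food_rhs <- function(state, params, meal_class = c("liquid", "mixed")) {
  meal_class <- match.arg(meal_class)
  kgut <- kgut_for_class(params, meal_class)
  qsto <- state[["qsto"]]
  qgut <- state[["qgut"]]
  c(
    dqsto = -params$ksto * qsto,
    dqgut = params$ksto * qsto - kgut * qgut
  )
}

#' Right-hand side of the glucose-insulin subsystem
#'
#' The fast glucose-insulin core: hepatic production, insulin-independent
#' and insulin-dependent clearance, gut absorption, sigmoidal insulin
#' secretion and first-order insulin clearance:
#' \deqn{dG/dt = R_0 - (E_{G0} + S_I I) G + k_{gut} q_{gut},}
#' \deqn{dI/dt = I_{max} G^2/(\alpha + G^2) - k_I I.}
#'
#' @param state Named numeric vector or list with components `qgut`, `G`,
#'   `I`.
#' @inheritParams food_rhs
#' @return Named numeric vector `c(dG, dI)`.
#' @export
glucose_insulin_rhs <- function(state, params,
                                meal_class = c("liquid", "mixed")) {
  meal_class <- match.arg(meal_class)
  kgut <- kgut_for_class(params, meal_class)
  G <- state[["G"]]
  I <- state[["I"]]
  qgut <- state[["qgut"]]
  c(
    dG = params$R0 - (params$EG0 + params$SI * I) * G + kgut * qgut,
    dI = params$Imax * G^2 / (params$alpha + G^2) - params$kI * I
  )
}

#' Simulate the minimal model forward under impulsive meal inputs
#'
#' Integrates the coupled food/glucose-insulin system on a dense grid. Meals
#' are state resets: at each meal time the stomach content jumps by the meal
#' amplitude and integration restarts, rather than being represented by a
#' stiff forcing spike. Internally each meal is carried in its own linear
#' stomach/gut cascade (so liquid and mixed meals with different absorption
#' rates can coexist in one window); the reported `qsto` and `qgut` columns
#' are the sums over meals and `ra = sum(kgut_i * qgut_i)` is the total rate
#' of appearance of glucose due to food.
#'
#' Integration uses an adaptive solver (`deSolve::ode`, lsoda) with tight
#' tolerances (`rtol = 1e-8`, `atol = 1e-10` by default) so that the linear
#' food cascade matches its closed-form exponential solution to high
#' accuracy.
#'
#' @param params A [cgm_parameters()] bundle.
#' @param meals A [meal_events()] table (may be empty).
#' @param t_end End of the simulation window, minutes.
#' @param t_start Start of the window, minutes (default 0).
#' @param grid_step Output grid spacing, minutes.
#' @param init Optional named vector `c(qsto, qgut, G, I)` of initial
#'   values. Defaults to the fasting steady state with empty gut. A nonzero
#'   initial gut load is integrated with the liquid-meal absorption rate.
#' @param rtol,atol Relative/absolute integrator tolerances.
#' @param extra_times Additional output times merged into the grid (e.g. the
#'   exact timestamps of a CGM record).
#' @return A tibble of class `cgm_trajectory` with columns `time_min`,
#'   `qsto`, `qgut`, `G`, `I`, `ra`. Meal times are carried in the
#'   `"meals"` attribute.
#' @export
#' @examples
#' p <- reference_parameters("non_diabetic")
#' day <- meal_events(c(450, 1051, 1260), c(50, 177, 316),
#'   c("liquid", "mixed", "mixed"))
#' traj <- simulate_glucose(p, day, t_end = 1440)
#' head(traj)
simulate_glucose <- function(params, meals = meal_events(numeric(), numeric()),
                             t_end, t_start = 0, grid_step = 1, init = NULL,
                             rtol = 1e-8, atol = 1e-10, extra_times = NULL) {
  stopifnot(inherits(params, "cgm_parameters"))
  if (!inherits(meals, "cgm_meals")) {
    abort("`meals` must be built with `meal_events()`.")
  }
  if (grid_step <= 0) abort("`grid_step` must be > 0.")
  if (t_end <= t_start) abort("`t_end` must exceed `t_start`.")
  if (nrow(meals) > 0 &&
    (min(meals$time_min) < t_start || max(meals$time_min) > t_end)) {
    abort("All meal times must lie within [t_start, t_end].")
  }

  if (is.null(init)) {
    ss <- fasting_steady_state(params)
    init <- c(qsto = 0, qgut = 0, G = ss$G_star, I = ss$I_star)
  } else {
    init <- init[c("qsto", "qgut", "G", "I")]
    if (any(is.na(init))) abort("`init` must name qsto, qgut, G and I.")
    if (any(init < 0)) abort("Initial state components must be >= 0.")
  }

  # One (qsto, qgut) cascade per meal, plus cascade 0 for any initial load.
  n_meal <- nrow(meals)
  kguts <- c(
    params$kgut_liquid,
    if (n_meal) vapply(meals$meal_class, kgut_for_class,
      numeric(1),
      params = params
    ) else numeric()
  )
  n_casc <- length(kguts)
  y0 <- c(
    as.numeric(rbind(
      c(init[["qsto"]], rep(0, n_meal)),
      c(init[["qgut"]], rep(0, n_meal))
    )),
    init[["G"]], init[["I"]]
  )
  iG <- 2L * n_casc + 1L
  iI <- iG + 1L
  names(y0) <- c(
    paste0(rep(c("qsto", "qgut"), n_casc), rep(seq_len(n_casc), each = 2L)),
    "G", "I"
  )

  odd <- seq(1L, 2L * n_casc, by = 2L)
  even <- odd + 1L
  ksto <- params$ksto
  R0 <- params$R0
  EG0 <- params$EG0
  SI <- params$SI
  Imax <- params$Imax
  alpha <- params$alpha
  kI <- params$kI
  ny <- 2L * n_casc + 2L
  rhs <- function(t, y, parms) {
    qsto <- y[odd]
    qgut <- y[even]
    G <- y[iG]
    I <- y[iI]
    dy <- numeric(ny)
    dy[odd] <- -ksto * qsto
    dy[even] <- ksto * qsto - kguts * qgut
    dy[iG] <- R0 - (EG0 + SI * I) * G + sum(kguts * qgut)
    dy[iI] <- Imax * G^2 / (alpha + G^2) - kI * I
    list(dy)
  }

  times <- sort(unique(c(seq(t_start, t_end, by = grid_step), t_end,
    meals$time_min, extra_times)))
  events <- NULL
  if (n_meal > 0) {
    events <- list(data = data.frame(
      var = paste0("qsto", seq_len(n_meal) + 1L), # cascade 1 = initial load
      time = meals$time_min,
      value = meals$amplitude,
      method = "add"
    ))
  }

  sol <- tryCatch(
    deSolve::ode(
      y = y0, times = times, func = rhs, parms = NULL, method = "lsoda",
      rtol = rtol, atol = atol, events = events, maxsteps = 50000
    ),
    warning = function(w) {
      abort(sprintf(
        "ODE integration failed on [%g, %g]: %s",
        t_start, t_end, conditionMessage(w)
      ))
    }
  )
  sol <- unclass(sol)
  qsto_cols <- 1L + seq(1L, 2L * n_casc, by = 2L)
  qgut_cols <- 1L + seq(2L, 2L * n_casc, by = 2L)
  qgut_mat <- sol[, qgut_cols, drop = FALSE]
  out <- tibble(
    time_min = sol[, 1L],
    qsto = rowSums(sol[, qsto_cols, drop = FALSE]),
    qgut = rowSums(qgut_mat),
    G = sol[, iG + 1L],
    I = sol[, iI + 1L],
    ra = as.numeric(qgut_mat %*% kguts)
  )
  structure(out,
    class = c("cgm_trajectory", class(tibble())),
    params = params, meals = meals
  )
}

#' @export
print.cgm_trajectory <- function(x, ...) {
  meals <- attr(x, "meals")
  cat(sprintf(
    "<cgm_trajectory> %d points over [%g, %g] min, %d meal(s)\n",
    nrow(x), min(x$time_min), max(x$time_min),
    if (is.null(meals)) 0L else nrow(meals)
  ))
  NextMethod()
}

# Pull rows of a trajectory at requested times; times must lie on the grid.
sample_trajectory <- function(traj, at) {
  idx <- match(round(at, 9), round(traj$time_min, 9))
  if (anyNA(idx)) {
    abort("Requested sample times are not on the trajectory grid.")
  }
  traj[idx, , drop = FALSE]
}
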