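#' Weighted least-squares cost of a candidate personalization
#'
#' Simulates the model over the data window, samples the simulated glucose
#' at the exact data timestamps and returns the weighted sum of squared
#' residuals \eqn{\sum_j w_j (G_{data,j} - G_{sim,j})^2}. Weights allow the
#' landmark liquid-meal pulse to be weighted relatively heavily, which is
#' what anchors the personalization.
#'
#' The segment's initial state is the candidate's fasting steady state with
#' an empty gut, unless the segment starts mid-excursion (first sample more
#' than 5% away from the candidate's resting glucose), in which case the
#' initial glucose is pinned to the first data point and insulin to its
#' quasi-steady value there. A failed simulation returns `Inf`, which keeps
#' derivative-free optimisers safe.
#'
#' @param data A glucose segment (`cgm_series` or tibble with `time_min`,
#'   `glucose`).
#' @param meals A [meal_events()] table whose amplitudes are the candidate
#'   amplitudes.
#' @param params A candidate [cgm_parameters()] bundle.
#' @param weights Per-sample weights (default all 1).
#' @param rtol,atol Integrator tolerances for the segment simulation.
#' @return The scalar weighted squared-error cost.
#' @export
fit_cost <- function(data, meals, params, weights = NULL,
                     rtol = 1e-8, atol = 1e-10) {
  weights <- weights %||% rep(1, nrow(data))
  if (length(weights) != nrow(data) || any(weights < 0)) {
    abort("`weights` must be non-negative, one per sample.")
  }
  sim <- tryCatch(
    segment_simulation(data, meals, params, rtol = rtol, atol = atol),
    error = function(e) NULL
  )
  if (is.null(sim)) {
    return(Inf)
  }
  sum(weights * (data$glucose - sim$G)^2)
}

# Simulate over the segment window and sample at the data timestamps.
segment_simulation <- function(data, meals, params, dense = FALSE,
                               rtol = 1e-8, atol = 1e-10) {
  t0 <- data$time_min[1]
  t1 <- data$time_min[nrow(data)]
  ss <- fasting_steady_state(params)
  init <- c(qsto = 0, qgut = 0, G = ss$G_star, I = ss$I_star)
  if (abs(data$glucose[1] - ss$G_star) / ss$G_star > 0.05) {
    G0 <- data$glucose[1]
    init[["G"]] <- G0
    init[["I"]] <- params$Imax * G0^2 / (params$alpha + G0^2) / params$kI
  }
  traj <- simulate_glucose(params, meals,
    t_start = t0, t_end = t1, grid_step = if (dense) 1 else (t1 - t0),
    init = init, extra_times = data$time_min, rtol = rtol, atol = atol
  )
  sample_trajectory(traj, data$time_min)
}

#' Personalize the model to a CGM segment
#'
#' Fits the identifiable model parameters and the per-meal amplitudes to a
#' segment of a CGM record containing at least one meal — ideally an
#' isolated liquid-meal pulse, whose stereotyped shape identifies the whole
#' parameter set. The non-identifiable parameters `EG0` and `alpha` are
#' always held fixed, and `kI` is never free: it is recomputed from the
#' steady-state identity [infer_ki()] whenever `Imax` moves, so the
#' laboratory fasting pair stays an equilibrium of the insulin equation
#' throughout the search.
#'
#' Optimisation runs in log-parameter space under box constraints (default
#' a factor of `bounds_factor` either side of the starting bundle) as a
#' seeded two-stage procedure: a derivative-free Hooke-Jeeves pattern
#' search, then a bounded quasi-Newton polish (`stats::nlminb`). The pair
#' is iterated until the relative change in every element of the parameter
#' vector falls below `tol` (default 1e-6) or the outer iteration cap is
#' reached.
#'
#' @param data The glucose segment to fit.
#' @param meals A [meal_events()] table: meal times come from the food
#'   diary and are *not* optimized; the amplitudes are starting values and
#'   are free unless `fit_amplitudes = FALSE`.
#' @param params Starting [cgm_parameters()] bundle; also supplies the
#'   fixed `EG0`, `alpha`, `Gss`, `Iss`.
#' @param free Character vector of free model parameters, a subset of
#'   `c("R0", "SI", "Imax", "ksto", "kgut_liquid", "kgut_mixed")`.
#' @param fit_amplitudes Fit the meal amplitudes (default `TRUE`).
#' @param weights Optional per-sample weights; overrides `pulse_window`.
#' @param pulse_window Optional length-2 time window (min) whose samples
#'   get `pulse_weight` times the unit weight — use it to up-weight the
#'   landmark liquid pulse.
#' @param pulse_weight Weight multiplier inside `pulse_window` (default 5).
#' @param bounds_factor Box half-width as a multiplicative factor around
#'   the starting values (default 10).
#' @param seed Integer seed; the whole search is deterministic given it.
#' @param tol Relative-change termination tolerance (default 1e-6).
#' @param control List of caps and tolerances: `outer` (default 8),
#'   `hj_evals` (default 2000 pattern-search evaluations per outer pass),
#'   `local_iter` (default 500 nlminb iterations), `rtol`/`atol`
#'   (integrator tolerances used inside the cost, defaults 1e-8/1e-10).
#' @return An object of class `cgm_fit`; see [tidy.cgm_fit()] and
#'   [glance.cgm_fit()]. Key elements: `params` (fitted bundle with `kI`
#'   tracking `Imax`), `meals` (with fitted amplitudes), `cost`,
#'   `converged`, `termination` (final relative change), `n_evals`.
#' @export
#' @examples
#' \donttest{
#' day <- reference_day("non_diabetic")
#' seg <- dplyr::filter(day$cgm_true, time_min >= 330, time_min <= 900)
#' fit <- fit_segment(
#'   cgm_series(seg$time_min, seg$glucose, source = "synthetic"),
#'   meal_events(450, 60, "liquid"),
#'   reference_parameters("non_diabetic"),
#'   free = c("SI", "Imax"), seed = 1
#' )
#' glance(fit)
#' }
fit_segment <- function(data, meals, params,
                        free = c("SI", "Imax", "ksto", "kgut_liquid"),
                        fit_amplitudes = TRUE, weights = NULL,
                        pulse_window = NULL, pulse_weight = 5,
                        bounds_factor = 10, seed = 1L, tol = 1e-6,
                        control = list()) {
  stopifnot(inherits(params, "cgm_parameters"))
  if (!inherits(meals, "cgm_meals") || nrow(meals) == 0) {
    abort(paste(
      "`fit_segment()` needs at least one diary meal in the segment;",
      "refusing to fit food amplitudes to a meal-free record."
    ))
  }
  allowed <- c("R0", "SI", "Imax", "ksto", "kgut_liquid", "kgut_mixed")
  if (any(free %in% c("EG0", "alpha", "kI"))) {
    abort("`EG0`, `alpha` and `kI` are not identifiable and cannot be free.")
  }
  if (!all(free %in% allowed)) {
    abort(sprintf(
      "Unknown free parameter(s): %s",
      paste(setdiff(free, allowed), collapse = ", ")
    ))
  }
  if ("kgut_mixed" %in% free && is.null(params$kgut_mixed)) {
    abort("Cannot free `kgut_mixed`: the starting bundle does not set it.")
  }
  ctrl <- modifyList(
    list(
      outer = 8L, hj_evals = 2000L, local_iter = 500L,
      rtol = 1e-8, atol = 1e-10
    ),
    control
  )

  if (is.null(weights)) {
    weights <- rep(1, nrow(data))
    if (!is.null(pulse_window)) {
      inside <- data$time_min >= pulse_window[1] &
        data$time_min <= pulse_window[2]
      weights[inside] <- pulse_weight
    }
  }

  amp0 <- if (fit_amplitudes) {
    ifelse(meals$amplitude > 0, meals$amplitude, 100)
  } else {
    numeric()
  }
  theta0 <- c(
    unlist(params[free]),
    if (fit_amplitudes) setNames(amp0, paste0("amp_", seq_len(nrow(meals))))
  )
  z0 <- log(theta0)
  lower <- z0 - log(bounds_factor)
  upper <- z0 + log(bounds_factor)

  build <- function(z) {
    theta <- exp(z)
    p <- unclass(params)
    p[free] <- theta[free]
    p$kI <- infer_ki(p$Imax, p$alpha, p$Gss, p$Iss)
    m <- meals
    if (fit_amplitudes) {
      m$amplitude <- unname(theta[paste0("amp_", seq_len(nrow(meals)))])
    }
    list(params = structure(p, class = "cgm_parameters"), meals = m)
  }
  n_evals <- 0L
  objective <- function(z) {
    n_evals <<- n_evals + 1L
    cand <- build(z)
    fit_cost(data, cand$meals, cand$params, weights,
      rtol = ctrl$rtol, atol = ctrl$atol)
  }

  withr::with_seed(seed, {
    z <- pmin(pmax(z0, lower), upper)
    f <- objective(z)
    f_init <- f
    outer_change <- Inf
    outer <- 0L
    while (outer < ctrl$outer && outer_change > tol) {
      outer <- outer + 1L
      z_prev <- z
      hj <- hooke_jeeves(objective, z, lower, upper,
        step0 = if (outer == 1L) 0.5 else 0.05,
        step_tol = 1e-4, max_evals = ctrl$hj_evals, f0 = f
      )
      z <- hj$par
      f <- hj$value
      loc <- tryCatch(
        nlminb(z, objective,
          lower = lower, upper = upper,
          control = list(iter.max = ctrl$local_iter, rel.tol = 1e-12)
        ),
        error = function(e) NULL
      )
      if (!is.null(loc) && is.finite(loc$objective) && loc$objective <= f) {
        z <- pmin(pmax(loc$par, lower), upper)
        f <- loc$objective
      }
      outer_change <- max(abs(exp(z) - exp(z_prev)) / pmax(exp(z_prev), 1e-12))
    }
  })

  best <- build(z)
  converged <- outer_change <= tol
  structure(
    list(
      params = best$params,
      meals = best$meals,
      free = free,
      fit_amplitudes = fit_amplitudes,
      cost = f,
      cost_initial = f_init,
      n_evals = n_evals,
      n_outer = outer,
      converged = converged,
      termination = outer_change,
      tol = tol,
      data = data,
      weights = weights,
      seed = seed
    ),
    class = "cgm_fit"
  )
}

# Hooke-Jeeves coordinate pattern search with box constraints.
# Deterministic: explores +/- steps along each coordinate, with pattern
# moves on success and geometric step shrinking on failure.
hooke_jeeves <- function(fn, x0, lower, upper, step0 = 0.5,
                         shrink = 0.5, step_tol = 1e-4,
                         max_evals = 2000L, f0 = NULL) {
  x <- pmin(pmax(x0, lower), upper)
  f <- f0 %||% fn(x)
  evals <- 0L
  step <- step0
  d <- length(x)
  explore <- function(base, fbase) {
    xb <- base
    fb <- fbase
    for (i in seq_len(d)) {
      for (s in c(step, -step)) {
        cand <- xb
        cand[i] <- min(max(cand[i] + s, lower[i]), upper[i])
        if (cand[i] == xb[i]) next
        fc <- fn(cand)
        evals <<- evals + 1L
        if (fc < fb) {
          xb <- cand
          fb <- fc
          break
        }
      }
    }
    list(par = xb, value = fb)
  }
  while (step > step_tol && evals < max_evals) {
    ex <- explore(x, f)
    if (ex$value < f) {
      # pattern move: extrapolate along the improving direction
      repeat {
        xp <- pmin(pmax(ex$par + (ex$par - x), lower), upper)
        x <- ex$par
        f <- ex$value
        if (evals >= max_evals) break
        ex2 <- explore(xp, fn(xp))
        evals <- evals + 1L
        if (ex2$value < f) ex <- ex2 else break
      }
    } else {
      step <- step * shrink
    }
  }
  list(par = x, value = f, evals = evals)
}

#' @export
print.cgm_fit <- function(x, ...) {
  cat(sprintf(
    "<cgm_fit> cost %.4g (from %.4g), %d evaluations, converged: %s\n",
    x$cost, x$cost_initial, x$n_evals, x$converged
  ))
  cat("Fitted parameters:\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy the fitted parameters and meal amplitudes
#'
#' @param x A `cgm_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per free quantity: `term`, `estimate`,
#'   and `fixed` (`FALSE` for free terms, `TRUE` for the bundle's fixed
#'   parameters, which are included for context).
#' @export
tidy.cgm_fit <- function(x, ...) {
  p <- tidy(x$params)
  p$fixed <- !(p$term %in% x$free)
  amps <- if (x$fit_amplitudes) {
    tibble(
      term = paste0("amp_", seq_len(nrow(x$meals))),
      estimate = x$meals$amplitude,
      fixed = FALSE
    )
  }
  dplyr::bind_rows(p, amps)
}

#' One-row fit summary
#'
#' @param x A `cgm_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `cost`, `cost_initial`, `n_evals`, `n_outer`,
#'   `converged`, `termination`.
#' @export
glance.cgm_fit <- function(x, ...) {
  tibble(
    cost = x$cost, cost_initial = x$cost_initial, n_evals = x$n_evals,
    n_outer = x$n_outer, converged = x$converged,
    termination = x$termination
  )
}

#' Serialize a fit result to JSON
#'
#' Writes the fitted bundle, amplitudes, diagnostics and a provenance block
#' (hash of the data segment and of the configuration) so a fit can be
#' audited and reproduced.
#'
#' @param fit A `cgm_fit` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "cgm_fit"))
  payload <- list(
    params = fit$params[!vapply(fit$params, is.null, logical(1))],
    amplitudes = fit$meals$amplitude,
    meal_times = fit$meals$time_min,
    meal_classes = fit$meals$meal_class,
    free = fit$free,
    cost = fit$cost,
    n_evals = fit$n_evals,
    converged = fit$converged,
    termination = fit$termination,
    seed = fit$seed,
    provenance = list(
      data_hash = digest_rows(fit$data),
      config_hash = digest_rows(list(
        fit$free, fit$weights, fit$tol, fit$seed
      )),
      package_version = as.character(utils::packageVersion("cgmpulse"))
    )
  )
  write_atomic(path, function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA)
  })
}

# md5 of a serialized R object (provenance stamps)
digest_rows <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Estimate insulin-independent glucose clearance from a night segment
#'
#' Late at night, several hours after the last meal, insulin action is weak
#' and the glucose equation reduces to the insulin-free relaxation
#' \eqn{dG/dt \approx R_0 - E_{G0} G}, whose solution is
#' \deqn{G(t) = G_\infty + (G_0 - G_\infty) e^{-E_{G0} t},}
#' with plateau \eqn{G_\infty = R_0/E_{G0}}. Fitting this exponential to a
#' decaying night portion of the record estimates `EG0` directly — useful
#' because `EG0` is otherwise fixed rather than fitted.
#'
#' @param data A decaying night segment (>= 6 samples).
#' @return A one-row tibble: `EG0` (min^-1), `G_inf`, `G0` (mg/dl) and
#'   `rss`.
#' @export
estimate_eg0_night <- function(data) {
  if (!all(c("time_min", "glucose") %in% names(data))) {
    abort("`data` must have columns `time_min` and `glucose`.")
  }
  if (nrow(data) < 6) abort("Need at least 6 samples to fit the decay.")
  t <- data$time_min - data$time_min[1]
  g <- data$glucose
  slope <- unname(coef(lm(g ~ t))[2])
  if (!(slope < 0) || g[1] <= min(g) + 1e-9) {
    abort("Segment does not decay; cannot estimate EG0 from it.")
  }
  # log-linear starting values on the shifted series
  g_inf0 <- max(min(g) - 0.05 * diff(range(g)), 1)
  shifted <- pmax(g - g_inf0, 1e-6)
  ll <- lm(log(shifted) ~ t)
  k0 <- max(-unname(coef(ll)[2]), 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      g ~ G_inf + (G0 - G_inf) * exp(-k * t),
      start = list(G_inf = g_inf0, G0 = g[1], k = k0),
      lower = c(G_inf = 0, G0 = 0, k = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      abort(sprintf("Exponential decay fit failed: %s", conditionMessage(e)))
    }
  )
  est <- coef(fit)
  if (est[["k"]] <= 1e-7) {
    abort("Fitted decay rate is ~0; segment carries no usable decay.")
  }
  tibble(
    EG0 = est[["k"]], G_inf = est[["G_inf"]], G0 = est[["G0"]],
    rss = sum(stats::resid(fit)^2)
  )
}
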