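#' Fasting steady state of the glucose-insulin model
#'
#' Solves the meal-free equilibrium of the coupled model. With the gut empty,
#' insulin at its quasi-steady value is
#' \eqn{I_\infty(G) = I_{max} G^2/(\alpha + G^2)/k_I}, and the fasting
#' glucose solves the scalar balance
#' \deqn{R_0 = (E_{G0} + S_I\, I_\infty(G))\, G.}
#' The right-hand side is continuous and increasing from 0, and any physical
#' equilibrium must lie below the insulin-free ceiling `R0/EG0`, so the root
#' is found by bracketed search (Brent) on `(0, R0/EG0]`.
#'
#' The solved resting point is deliberately distinct from the laboratory
#' fasting anchors (`Gss`, `Iss`) stored in the bundle: a fitted model's own
#' resting insulin is typically a little below the laboratory measurement,
#' and both quantities are exposed.
#'
#' @param params A [cgm_parameters()] bundle.
#' @param tol Residual tolerance demanded of both ODE right-hand sides at the
#'   returned point.
#' @return A one-row tibble with columns `G_star` (mg/dl) and `I_star`
#'   (uU/ml).
#' @export
#' @examples
#' fasting_steady_state(reference_parameters("non_diabetic"))
fasting_steady_state <- function(params, tol = 1e-8) {
  stopifnot(inherits(params, "cgm_parameters"))
  I_inf <- function(G) params$Imax * G^2 / (params$alpha + G^2) / params$kI
  resid <- function(G) params$R0 - (params$EG0 + params$SI * I_inf(G)) * G
  ceiling_G <- params$R0 / params$EG0
  lo <- ceiling_G * 1e-9
  if (resid(lo) <= 0 || resid(ceiling_G) > 0) {
    abort(paste(
      "No sign change of the fasting glucose balance on (0, R0/EG0]:",
      "the bundle admits no physical fasting equilibrium."
    ))
  }
  root <- uniroot(resid, c(lo, ceiling_G), tol = tol * 1e-2)
  G_star <- root$root
  I_star <- I_inf(G_star)
  dG <- params$R0 - (params$EG0 + params$SI * I_star) * G_star
  dI <- params$Imax * G_star^2 / (params$alpha + G_star^2) -
    params$kI * I_star
  if (abs(dG) > tol || abs(dI) > tol) {
    abort(sprintf(
      "Equilibrium residuals exceed tolerance (dG = %.3g, dI = %.3g).",
      dG, dI
    ))
  }
  tibble(G_star = G_star, I_star = I_star)
}
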