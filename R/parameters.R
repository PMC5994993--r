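#' Construct a validated minimal-model parameter bundle
#'
#' Bundles the nine rate constants of the coupled food/glucose-insulin model
#' together with the laboratory fasting anchors. The glucose-insulin core is
#' the fast subsystem of the Topp model,
#' \deqn{dG/dt = R_0 - (E_{G0} + S_I I)\,G + k_{gut} q_{gut},}
#' \deqn{dI/dt = I_{max} G^2/(\alpha + G^2) - k_I I,}
#' fed by a two-compartment stomach/gut absorption cascade with rates
#' `ksto` and `kgut`. Meals of class `"liquid"` use `kgut_liquid`; meals of
#' class `"mixed"` use `kgut_mixed` (which may be absent if the record holds
#' no mixed meals).
#'
#' When `kI` is omitted it is derived from the steady-state identity
#' [infer_ki()], which makes the laboratory fasting pair (`Gss`, `Iss`) an
#' exact equilibrium of the insulin equation.
#'
#' @param R0 Basal hepatic glucose production, mg dl^-1 min^-1.
#' @param EG0 Insulin-independent glucose clearance rate, min^-1.
#' @param SI Insulin sensitivity, ml uU^-1 min^-1.
#' @param alpha Half-saturation constant of insulin secretion, mg^2 dl^-2.
#' @param Imax Maximal insulin secretion rate, uU ml^-1 min^-1.
#' @param ksto Stomach emptying rate, min^-1.
#' @param kgut_liquid Gut absorption rate for liquid meals, min^-1.
#' @param kgut_mixed Gut absorption rate for mixed meals, min^-1, or `NULL`.
#' @param Gss Laboratory fasting glucose, mg/dl.
#' @param Iss Laboratory fasting insulin, uU/ml.
#' @param kI Insulin clearance rate, min^-1. Derived from [infer_ki()] when
#'   `NULL` (the default).
#'
#' @return An object of class `cgm_parameters` (a named list).
#' @seealso [reference_parameters()] for the shipped example bundles,
#'   [infer_ki()], [fasting_steady_state()].
#' @export
#' @examples
#' p <- cgm_parameters(
#'   R0 = 2.1, EG0 = 1e-3, SI = 3.06e-3, alpha = 1e4, Imax = 0.28,
#'   ksto = 0.036, kgut_liquid = 0.098, kgut_mixed = 0.011,
#'   Gss = 90, Iss = 12.4
#' )
#' p$kI # derived from the fasting anchors
cgm_parameters <- function(R0, EG0, SI, alpha, Imax, ksto, kgut_liquid,
                           kgut_mixed = NULL, Gss, Iss, kI = NULL) {
  num1 <- function(x, nm, positive = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      abort(sprintf("`%s` must be a single finite number.", nm))
    }
    if (positive && x <= 0) {
      abort(sprintf("`%s` must be strictly positive (got %g).", nm, x))
    }
    as.numeric(x)
  }
  p <- list(
    R0 = num1(R0, "R0"), EG0 = num1(EG0, "EG0"), SI = num1(SI, "SI"),
    alpha = num1(alpha, "alpha"), Imax = num1(Imax, "Imax"),
    ksto = num1(ksto, "ksto"),
    kgut_liquid = num1(kgut_liquid, "kgut_liquid"),
    kgut_mixed = if (!is.null(kgut_mixed)) num1(kgut_mixed, "kgut_mixed"),
    Gss = num1(Gss, "Gss"), Iss = num1(Iss, "Iss")
  )
  p$kI <- if (is.null(kI)) {
    infer_ki(p$Imax, p$alpha, p$Gss, p$Iss)
  } else {
    num1(kI, "kI")
  }
  structure(p, class = "cgm_parameters")
}

#' @export
print.cgm_parameters <- function(x, ...) {
  cat("<cgm_parameters>\n")
  flds <- x[!vapply(x, is.null, logical(1))]
  cat(paste0(
    "  ", format(names(flds)), " = ",
    vapply(flds, function(v) format(v, digits = 6), character(1)),
    collapse = "\n"
  ), "\n")
  invisible(x)
}

#' Tidy a parameter bundle into a tibble
#'
#' @param x A `cgm_parameters` object.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.cgm_parameters <- function(x, ...) {
  flds <- x[!vapply(x, is.null, logical(1))]
  tibble(term = names(flds), estimate = unlist(flds, use.names = FALSE))
}

#' Reference parameter bundles for a non-diabetic and a diabetic subject
#'
#' Returns one of the two personalised parameter sets shipped with the
#' package: a healthy (non-diabetic) subject and a type 2 diabetic patient,
#' each obtained by fitting isolated liquid-meal pulses of a free-living CGM
#' record. The diabetic bundle carries no mixed-meal absorption rate. `kI`
#' is stored at the full precision of the steady-state identity.
#'
#' @param case `"non_diabetic"` or `"diabetic"`.
#' @return A [cgm_parameters()] object.
#' @export
#' @examples
#' reference_parameters("non_diabetic")
reference_parameters <- function(case = c("non_diabetic", "diabetic")) {
  case <- match.arg(case)
  path <- system.file("extdata", paste0("params_", case, ".json"),
    package = "cgmpulse", mustWork = TRUE
  )
  read_parameters(path)
}

#' Read / write a parameter bundle as JSON
#'
#' Field names in the JSON file match the arguments of [cgm_parameters()].
#' `kI` is optional in the file; when absent it is derived from the
#' steady-state identity.
#'
#' @param path Path to a JSON file.
#' @return `read_parameters()` returns a `cgm_parameters` object;
#'   `write_parameters()` returns `path`, invisibly.
#' @export
read_parameters <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c(
    "R0", "EG0", "SI", "alpha", "Imax", "ksto", "kgut_liquid",
    "kgut_mixed", "Gss", "Iss", "kI"
  )
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf(
      "Unknown parameter field(s) in '%s': %s", path,
      paste(unknown, collapse = ", ")
    ))
  }
  do.call(cgm_parameters, raw[intersect(known, names(raw))])
}

#' @rdname read_parameters
#' @param params A `cgm_parameters` object.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "cgm_parameters"))
  flds <- params[!vapply(params, is.null, logical(1))]
  write_atomic(path, function(tmp) {
    jsonlite::write_json(flds, tmp, auto_unbox = TRUE, digits = NA)
  })
}

#' Steady-state identity for the insulin clearance rate
#'
#' At a fasting steady state the insulin equation balances secretion against
#' clearance, so the clearance rate is fixed by the laboratory fasting pair:
#' \deqn{k_I = \frac{I_{max} G_{ss}^2 / (\alpha + G_{ss}^2)}{I_{ss}}.}
#' Because fasting insulin is cheap to measure while `kI` is not directly
#' identifiable from glucose data alone, this identity removes one free
#' parameter from every fit: whenever `Imax` moves during optimisation, `kI`
#' is recomputed from it.
#'
#' @param Imax Maximal insulin secretion rate, uU ml^-1 min^-1.
#' @param alpha Half-saturation constant, mg^2 dl^-2. `alpha = 0` gives the
#'   saturation limit `Imax / Iss`.
#' @param Gss Fasting glucose, mg/dl.
#' @param Iss Fasting insulin, uU/ml.
#' @return The implied insulin clearance rate, min^-1.
#' @export
#' @examples
#' infer_ki(Imax = 0.28, alpha = 1e4, Gss = 90, Iss = 12.4) # ~0.01
#' infer_ki(Imax = 0.93, alpha = 1e4, Gss = 195, Iss = 12.5) # ~0.06
infer_ki <- function(Imax, alpha, Gss, Iss) {
  if (any(!is.finite(c(Imax, alpha, Gss, Iss)))) {
    abort("All inputs to `infer_ki()` must be finite.")
  }
  if (Imax <= 0 || alpha < 0 || Gss <= 0 || Iss <= 0) {
    abort("`infer_ki()` needs Imax, Gss, Iss > 0 and alpha >= 0.")
  }
  Imax * Gss^2 / (alpha + Gss^2) / Iss
}

# kgut for a given meal class; explicit configuration error when the bundle
# lacks the mixed-meal rate (e.g. the diabetic reference bundle).
kgut_for_class <- function(params, meal_class) {
  if (meal_class == "liquid") {
    return(params$kgut_liquid)
  }
  if (is.null(params$kgut_mixed)) {
    abort(paste(
      "This parameter bundle has no `kgut_mixed`, but a mixed meal was",
      "requested. Supply `kgut_mixed` or reclassify the meal."
    ))
  }
  params$kgut_mixed
}
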