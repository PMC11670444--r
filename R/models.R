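#' Curve models for hydraulic vulnerability and stomatal response
#'
#' Three response models underpin the pipeline: a Weibull cumulative model for
#' the fraction of embolized xylem as a function of tension, a sigmoidal
#' (logistic) model for the decline of leaf hydraulic conductance with water
#' potential, and a four-parameter log-logistic model for stomatal conductance.
#' Parameter sets are created with the `*_params()` constructors, which
#' validate the physical constraints (positive scale and shape, negative
#' midpoint water potential, ordered asymptotes).
#'
#' The Weibull model is defined on tension `x = -psi >= 0` (MPa):
#' `F(x) = 1 - exp(-(x/b)^c)`. Water potentials are converted to tension once,
#' at the module boundary; everything the user passes is a (negative) water
#' potential in MPa.
#'
#' @param scale_b Weibull scale (MPa of tension), > 0.
#' @param shape_c Weibull shape (dimensionless), > 0.
#' @name models
NULL

#' @rdname models
#' @export
weibull_params <- function(scale_b, shape_c) {
  check_number(scale_b, "scale_b"); check_number(shape_c, "shape_c")
  if (scale_b <= 0 || shape_c <= 0) stop_input("Weibull scale and shape must be > 0")
  structure(list(scale_b = scale_b, shape_c = shape_c), class = "weibull_params")
}

#' @rdname models
#' @param psi50 Water potential at 50% response (MPa), < 0.
#' @param slope_a Sigmoid steepness (MPa^-1), > 0.
#' @export
sigmoid_params <- function(psi50, slope_a) {
  check_number(psi50, "psi50"); check_number(slope_a, "slope_a")
  if (psi50 >= 0) stop_input("`psi50` must be negative (a water potential in MPa)")
  if (slope_a <= 0) stop_input("`slope_a` must be > 0")
  structure(list(psi50 = psi50, slope_a = slope_a), class = "sigmoid_params")
}

#' @rdname models
#' @param lower,upper Lower/upper conductance asymptotes (mmol m-2 s-1),
#'   `0 <= lower < upper`.
#' @param slope_b Log-logistic steepness (dimensionless), > 0.
#' @param ed50 Tension at the halfway response (MPa), > 0.
#' @export
loglogistic_params <- function(lower, upper, slope_b, ed50) {
  check_number(lower, "lower"); check_number(upper, "upper")
  check_number(slope_b, "slope_b"); check_number(ed50, "ed50")
  if (lower < 0 || upper < lower) stop_input("need 0 <= lower <= upper")
  if (slope_b <= 0 || ed50 <= 0) stop_input("`slope_b` and `ed50` must be > 0")
  structure(list(lower = lower, upper = upper, slope_b = slope_b, ed50 = ed50),
            class = "loglogistic_params")
}

#' Weibull embolized fraction at a given xylem tension
#'
#' @param tension Xylem tension (MPa), `-psi`, non-negative; vectorized.
#' @param params A [weibull_params()] object.
#' @return Fraction embolized in `[0, 1]`.
#' @examples
#' weibull_fraction(4.2198, weibull_params(4.768, 3))  # ~0.5
#' @export
weibull_fraction <- function(tension, params) {
  stopifnot(inherits(params, "weibull_params"))
  if (any(!is.finite(tension)) || any(tension < 0)) {
    stop_input("`tension` must be finite and >= 0")
  }
  1 - exp(-(tension / params$scale_b)^params$shape_c)
}

#' Tension inducing x% embolism (Px inversion of the Weibull model)
#'
#' @inheritParams weibull_fraction
#' @param x_percent Percent embolism in (0, 100); vectorized.
#' @return Tension (MPa) such that `weibull_fraction()` equals `x_percent/100`.
#' @examples
#' weibull_px(weibull_params(1, 1), 50)  # log(2)
#' @export
weibull_px <- function(params, x_percent) {
  stopifnot(inherits(params, "weibull_params"))
  if (any(!is.finite(x_percent)) || any(x_percent <= 0) || any(x_percent >= 100)) {
    stop_input("`x_percent` must lie strictly between 0 and 100")
  }
  params$scale_b * (-log(1 - x_percent / 100))^(1 / params$shape_c)
}

# (b, c) <-> (P50, S50) reparameterization used for fitting.
# P50 = b * (ln 2)^(1/c) is the tension at 50% embolism; S50 is the slope of
# the percent curve there, in percent per MPa: S50 = 50 * ln(2) * c / P50.
weibull_to_p50 <- function(params) {
  p50 <- params$scale_b * log(2)^(1 / params$shape_c)
  list(p50 = p50, s50 = 50 * log(2) * params$shape_c / p50)
}

weibull_from_p50 <- function(p50, s50) {
  if (p50 <= 0 || s50 <= 0) stop_input("`p50` and `s50` must be > 0")
  shape_c <- s50 * p50 / (50 * log(2))
  weibull_params(scale_b = p50 / log(2)^(1 / shape_c), shape_c = shape_c)
}

#' Sigmoidal relative conductance at a given water potential
#'
#' `1 / (1 + exp(slope_a * (psi50 - psi)))`: 1 when well hydrated, 0.5 at
#' `psi50`, 0 under extreme tension.
#'
#' @param psi Leaf water potential (MPa); vectorized.
#' @param params A [sigmoid_params()] object.
#' @return Relative conductance in (0, 1).
#' @export
sigmoid_relcond <- function(psi, params) {
  stopifnot(inherits(params, "sigmoid_params"))
  if (any(!is.finite(psi))) stop_input("`psi` must be finite")
  1 / (1 + exp(params$slope_a * (params$psi50 - psi)))
}

#' Log-logistic stomatal conductance at a given water potential
#'
#' `lower + (upper - lower) / (1 + ((-psi)/ed50)^slope_b)`, evaluated on
#' tension `-psi > 0`.
#'
#' @param psi Leaf water potential (MPa), strictly negative; vectorized.
#' @param params A [loglogistic_params()] object.
#' @return Conductance in `[lower, upper]` (mmol m-2 s-1).
#' @export
loglogistic_g <- function(psi, params) {
  stopifnot(inherits(params, "loglogistic_params"))
  if (any(!is.finite(psi)) || any(psi >= 0)) {
    stop_input("`psi` must be finite and < 0 (tension must be positive)")
  }
  params$lower + (params$upper - params$lower) /
    (1 + ((-psi) / params$ed50)^params$slope_b)
}
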