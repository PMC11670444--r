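#' Fit a vulnerability or stomatal-response curve by nonlinear least squares
#'
#' Fits one of three response models to `(x, y)` observations with bounded
#' Levenberg-Marquardt least squares ([minpack.lm::nlsLM()]), using
#' deterministic data-driven starting values and a small fixed ladder of
#' restarts on non-convergence. `x` is always leaf water potential in MPa
#' (negative); models defined on tension convert internally via `-x`.
#'
#' * `"weibull"` — percent embolism `y` in `[0, 100]`:
#'   `y = 100 * (1 - exp(-((-x)/b)^c))`. The optimizer works in the
#'   `(P50, S50)` space (tension at 50% embolism, slope there in % per MPa),
#'   which makes bootstrap percentiles of P50 well behaved; `(b, c)` are
#'   recovered from `P50 = b (ln 2)^{1/c}` and `S50 = 50 ln(2) c / P50`.
#' * `"sigmoid"` — conductance `y >= 0`:
#'   `y = kmax / (1 + exp(a (psi50 - x)))` with free amplitude `kmax`.
#' * `"loglogistic"` — conductance `y >= 0`:
#'   `y = lower + (upper - lower) / (1 + ((-x)/ed50)^b)`, `lower >= 0`.
#'
#' @param data Data frame with numeric columns `x` (water potential, MPa) and
#'   `y` (percent embolism or conductance).
#' @param model One of `"weibull"`, `"sigmoid"`, `"loglogistic"`.
#' @param init Optional named list overriding the automatic starting values
#'   (names as in the fitted coefficients).
#' @return An object of class `vc_fit`: a list with elements `model`, `coef`
#'   (named numeric vector), `params` (the corresponding `*_params` object),
#'   `r2` (1 - SS_res/SS_tot on the fitted scale), `n_obs`, `converged`, and
#'   the data used. Non-convergence is flagged (`converged = FALSE`), never
#'   silent.
#' @examples
#' x <- seq(-8, -0.5, by = 0.5)
#' y <- 100 * weibull_fraction(-x, weibull_params(4.768, 3))
#' fit_curve(data.frame(x = x, y = y), "weibull")
#' @export
fit_curve <- function(data, model = c("weibull", "sigmoid", "loglogistic"),
                      init = NULL) {
  model <- match.arg(model)
  if (!is.data.frame(data) || !all(c("x", "y") %in% names(data))) {
    stop_input("`data` must be a data frame with columns `x` and `y`")
  }
  ok <- is.finite(data$x) & is.finite(data$y)
  data <- data[ok, c("x", "y")]
  p <- switch(model, weibull = 2L, sigmoid = 3L, loglogistic = 4L)
  if (nrow(data) < p + 1L) {
    stop_input("need at least ", p + 1L, " finite observations for a ", model, " fit")
  }
  x <- data$x; y <- data$y

  degenerate <- sum((y - mean(y))^2) == 0
  spec <- switch(model,
    weibull = fit_spec_weibull(x, y),
    sigmoid = fit_spec_sigmoid(x, y),
    loglogistic = fit_spec_loglogistic(x, y)
  )
  start <- spec$start
  if (!is.null(init)) start[names(init)] <- as.numeric(init)

  fit <- NULL
  if (!degenerate) {
    for (fac in c(1, 0.5, 2, 0.25, 4)) {
      st <- start
      st[spec$restart_on] <- start[spec$restart_on] * fac
      st <- pmin(pmax(st, spec$lower), spec$upper)
      fit <- tryCatch(
        minpack.lm::nlsLM(spec$formula, data = data.frame(x = x, y = y),
                          start = as.list(st), lower = spec$lower,
                          upper = spec$upper,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
  }

  if (is.null(fit)) {
    cf <- start
    converged <- FALSE
  } else {
    cf <- coef(fit)
    converged <- TRUE
  }
  yhat <- spec$eval(cf, x)
  if (any(!is.finite(yhat))) converged <- FALSE
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0 || any(!is.finite(yhat))) NA_real_
        else 1 - sum((y - yhat)^2) / ss_tot
  # degenerate optima (e.g. a vanishing Weibull shape) cannot be expressed as
  # a valid parameter object; keep the raw coefficients and flag the fit
  params <- tryCatch(spec$as_params(cf), error = function(e) {
    converged <<- FALSE
    NULL
  })

  structure(list(
    model = model,
    coef = cf,
    params = params,
    r2 = r2,
    n_obs = length(y),
    converged = converged,
    data = tibble::tibble(x = x, y = y)
  ), class = "vc_fit")
}

fit_spec_weibull <- function(x, y) {
  tension <- -x
  i50 <- which.min(abs(y - 50))
  p50_init <- max(tension[i50], 1e-3)
  s50_init <- local_slope(tension, y, i50)
  if (!is.finite(s50_init) || s50_init <= 0) s50_init <- 20
  list(
    # with c = s50*p50/(50 ln2) and b = p50/ln2^(1/c): (t/b)^c = ln2 (t/p50)^c
    formula = y ~ 100 * (1 - exp(-log(2) * ((-x) / p50)^(s50 * p50 / (50 * log(2))))),
    start = c(p50 = p50_init, s50 = s50_init),
    lower = c(p50 = 1e-6, s50 = 1e-6),
    upper = c(p50 = Inf, s50 = Inf),
    restart_on = "s50",
    eval = function(cf, x) {
      cc <- cf[["s50"]] * cf[["p50"]] / (50 * log(2))
      100 * (1 - exp(-log(2) * ((-x) / cf[["p50"]])^cc))
    },
    as_params = function(cf) weibull_from_p50(cf[["p50"]], cf[["s50"]])
  )
}

fit_spec_sigmoid <- function(x, y) {
  kmax_init <- max(y)
  i50 <- which.min(abs(y - kmax_init / 2))
  psi50_init <- min(x[i50], -1e-6)
  # logistic slope at midpoint is kmax*a/4
  sl <- local_slope(x, y, i50)
  a_init <- if (is.finite(sl) && sl > 0) 4 * sl / max(kmax_init, 1e-12) else 2
  list(
    formula = y ~ kmax / (1 + exp(a * (psi50 - x))),
    start = c(psi50 = psi50_init, a = max(a_init, 1e-3), kmax = max(kmax_init, 1e-6)),
    lower = c(psi50 = -Inf, a = 1e-6, kmax = 1e-9),
    upper = c(psi50 = 0, a = Inf, kmax = Inf),
    restart_on = "a",
    eval = function(cf, x) {
      cf[["kmax"]] * sigmoid_relcond(x, sigmoid_params(cf[["psi50"]], cf[["a"]]))
    },
    as_params = function(cf) sigmoid_params(min(cf[["psi50"]], -1e-12), cf[["a"]])
  )
}

fit_spec_loglogistic <- function(x, y) {
  tension <- -x
  list(
    formula = y ~ lower + (upper - lower) / (1 + ((-x) / ed50)^b),
    start = c(lower = max(min(y), 0), upper = max(y),
              ed50 = max(median(tension), 1e-3), b = 2),
    lower = c(lower = 0, upper = 1e-9, ed50 = 1e-6, b = 1e-6),
    upper = c(lower = Inf, upper = Inf, ed50 = Inf, b = Inf),
    restart_on = "b",
    eval = function(cf, x) {
      cf[["lower"]] + (cf[["upper"]] - cf[["lower"]]) /
        (1 + ((-x) / cf[["ed50"]])^cf[["b"]])
    },
    as_params = function(cf) {
      loglogistic_params(cf[["lower"]], max(cf[["upper"]], cf[["lower"]]),
                         cf[["b"]], cf[["ed50"]])
    }
  )
}

# finite-difference slope of y on x around index i (symmetric neighbours)
local_slope <- function(x, y, i) {
  j <- max(1L, i - 2L):min(length(x), i + 2L)
  abs(ls_line(x[j], y[j])$slope)
}

#' Water potential at 50% response from a fitted curve
#'
#' For a Weibull fit this is `-P50` (the negated tension at 50% embolism);
#' for a sigmoid fit the fitted midpoint `psi50`.
#'
#' @param fit A `vc_fit` object.
#' @return Water potential (MPa, negative).
#' @export
fitted_psi50 <- function(fit) {
  stopifnot(inherits(fit, "vc_fit"))
  switch(fit$model,
    weibull = -fit$coef[["p50"]],
    sigmoid = fit$coef[["psi50"]],
    stop_input("psi50 is defined for weibull and sigmoid fits only"))
}

#' @export
predict.vc_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata$x
  spec <- switch(object$model,
    weibull = fit_spec_weibull(object$data$x, object$data$y),
    sigmoid = fit_spec_sigmoid(object$data$x, object$data$y),
    loglogistic = fit_spec_loglogistic(object$data$x, object$data$y))
  spec$eval(object$coef, x)
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("<vc_fit> ", x$model, " model, n = ", x$n_obs,
      if (!x$converged) "  [NOT CONVERGED]" else "", "\n", sep = "")
  print(round(x$coef, 5))
  cat("R2 =", format(x$r2, digits = 5), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy vc_fit
#' @export
tidy.vc_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @method glance vc_fit
#' @export
glance.vc_fit <- function(x, ...) {
  tibble::tibble(model = x$model, r2 = x$r2, n_obs = x$n_obs,
                 converged = x$converged)
}
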