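#' Reference maximum stomatal conductance from control plants
#'
#' @param points Data frame with columns `psi`, `g_leaf`
#'   (mmol m-2 s-1) and `group` (`"control"`/`"drought"`).
#' @param method `"mean"` (default; robust to a single high reading) or
#'   `"max"`.
#' @return Conductance (mmol m-2 s-1).
#' @export
control_gmax <- function(points, method = c("mean", "max")) {
  method <- match.arg(method)
  g <- points$g_leaf[points$group == "control"]
  if (length(g) == 0) stop_input("no control-group points")
  if (method == "mean") mean(g) else max(g)
}

#' Water potential of 95% stomatal closure, by resampling
#'
#' Repeats, `n_boot` times (default 999): resample the drought-group points
#' with replacement, fit the log-logistic stomatal response, evaluate the
#' fitted curve on a dense water-potential grid (step <= `grid_step` MPa)
#' spanning the resample's observed range, and linearly interpolate the water
#' potential at which conductance falls to 5% of `g_max`. Replicates whose
#' fitted curve never crosses the threshold inside the data range (or whose
#' fit fails) are redrawn from the same RNG stream. The reported estimate is
#' the mean over replicates; the confidence interval the 2.5/97.5 percentiles.
#'
#' @inheritParams control_gmax
#' @param g_max Reference maximum conductance (see [control_gmax()]).
#' @param n_boot Number of successful replicates (default 999).
#' @param seed Integer seed.
#' @param grid_step Interpolation grid step (MPa), default 0.005.
#' @param closure_fraction Residual fraction defining closure (default 0.05).
#' @return List with `psi_g95_mean` (MPa), `ci` (a `boot_ci`; its `point` is
#'   the full-data estimate), `threshold_g`, `n_redrawn`.
#' @export
psi_g95_bootstrap <- function(points, g_max, n_boot = 999, seed = NULL,
                              grid_step = 0.005, closure_fraction = 0.05) {
  check_number(g_max, "g_max")
  drought <- points[points$group == "drought", , drop = FALSE]
  if (nrow(drought) < 5) stop_input("need at least 5 drought-group points")
  threshold <- closure_fraction * g_max
  d <- tibble::tibble(x = drought$psi, y = drought$g_leaf)

  crossing <- function(df) {
    f <- fit_curve(df, "loglogistic")
    if (!f$converged) return(NA_real_)
    lo <- min(df$x); hi <- max(df$x)
    grid <- seq(lo, hi, by = min(grid_step, (hi - lo) / 10))
    g_hat <- predict(f, newdata = data.frame(x = grid))
    # monotone non-decreasing in psi: interpolate psi as a function of g
    if (threshold < min(g_hat) || threshold > max(g_hat)) return(NA_real_)
    approx(x = g_hat, y = grid, xout = threshold, ties = "ordered")$y
  }
  ci <- bootstrap_ci(d, crossing, n_boot = n_boot, seed = seed)
  list(psi_g95_mean = ci$boot_mean, ci = ci, threshold_g = threshold,
       n_redrawn = ci$n_redrawn)
}

#' Stomatal safety margin
#'
#' Difference between the water potential of near-complete stomatal closure
#' and the water potential of 50% xylem embolism. Positive when embolism
#' occurs only beyond stomatal closure.
#'
#' @param psi_g95 Water potential of 95% stomatal closure (MPa).
#' @param psi50_xe Water potential of 50% xylem embolism (MPa).
#' @return Margin (MPa); negative values are flagged with a warning.
#' @examples
#' stomatal_safety_margin(-1.81, -4.22)  # 2.41
#' @export
stomatal_safety_margin <- function(psi_g95, psi50_xe) {
  check_number(psi_g95, "psi_g95"); check_number(psi50_xe, "psi50_xe")
  ssm <- psi_g95 - psi50_xe
  if (ssm < 0) warn("negative stomatal safety margin: embolism precedes stomatal closure")
  ssm
}

#' Full stomatal-response analysis
#'
#' Combines [control_gmax()], [psi_g95_bootstrap()] and, when `psi50_xe` is
#' supplied, [stomatal_safety_margin()].
#'
#' @inheritParams psi_g95_bootstrap
#' @param psi50_xe Optional water potential of 50% xylem embolism (MPa).
#' @param gmax_method Passed to [control_gmax()].
#' @return A one-row tibble of class `stomatal_result`: `g_max_control`,
#'   `threshold_g`, `psi_g95_mean`, `psi_g95_lo`, `psi_g95_hi`, `ssm`,
#'   `n_boot`, `n_redrawn`.
#' @export
stomatal_response <- function(points, n_boot = 999, seed = NULL,
                              psi50_xe = NULL, gmax_method = "mean") {
  g_max <- control_gmax(points, gmax_method)
  res <- psi_g95_bootstrap(points, g_max, n_boot = n_boot, seed = seed)
  out <- tibble::tibble(
    g_max_control = g_max,
    threshold_g = res$threshold_g,
    psi_g95_mean = res$psi_g95_mean,
    psi_g95_lo = res$ci$lo,
    psi_g95_hi = res$ci$hi,
    ssm = if (is.null(psi50_xe)) NA_real_
          else stomatal_safety_margin(res$psi_g95_mean, psi50_xe),
    n_boot = n_boot,
    n_redrawn = res$n_redrawn
  )
  class(out) <- c("stomatal_result", class(out))
  out
}
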