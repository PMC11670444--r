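#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_vline
#'   geom_abline labs theme_minimal annotate
#' @export
ggplot2::autoplot

#' @method autoplot pv_curve
#' @export
autoplot.pv_curve <- function(object, region = NULL, ...) {
  df <- tibble::tibble(deficit = object$points$deficit,
                       inv_psi = -1 / object$points$psi)
  p <- ggplot(df, aes(x = .data$deficit, y = .data$inv_psi)) +
    geom_point() +
    labs(x = "relative water deficit (1 - RWC)",
         y = expression(-1 / Psi[leaf] ~ (MPa^-1)),
         title = "Pressure-volume isotherm") +
    theme_minimal()
  if (is.null(region)) {
    region <- tryCatch(detect_osmotic_region(object), error = function(e) NULL)
  }
  if (!is.null(region)) {
    p <- p + geom_abline(slope = region$slope, intercept = region$intercept,
                         linetype = 2, colour = "steelblue")
  }
  p
}

#' @method autoplot vc_fit
#' @export
autoplot.vc_fit <- function(object, n_grid = 200, ...) {
  grid <- tibble::tibble(x = seq(min(object$data$x), max(object$data$x),
                                 length.out = n_grid))
  grid$y <- predict(object, grid)
  ggplot(object$data, aes(x = .data$x, y = .data$y)) +
    geom_point(alpha = 0.6) +
    geom_line(data = grid, colour = "steelblue") +
    labs(x = expression(Psi[leaf] ~ (MPa)), y = "response",
         title = paste(object$model, "fit")) +
    theme_minimal()
}

#' @method autoplot ov_curve
#' @export
autoplot.ov_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$psi, y = .data$percent)) +
    geom_point(aes(colour = .data$method)) +
    labs(x = expression(Psi[leaf] ~ (MPa)), y = "embolized area (%)",
         title = "Optical vulnerability curve") +
    theme_minimal()
}

#' Threshold-sequence plot of a trait report
#'
#' Vertical markers for the critical water potentials (turgor loss, 50% loss
#' of leaf conductance, 95% stomatal closure, 50% xylem embolism) over the
#' fitted relative response curves.
#'
#' @param report A `trait_report` from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_thresholds <- function(report) {
  stopifnot(inherits(report, "trait_report"))
  th <- report$thresholds[is.finite(report$thresholds$psi_mpa), ]
  ggplot(th, aes(x = .data$psi_mpa, y = 0)) +
    geom_vline(aes(xintercept = .data$psi_mpa, colour = .data$threshold),
               linetype = 2) +
    labs(x = expression(Psi[leaf] ~ (MPa)), y = NULL, colour = NULL,
         title = "Critical water-potential thresholds") +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
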