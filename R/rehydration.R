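#' Equilibration quality control for rehydration trials
#'
#' Before a rehydration trial, two neighbouring leaves from the same culm are
#' measured; if their water potentials differ by more than 0.1 MPa the culm
#' has not equilibrated and is discarded. The boundary (exactly 0.1 MPa) is
#' accepted.
#'
#' @param psi_a,psi_b Water potentials of the two check leaves (MPa);
#'   vectorized.
#' @return Logical vector: `TRUE` = accept.
#' @export
qc_equilibration <- function(psi_a, psi_b) {
  if (any(!is.finite(psi_a)) || any(!is.finite(psi_b))) {
    stop_input("check-leaf water potentials must be finite")
  }
  abs(psi_a - psi_b) <= 0.1 + 1e-12  # boundary inclusive, robust to fp noise
}

#' Leaf hydraulic conductance from one or more rehydration trials
#'
#' Rehydration of a detached leaf relaxes its water potential exponentially,
#' so the conductance follows from the initial and final water potentials and
#' the rehydration time:
#' `K_leaf = C_leaf * ln(psi_i / psi_f) / t`,
#' with the full-turgor capacitance `c_ft` used when `psi_i` is above the
#' turgor loss point and the post-turgor-loss capacitance `c_tlp` otherwise
#' (the boundary `psi_i == psi_tlp` is assigned to the TLP branch).
#' Capacitances are in mol m-2 MPa-1; the result is reported in
#' mmol s-1 m-2 MPa-1 (factor 1000).
#'
#' @param trials Data frame with columns `psi_i`, `psi_f` (MPa, < 0) and
#'   `t_s` (s, > 0); optional `psi_check_a`/`psi_check_b` trigger the
#'   [qc_equilibration()] filter (rejected trials are dropped with a warning).
#' @param c_ft,c_tlp Leaf capacitance at full turgor / beyond turgor loss
#'   (mol m-2 MPa-1).
#' @param psi_tlp Turgor loss point (MPa).
#' @return Tibble with columns `psi_i`, `kleaf` (mmol s-1 m-2 MPa-1) and
#'   `capacitance_used` (`"FT"`/`"TLP"`).
#' @examples
#' kleaf_eq1(data.frame(psi_i = -0.5, psi_f = -0.2061, t_s = 20),
#'           c_ft = 0.37, c_tlp = 1.49, psi_tlp = -1.8)
#' @export
kleaf_eq1 <- function(trials, c_ft, c_tlp, psi_tlp) {
  need <- c("psi_i", "psi_f", "t_s")
  if (!is.data.frame(trials) || !all(need %in% names(trials))) {
    stop_input("`trials` must have columns psi_i, psi_f, t_s")
  }
  if (all(c("psi_check_a", "psi_check_b") %in% names(trials))) {
    keep <- qc_equilibration(trials$psi_check_a, trials$psi_check_b)
    if (any(!keep)) {
      warn(paste0(sum(!keep), " trial(s) discarded by the 0.1 MPa equilibration rule"))
      trials <- trials[keep, , drop = FALSE]
    }
  }
  with(trials, {
    if (any(psi_i >= 0) || any(psi_f >= 0)) stop_input("psi_i and psi_f must be < 0")
    if (any(t_s <= 0)) stop_input("rehydration time must be > 0")
    if (any(psi_f < psi_i)) stop_input("leaf dehydrated during rehydration (psi_f more negative than psi_i)")
  })
  use_tlp <- trials$psi_i <= psi_tlp
  cap <- ifelse(use_tlp, c_tlp, c_ft)
  tibble::tibble(
    psi_i = trials$psi_i,
    kleaf = 1000 * cap * log(trials$psi_i / trials$psi_f) / trials$t_s,
    capacitance_used = ifelse(use_tlp, "TLP", "FT")
  )
}

#' Maximum leaf hydraulic conductance of well-hydrated leaves
#'
#' Mean of the conductances measured at `psi_i` above the hydration
#' threshold (default -0.7 MPa).
#'
#' @param points Tibble from [kleaf_eq1()] (columns `psi_i`, `kleaf`).
#' @param psi_threshold Hydration cutoff (MPa), exclusive.
#' @return Mean conductance (mmol s-1 m-2 MPa-1).
#' @export
max_kleaf <- function(points, psi_threshold = -0.7) {
  sel <- points$psi_i > psi_threshold
  if (!any(sel)) stop_input("no well-hydrated points (psi_i > ", psi_threshold, " MPa)")
  mean(points$kleaf[sel])
}

#' Fit the whole-leaf hydraulic vulnerability curve
#'
#' Sigmoidal fit of `kleaf` against `psi_i`; the water potential at 50% loss
#' of maximum conductance is the fitted midpoint, with a percentile-bootstrap
#' confidence interval.
#'
#' @param points Tibble with columns `psi_i` and `kleaf` (>= 6 rows spanning
#'   the 50% point).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return List of class `kleaf_vc`: `fit` (a `vc_fit`), `psi50_k`, and
#'   `ci` (a `boot_ci` on the midpoint).
#' @export
fit_kleaf_vc <- function(points, n_boot = 1000, seed = NULL) {
  d <- tibble::tibble(x = points$psi_i, y = points$kleaf)
  fit <- fit_curve(d, "sigmoid")
  if (!fit$converged) stop_input("whole-leaf vulnerability fit did not converge")
  stat <- function(df) {
    f <- fit_curve(df, "sigmoid")
    if (!f$converged) return(NA_real_)
    fitted_psi50(f)
  }
  ci <- bootstrap_ci(d, stat, n_boot = n_boot, seed = seed)
  structure(list(fit = fit, psi50_k = fitted_psi50(fit), ci = ci),
            class = "kleaf_vc")
}

#' @export
print.kleaf_vc <- function(x, ...) {
  cat(sprintf("<kleaf_vc> psi50_k = %.3f MPa  95%% CI [%.3f, %.3f]  R2 = %.3f\n",
              x$psi50_k, x$ci$lo, x$ci$hi, x$fit$r2))
  invisible(x)
}
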