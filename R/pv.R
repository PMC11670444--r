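#' Construct a pressure-volume curve object
#'
#' Bundles the ordered (water potential, fresh mass) observations of one
#' slowly dehydrating leaf with its area and dry weight. Observations are
#' ordered by decreasing fresh mass (increasing dehydration); exact
#' consecutive duplicates are dropped, so appending a repeat of the last
#' reading is a no-op.
#'
#' @param data Data frame with columns `psi_mpa` (leaf water potential, MPa,
#'   < 0) and `fresh_mass` (leaf fresh mass in the unit given by `mass_unit`;
#'   the column may also be named `fresh_mass_g`).
#' @param leaf_area_mm2 One-sided leaf area (mm^2), > 0.
#' @param dry_weight_g Oven-dry leaf mass (g), > 0.
#' @param saturated_mass_g Fresh mass at full turgor (g). Defaults to the
#'   first (heaviest) recorded mass, matching a protocol that starts from
#'   rehydrated leaves.
#' @param mass_unit Unit of the fresh-mass column, `"g"` (default) or `"mg"`.
#' @return An object of class `pv_curve`: list with a `points` tibble
#'   (`psi`, `mass_g`, `rwc`, `deficit`) plus the leaf metadata.
#' @export
pv_curve <- function(data, leaf_area_mm2, dry_weight_g, saturated_mass_g = NULL,
                     mass_unit = c("g", "mg")) {
  mass_unit <- match.arg(mass_unit)
  psi <- data[["psi_mpa"]] %||% data[["psi"]]
  mass <- data[["fresh_mass"]] %||% data[["fresh_mass_g"]] %||% data[["mass"]]
  if (is.null(psi) || is.null(mass)) {
    stop_input("`data` needs columns `psi_mpa` and `fresh_mass` (or `fresh_mass_g`)")
  }
  if (mass_unit == "mg") mass <- mass / 1000
  if (any(!is.finite(psi)) || any(psi >= 0)) stop_input("all `psi_mpa` must be finite and < 0")
  if (any(!is.finite(mass)) || any(mass <= 0)) stop_input("all masses must be finite and > 0")
  check_number(leaf_area_mm2, "leaf_area_mm2"); check_number(dry_weight_g, "dry_weight_g")
  if (leaf_area_mm2 <= 0) stop_input("`leaf_area_mm2` must be > 0")
  if (dry_weight_g <= 0) stop_input("`dry_weight_g` must be > 0")

  ord <- order(mass, decreasing = TRUE)
  psi <- psi[ord]; mass <- mass[ord]
  dup <- c(FALSE, diff(mass) == 0 & diff(psi) == 0)
  psi <- psi[!dup]; mass <- mass[!dup]
  if (length(psi) < 6) stop_input("a pressure-volume curve needs at least 6 points")
  if (any(diff(mass) >= 0)) stop_input("fresh mass must be strictly decreasing")
  if (which.max(psi) != 1L) {
    warn("heaviest point does not have the least negative psi (measurement noise?)")
  }
  if (any(mass <= dry_weight_g)) {
    stop_input("fresh mass at point ", which(mass <= dry_weight_g)[1],
               " is not above the dry weight")
  }
  sat <- saturated_mass_g %||% mass[1]
  if (sat < max(mass)) stop_input("`saturated_mass_g` must be >= every fresh mass")

  rwc <- (mass - dry_weight_g) / (sat - dry_weight_g)
  bad <- rwc <= 0 | rwc > 1
  if (any(bad)) {
    stop_input("relative water content outside (0, 1] at point ", which(bad)[1])
  }
  structure(list(
    points = tibble::tibble(psi = psi, mass_g = mass, rwc = rwc, deficit = 1 - rwc),
    leaf_area_mm2 = leaf_area_mm2,
    dry_weight_g = dry_weight_g,
    saturated_mass_g = sat
  ), class = "pv_curve")
}

#' @export
print.pv_curve <- function(x, ...) {
  cat(sprintf("<pv_curve> %d points, psi %.2f to %.2f MPa, area %.1f mm2, DW %.4f g\n",
              nrow(x$points), x$points$psi[1], tail(x$points$psi, 1),
              x$leaf_area_mm2, x$dry_weight_g))
  invisible(x)
}

#' Relative water content sequence of a pressure-volume curve
#'
#' `RWC_i = (mass_i - DW) / (saturated_mass - DW)`.
#'
#' @param curve A [pv_curve()] object.
#' @return Numeric vector of fractions in (0, 1], one per point.
#' @export
relative_water_content <- function(curve) {
  stopifnot(inherits(curve, "pv_curve"))
  curve$points$rwc
}

#' Locate the linear osmotic region of a pressure-volume curve
#'
#' Works on the transformed isotherm `-1/psi` versus relative water deficit
#' `1 - RWC`. Beyond the turgor loss point this relationship is linear
#' (solute conservation in a shrinking symplast); turgid points bend away
#' from the line. The region is found by shrinking from the hydrated end:
#' starting from all points (anchored at the most-dehydrated end), the
#' most-hydrated point of the candidate run is dropped as long as dropping it
#' increases the regression R^2. The final run must span at least 4 points
#' with R^2 > 0.95, else an error is raised.
#'
#' @param curve A [pv_curve()] object (>= 6 points).
#' @return An object of class `osmotic_region`: list with `start`, `end`
#'   (point indices, dehydration order), `slope`, `intercept` (of `-1/psi` on
#'   deficit), `r2`, `n`.
#' @export
detect_osmotic_region <- function(curve) {
  stopifnot(inherits(curve, "pv_curve"))
  d <- curve$points$deficit
  y <- -1 / curve$points$psi
  n <- length(y)
  run_r2 <- function(k) ls_line(d[k:n], y[k:n])$r2
  k <- 1L
  r2 <- run_r2(k)
  while (n - k >= 4L) {
    r2_next <- run_r2(k + 1L)
    # keep dropping hydrated points until the run is linear (R^2 > 0.95);
    # once it is, stop at the first drop that no longer improves R^2
    if (is.na(r2) || r2 <= 0.95 || r2_next > r2) {
      k <- k + 1L; r2 <- r2_next
    } else break
  }
  if (n - k + 1L < 4L || is.na(r2) || r2 <= 0.95) {
    stop_input("no linear osmotic region (>= 4 consecutive points with R^2 > 0.95)")
  }
  line <- ls_line(d[k:n], y[k:n])
  structure(list(start = k, end = n, slope = line$slope,
                 intercept = line$intercept, r2 = line$r2, n = n - k + 1L),
            class = "osmotic_region")
}

#' Osmotic potential at full turgor and apoplastic water fraction
#'
#' From the line `-1/psi = intercept + slope * deficit`:
#' `pi0 = -1/intercept`, and the deficit `d0 = -intercept/slope` at which the
#' line reaches zero marks exhaustion of symplastic water, so
#' `AWF = 1 - d0`.
#'
#' @param line An `osmotic_region` (or any list with `slope` and `intercept`).
#' @return List with `pi0` (MPa, < 0) and `awf` (fraction).
#' @export
osmotic_parameters <- function(line) {
  if (!is.finite(line$slope) || !is.finite(line$intercept)) stop_input("invalid line fit")
  if (line$slope >= 0) stop_input("osmotic line slope must be negative (curve not dehydrating)")
  if (line$intercept <= 0) stop_input("osmotic line intercept must be positive")
  d0 <- -line$intercept / line$slope
  list(pi0 = -1 / line$intercept, awf = 1 - d0)
}

#' Turgor loss point of a pressure-volume curve
#'
#' The turgor loss point is taken as the least-dehydrated point inside the
#' linear osmotic region (the last point to enter it).
#'
#' @param curve A [pv_curve()] object.
#' @param region An `osmotic_region` from [detect_osmotic_region()].
#' @return List with `psi_tlp` (MPa) and `rwc_tlp` (fraction).
#' @export
turgor_loss_point <- function(curve, region) {
  stopifnot(inherits(curve, "pv_curve"), inherits(region, "osmotic_region"))
  if (region$n < 4) stop_input("osmotic region spans fewer than 4 points")
  list(psi_tlp = curve$points$psi[region$start],
       rwc_tlp = curve$points$rwc[region$start])
}

#' Bulk modulus of elasticity over the turgid range
#'
#' Turgor pressure at each pre-turgor-loss point is `P = psi - pi`, with the
#' osmotic potential `pi` extrapolated from the osmotic line
#' (`pi = -1/(intercept + slope * deficit)`, assuming solute conservation).
#' `eps_total` is the least-squares slope of `P` versus total relative water
#' content; `eps_sym`, on the symplastic water basis, equals
#' `eps_total * (1 - AWF)` exactly (chain rule through
#' `RWC_sym = (RWC - AWF)/(1 - AWF)`).
#'
#' @inheritParams turgor_loss_point
#' @return List with `eps_total` and `eps_sym` (MPa).
#' @export
elastic_modulus <- function(curve, region) {
  stopifnot(inherits(curve, "pv_curve"), inherits(region, "osmotic_region"))
  pre <- seq_len(region$start - 1L)
  if (length(pre) < 3) stop_input("need at least 3 points with positive turgor")
  pts <- curve$points[pre, ]
  osm <- osmotic_parameters(region)
  pi_i <- -1 / (region$intercept + region$slope * pts$deficit)
  turgor <- pts$psi - pi_i
  eps_total <- ls_line(pts$rwc, turgor)$slope
  list(eps_total = eps_total, eps_sym = eps_total * (1 - osm$awf))
}

#' Leaf hydraulic capacitance on either side of the turgor loss point
#'
#' Least-squares slope of cumulative leaf water (mol, via the molar mass of
#' water, 18.015 g mol^-1) against water potential, normalized by leaf area.
#' The `pre` branch uses points with `psi > psi_tlp`, the `post` branch
#' points with `psi <= psi_tlp`.
#'
#' @inheritParams turgor_loss_point
#' @param psi_tlp Turgor loss point (MPa).
#' @param branch `"pre"` (full-turgor branch) or `"post"` (beyond turgor loss).
#' @param method `"slope"` (least squares, default) or `"endpoints"`.
#' @return Capacitance (mol m-2 MPa-1, positive).
#' @export
leaf_capacitance <- function(curve, psi_tlp, branch = c("pre", "post"),
                             method = c("slope", "endpoints")) {
  stopifnot(inherits(curve, "pv_curve"))
  branch <- match.arg(branch); method <- match.arg(method)
  sel <- if (branch == "pre") curve$points$psi > psi_tlp else curve$points$psi <= psi_tlp
  if (sum(sel) < 2) stop_input("fewer than 2 points on the ", branch, "-TLP branch")
  pts <- curve$points[sel, ]
  water_mol_m2 <- (pts$mass_g - curve$dry_weight_g) / MOLAR_MASS_WATER /
    (curve$leaf_area_mm2 * 1e-6)
  m <- nrow(pts)
  cap <- if (method == "slope") {
    ls_line(pts$psi, water_mol_m2)$slope
  } else {
    (water_mol_m2[m] - water_mol_m2[1]) / (pts$psi[m] - pts$psi[1])
  }
  if (!is.finite(cap) || cap == 0) {
    warn("degenerate capacitance branch (zero water loss)")
    cap <- 0
  }
  cap
}

#' Saturated water content and specific leaf area
#'
#' `SWC = (saturated mass - DW)/DW` (g water per g dry mass);
#' `SLA = leaf area / DW` in mm^2 mg^-1.
#'
#' @inheritParams turgor_loss_point
#' @return List with `swc` and `sla`.
#' @export
swc_and_sla <- function(curve) {
  stopifnot(inherits(curve, "pv_curve"))
  if (curve$dry_weight_g <= 0) stop_input("dry weight must be > 0")
  list(swc = (curve$saturated_mass_g - curve$dry_weight_g) / curve$dry_weight_g,
       sla = curve$leaf_area_mm2 / (curve$dry_weight_g * 1000))
}

#' Elaborate a pressure-volume curve into its full trait set
#'
#' Runs the whole isotherm elaboration: linear osmotic region, osmotic
#' potential at full turgor and apoplastic water fraction, turgor loss point,
#' elastic moduli, branch capacitances, saturated water content and specific
#' leaf area.
#'
#' @param curve A [pv_curve()] object.
#' @return A one-row tibble of class `pv_traits` with columns `swc`, `sla`,
#'   `pi0`, `psi_tlp`, `awf`, `rwc_tlp`, `eps_total`, `eps_sym`, `c_leaf_ft`,
#'   `c_leaf_tlp`, `osmotic_slope`, `osmotic_intercept`, `osmotic_r2`,
#'   `region_start`, `region_n`, `n_points`.
#' @examples
#' curve <- gen_pv_curve(pi0 = -1.5, eps_sym = 9, awf = 0.386, n_points = 60)$curve
#' analyze_pv(curve)
#' @export
analyze_pv <- function(curve) {
  stopifnot(inherits(curve, "pv_curve"))
  region <- detect_osmotic_region(curve)
  osm <- osmotic_parameters(region)
  tlp <- turgor_loss_point(curve, region)
  eps <- elastic_modulus(curve, region)
  base <- swc_and_sla(curve)
  out <- tibble::tibble(
    swc = base$swc, sla = base$sla,
    pi0 = osm$pi0, psi_tlp = tlp$psi_tlp, awf = osm$awf, rwc_tlp = tlp$rwc_tlp,
    eps_total = eps$eps_total, eps_sym = eps$eps_sym,
    c_leaf_ft = leaf_capacitance(curve, tlp$psi_tlp, "pre"),
    c_leaf_tlp = leaf_capacitance(curve, tlp$psi_tlp, "post"),
    osmotic_slope = region$slope, osmotic_intercept = region$intercept,
    osmotic_r2 = region$r2, region_start = region$start, region_n = region$n,
    n_points = nrow(curve$points)
  )
  if (!(out$psi_tlp <= out$pi0 && out$pi0 < 0)) {
    warn("trait invariant psi_tlp <= pi0 < 0 violated; inspect the curve")
  }
  class(out) <- c("pv_traits", class(out))
  out
}

#' Summarize pressure-volume traits across leaves
#'
#' Simple mean +/- SD aggregation of [analyze_pv()] rows from several leaves.
#'
#' @param traits A data frame of stacked `pv_traits` rows.
#' @return Tibble with one row per trait: `trait`, `mean`, `sd`, `n`.
#' @export
pv_traits_summary <- function(traits) {
  keep <- c("swc", "sla", "pi0", "psi_tlp", "awf", "rwc_tlp",
            "eps_total", "eps_sym", "c_leaf_ft", "c_leaf_tlp")
  traits |>
    dplyr::select(dplyr::any_of(keep)) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "trait") |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
}
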