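# small hand-built curve: 2 turgid points with the worked capacitance deltas,
# then 4 points on an exact osmotic line
capacitance_curve <- function() {
  data <- data.frame(
    psi_mpa = c(-0.5, -1.5, -2.0, -2.2, -2.4, -2.6),
    fresh_mass_g = c(1.02, 1.013335, 0.95, 0.93, 0.91, 0.89)
  )
  pv_curve(data, leaf_area_mm2 = 1000, dry_weight_g = 0.30)
}

test_that("relative water content is simple mass arithmetic with guards", {
  d <- data.frame(psi_mpa = c(-0.1, -0.4, -0.8, -1.2, -1.6, -2.0),
                  fresh_mass_g = c(1.02, 0.975, 0.93, 0.9, 0.876, 0.85))
  cv <- pv_curve(d, leaf_area_mm2 = 1000, dry_weight_g = 0.30)
  rwc <- relative_water_content(cv)
  expect_equal(rwc[1], 1)                       # fresh = saturated
  expect_equal(rwc[5], 0.80)                    # (0.876-0.30)/(1.02-0.30)
  d_bad <- d; d_bad$fresh_mass_g[6] <- 0.25     # below dry weight
  expect_error(pv_curve(d_bad, 1000, 0.30), "dry weight")
})

test_that("curve construction validates, orders, and deduplicates", {
  d <- data.frame(psi_mpa = c(-0.1, -0.4, -0.8, -1.2, -1.6),
                  fresh_mass_g = c(1.02, 0.975, 0.93, 0.9, 0.876))
  expect_error(pv_curve(d, 1000, 0.3), "at least 6")
  g <- gen_pv_curve(n_points = 40)
  dup <- rbind(g$data, g$data[nrow(g$data), ])
  cv_dup <- pv_curve(dup, g$truth$leaf_area_mm2, g$truth$dry_weight_g,
                     saturated_mass_g = g$curve$saturated_mass_g)
  expect_equal(analyze_pv(cv_dup), analyze_pv(g$curve))
})

test_that("trait extraction is invariant to declaring masses in mg", {
  g <- gen_pv_curve(n_points = 40)
  d_mg <- data.frame(psi_mpa = g$data$psi_mpa,
                     fresh_mass = g$data$fresh_mass_g * 1000)
  cv <- pv_curve(d_mg, g$truth$leaf_area_mm2, g$truth$dry_weight_g,
                 saturated_mass_g = g$curve$saturated_mass_g, mass_unit = "mg")
  expect_equal(analyze_pv(cv), analyze_pv(g$curve), tolerance = 1e-12)
})

test_that("osmotic region excludes an outlier at the hydrated end", {
  # 5 points exactly on -1/psi = 2/3 - 1.0857 * deficit, one hydrated outlier
  slope <- -1.0857; intercept <- 2 / 3
  d <- c(0.05, 0.20, 0.25, 0.30, 0.35, 0.40)
  y <- intercept + slope * d
  y[1] <- y[1] + 0.12  # outlier off the line
  psi <- -1 / y
  dw <- 0.3; sat <- 1.02
  mass <- dw + (sat - dw) * (1 - d)
  cv <- pv_curve(data.frame(psi_mpa = psi, fresh_mass_g = mass),
                 1000, dw, saturated_mass_g = sat)
  region <- detect_osmotic_region(cv)
  # brute-force oracle over all dry-end-anchored runs
  runs <- lapply(4:6, function(k) {
    idx <- (6 - k + 1):6
    yy <- -1 / psi[idx]
    fit <- lm(yy ~ d[idx])
    list(k = k, r2 = 1 - sum(residuals(fit)^2) / sum((yy - mean(yy))^2))
  })
  r2s <- vapply(runs, function(r) r$r2, numeric(1))
  qualifying <- vapply(runs, function(r) r$k, integer(1))[r2s >= max(r2s) - 1e-9]
  expect_equal(region$n, max(qualifying))  # ties broken toward more points
  expect_equal(region$start, 2L)  # the 5 collinear points
  expect_equal(region$r2, 1, tolerance = 1e-9)
})

test_that("osmotic region excludes all points with positive turgor (generator truth)", {
  g <- gen_pv_curve(pi0 = -1.5, eps_sym = 9, awf = 0.386, n_points = 40)
  region <- detect_osmotic_region(g$curve)
  turgid <- g$curve$points$psi > g$truth$psi_tlp + 1e-9
  expect_true(all(which(turgid) < region$start))
  expect_equal(region$r2, 1, tolerance = 1e-10)
})

test_that("osmotic line yields pi0 and the apoplastic fraction", {
  osm <- osmotic_parameters(list(slope = -(2 / 3) / 0.614, intercept = 2 / 3))
  expect_equal(osm$pi0, -1.5)
  expect_equal(osm$awf, 0.386, tolerance = 1e-12)
  expect_error(osmotic_parameters(list(slope = 0.2, intercept = 2 / 3)), "slope")
  # intercept -> infinity means pi0 -> 0 from below
  expect_gt(osmotic_parameters(list(slope = -1, intercept = 1e6))$pi0, -1e-5)
})

test_that("turgor loss point and elastic moduli match the osmometer truth", {
  g <- gen_pv_curve(pi0 = -1.5, eps_sym = 9, awf = 0.386, n_points = 200)
  region <- detect_osmotic_region(g$curve)
  tlp <- turgor_loss_point(g$curve, region)
  expect_equal(tlp$psi_tlp, -1.8, tolerance = 0.01)
  expect_equal(tlp$rwc_tlp, 0.8977, tolerance = 0.002)
  eps <- elastic_modulus(g$curve, region)
  expect_equal(eps$eps_sym, 9, tolerance = 0.1)
  expect_equal(eps$eps_total, 9 / (1 - 0.386), tolerance = 0.2)
  # exact algebraic identity of the implementation
  osm <- osmotic_parameters(region)
  expect_equal(eps$eps_sym, eps$eps_total * (1 - osm$awf), tolerance = 1e-12)
})

test_that("branch capacitance reproduces the worked two-point example", {
  cv <- capacitance_curve()
  # pre branch: delta psi = -1 MPa, delta mass = 0.006665 g, area 0.001 m2
  expect_equal(leaf_capacitance(cv, psi_tlp = -1.8, "pre"),
               0.006665 / 18.015 / 0.001, tolerance = 1e-9)
  expect_equal(leaf_capacitance(cv, psi_tlp = -1.8, "pre"), 0.37, tolerance = 1e-2)
  expect_equal(leaf_capacitance(cv, psi_tlp = -1.8, "pre", method = "endpoints"),
               leaf_capacitance(cv, psi_tlp = -1.8, "pre"), tolerance = 1e-12)
  expect_error(leaf_capacitance(cv, psi_tlp = -0.7, "pre"), "fewer than 2")
})

test_that("the post-turgor-loss branch always has the larger capacitance", {
  for (seed in 1:5) {
    g <- withr::with_seed(seed, gen_pv_curve(
      pi0 = runif(1, -3, -1), eps_sym = runif(1, 6, 20),
      awf = runif(1, 0.1, 0.5), n_points = 60, rwc_sym_min = 0.55))
    tr <- analyze_pv(g$curve)
    expect_gt(tr$c_leaf_tlp, tr$c_leaf_ft)
  }
})

test_that("saturated water content and specific leaf area are ratio arithmetic", {
  cv <- capacitance_curve()  # sat 1.02 g, DW 0.30 g
  base <- swc_and_sla(cv)
  expect_equal(base$swc, 2.4)
  g <- gen_pv_curve()  # area 69.7 mm2, DW 3.69 mg
  expect_equal(swc_and_sla(g$curve)$sla, 18.9, tolerance = 0.01)
})

test_that("the full elaboration recovers forced turgor-loss parameterizations", {
  p <- pv_params_from_tlp(psi_tlp = -1.8, rwc_sym_tlp = 5 / 6)
  expect_equal(p$pi0, -1.5)
  expect_equal(p$eps_sym, 9)
  tr <- analyze_pv(gen_pv_curve(pi0 = p$pi0, eps_sym = p$eps_sym,
                                awf = 0.386, n_points = 40)$curve)
  expect_equal(tr$pi0, -1.5, tolerance = 0.01)
  expect_equal(tr$psi_tlp, -1.8, tolerance = 0.05)
  expect_equal(tr$osmotic_r2, 1, tolerance = 1e-10)
})

test_that("random osmometer curves are recovered within 1% (noise-free)", {
  withr::with_seed(12, {
    for (i in 1:100) {
      pi0 <- runif(1, -3, -1); eps <- runif(1, 5, 20); awf <- runif(1, 0.1, 0.5)
      rtlp <- 1 + pi0 / eps
      if (rtlp < 0.7) next  # grid must extend beyond the turgor loss point
      g <- gen_pv_curve(pi0 = pi0, eps_sym = eps, awf = awf, n_points = 40,
                        rwc_sym_min = max(0.5, rtlp - 0.25))
      tr <- analyze_pv(g$curve)
      expect_equal(tr$pi0, pi0, tolerance = 0.01)
      expect_equal(tr$awf, awf, tolerance = 0.01)
      # turgor loss point within one grid step of the closed form
      psi <- g$curve$points$psi
      step <- max(abs(diff(psi[max(1, tr$region_start - 2):min(length(psi), tr$region_start + 2)])))
      expect_lt(abs(tr$psi_tlp - g$truth$psi_tlp), step + 1e-9)
    }
  })
})

test_that("recovered pi0 is nearly unbiased under 1% symplastic-water mass noise", {
  noise <- 0.01 * (1 - 0.386) * 2.4 * 0.00369
  est <- vapply(1:200, function(i) {
    g <- suppressWarnings(
      gen_pv_curve(n_points = 40, noise_sd_mass = noise, seed = 5000 + i))
    tr <- tryCatch(suppressWarnings(analyze_pv(g$curve)),
                   error = function(e) NULL)
    if (is.null(tr)) NA_real_ else tr$pi0
  }, numeric(1))
  expect_lt(mean(is.na(est)), 0.05)
  expect_lt(abs(mean(est, na.rm = TRUE) - (-1.5)) / 1.5, 0.05)
})
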