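flat_stack <- function(n_frames = 4, value = 0.3, nr = 12, nc = 12) {
  ov_stack(replicate(n_frames, matrix(value, nr, nc), simplify = FALSE),
           timestamps = seq(0, by = 300, length.out = n_frames))
}

test_that("stack construction enforces shape and time invariants", {
  expect_error(ov_stack(list(matrix(0, 4, 4)), 0), "at least 2")
  expect_error(ov_stack(list(matrix(0, 4, 4), matrix(0, 5, 4)), c(0, 300)),
               "identical dimensions")
  expect_error(ov_stack(list(matrix(0, 4, 4), matrix(0, 4, 4)), c(300, 300)),
               "increasing")
})

test_that("identical frames produce an all-zero trace", {
  tr <- detect_events(flat_stack())
  expect_equal(tr$new_px, rep(0L, 4))
  expect_equal(attr(tr, "total_px"), 0L)
})

test_that("scripted zero-noise events are recovered exactly, pixel for pixel", {
  g <- gen_ov_stack(seed = 21)
  tr <- detect_events(g$stack)
  expect_equal(tr$new_px, g$truth$trace$new_px)
  expect_equal(tr$cum_px, g$truth$trace$cum_px)
  expect_true(all(diff(tr$cum_px) >= 0))
})

test_that("sub-threshold noise yields no events; constant offsets are ignored", {
  frames <- withr::with_seed(5, replicate(6, {
    matrix(0.3 + runif(144, -0.01, 0.01), 12, 12)
  }, simplify = FALSE))
  st <- ov_stack(frames, seq(0, by = 300, length.out = 6))
  tr <- detect_events(st, diff_threshold = 0.05)
  expect_equal(attr(tr, "total_px"), 0L)

  g <- gen_ov_stack(seed = 22)
  shifted <- ov_stack(lapply(g$stack$frames, function(f) f + 0.17),
                      g$stack$timestamps, g$stack$pixel_size_mm)
  expect_equal(detect_events(shifted)$new_px, detect_events(g$stack)$new_px)
})

test_that("component filtering uses 8-connectivity", {
  nr <- 10
  f1 <- matrix(0, nr, nr); f2 <- f1
  for (i in 1:5) f2[i, i] <- 1            # 5-px diagonal: one 8-connected blob
  st <- ov_stack(list(f1, f2), c(0, 300))
  tr <- detect_events(st, diff_threshold = 0.5, min_component_px = 5)
  expect_equal(attr(tr, "total_px"), 5L)  # survives only if 8-connected
  tr2 <- detect_events(st, diff_threshold = 0.5, min_component_px = 6)
  expect_equal(attr(tr2, "total_px"), 0L)
})

test_that("water potential interpolation is linear and refuses extrapolation", {
  series <- tibble::tibble(time_s = c(0, 600), psi_mpa = c(-1, -2))
  expect_equal(psi_at(0, series), -1)
  expect_equal(psi_at(300, series), -1.5)
  expect_error(psi_at(-5, series), "extrapolate")
  expect_error(psi_at(601, series), "extrapolate")
})

test_that("curve building normalizes to the final cumulative area", {
  tr <- tibble::tibble(time = c(0, 300, 600, 900),
                       new_px = c(0L, 40L, 40L, 0L),
                       cum_px = c(0L, 40L, 80L, 80L))
  attr(tr, "total_px") <- 80L
  series <- tibble::tibble(time_s = c(0, 900), psi_mpa = c(-1, -4))
  cv <- build_ov_curve(tr, series, method = "pressure_chamber")
  expect_equal(cv$percent, c(0, 50, 100, 100))
  expect_equal(cv$psi, c(-1, -2, -3, -4))
  # frames beyond the record are dropped with a warning
  short <- tibble::tibble(time_s = c(0, 600), psi_mpa = c(-1, -3))
  expect_warning(cv2 <- build_ov_curve(tr, short), "dropped")
  expect_equal(nrow(cv2), 3L)
  zero <- tr; zero$new_px[] <- 0L; zero$cum_px[] <- 0L
  attr(zero, "total_px") <- 0L
  expect_error(build_ov_curve(zero, series), "no embolism")
})

test_that("a Weibull-scheduled stack yields the generating 50% point", {
  x <- seq(-8, -0.5, by = 0.25)
  cv <- gen_vc_observations("weibull", weibull_params(4.768, 3), x)$data
  f <- fit_ov(cv, n_boot = 80, seed = 3)
  expect_equal(f$psi50_xe, -4.2197, tolerance = 0.01)
  expect_lte(f$ci$lo, f$psi50_xe + 1e-6)
})

test_that("end-to-end stack recovery stays within 5% over seeded replicates", {
  err <- vapply(1:20, function(i) {
    g <- gen_ov_stack(seed = 300 + i)
    tr <- detect_events(g$stack)
    cv <- build_ov_curve(tr, g$psi_series)
    f <- fit_curve(data.frame(x = cv$psi, y = cv$percent), "weibull")
    abs(fitted_psi50(f) - g$truth$psi50) / abs(g$truth$psi50)
  }, numeric(1))
  expect_lt(max(err), 0.05)
})

test_that("pooling preserves observations and flags real differences", {
  x <- seq(-8, -0.5, by = 0.25)
  one <- gen_vc_observations("weibull", weibull_params(4.768, 3), x)$data
  curves <- list(pressure_chamber = one, dewpoint_hygrometer = one,
                 psychrometer = one)
  cmp <- pool_and_compare(curves, n_boot = 40, seed = 6)
  expect_equal(nrow(cmp$pooled_curve), 3 * nrow(one))
  expect_false(any(cmp$comparisons$different))
  expect_equal(cmp$pooled_fit$psi50_xe, cmp$per_method[[1]]$psi50_xe,
               tolerance = 1e-3)

  far <- list(
    a = gen_vc_observations("weibull", leafhydraulics:::weibull_from_p50(3, 30), x,
                            noise_sd = 0.5, seed = 7)$data,
    b = gen_vc_observations("weibull", leafhydraulics:::weibull_from_p50(5, 30), x,
                            noise_sd = 0.5, seed = 8)$data
  )
  cmp2 <- pool_and_compare(far, n_boot = 60, seed = 9)
  expect_true(all(cmp2$comparisons$different))
})

test_that("vein length density matches digital-segment geometry", {
  m <- matrix(0, 20, 110); m[10, 6:105] <- 1   # 100 px straight line
  expect_equal(vein_length_density(m, 0.01, 1), 1.0, tolerance = 1e-12)
  # 45-degree digital segment vs its Euclidean length (brute-force oracle)
  md <- matrix(0, 120, 120)
  for (i in 0:100) md[10 + i, 10 + i] <- 1
  oracle <- sqrt(2) * 100 * 0.01
  expect_equal(vein_length_density(md, 0.01, 1), oracle, tolerance = 0.015)
  expect_warning(v0 <- vein_length_density(matrix(0, 5, 5), 0.01, 1), "empty")
  expect_equal(v0, 0)
  # a 3-px-thick line thins to (nearly) the same centerline length
  mt <- matrix(0, 20, 110); mt[9:11, 6:105] <- 1
  expect_equal(vein_length_density(mt, 0.01, 1), 1.0, tolerance = 0.1)
})
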