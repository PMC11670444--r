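test_that("equilibration rule accepts within 0.1 MPa, boundary inclusive", {
  expect_true(qc_equilibration(-1.00, -1.05))
  expect_false(qc_equilibration(-1.00, -1.15))
  expect_true(qc_equilibration(-1.0, -1.1))  # boundary
  expect_error(qc_equilibration(NA_real_, -1), "finite")
})

test_that("the rehydration equation reproduces the worked conductance", {
  k <- kleaf_eq1(data.frame(psi_i = -0.500, psi_f = -0.2061, t_s = 20),
                 c_ft = 0.37, c_tlp = 1.49, psi_tlp = -1.8)
  expect_equal(k$kleaf, 0.37 * log(0.5 / 0.2061) / 20 * 1000, tolerance = 1e-12)
  expect_equal(round(k$kleaf, 1), 16.4)
  expect_equal(k$capacitance_used, "FT")
  # no relaxation means zero conductance
  k0 <- kleaf_eq1(data.frame(psi_i = -1, psi_f = -1, t_s = 30), 0.37, 1.49, -1.8)
  expect_equal(k0$kleaf, 0)
  expect_error(
    kleaf_eq1(data.frame(psi_i = -0.5, psi_f = -0.9, t_s = 20), 0.37, 1.49, -1.8),
    "dehydrated")
})

test_that("capacitance switches at the turgor loss point (boundary to TLP)", {
  k <- kleaf_eq1(data.frame(psi_i = c(-1.0, -1.8, -2.0),
                            psi_f = c(-0.5, -0.9, -1.0), t_s = 20),
                 c_ft = 0.37, c_tlp = 1.49, psi_tlp = -1.8)
  expect_equal(k$capacitance_used, c("FT", "TLP", "TLP"))
  expect_equal(k$kleaf[3], 1.49 * log(2) / 20 * 1000, tolerance = 1e-12)
})

test_that("qc-rejected trials are dropped with a warning before conversion", {
  tr <- data.frame(psi_check_a = c(-1.0, -1.0), psi_check_b = c(-1.05, -1.3),
                   psi_i = c(-1.0, -1.0), psi_f = c(-0.5, -0.5), t_s = 20)
  expect_warning(k <- kleaf_eq1(tr, 0.37, 1.49, -1.8), "discarded")
  expect_equal(nrow(k), 1L)
})

test_that("the equation round-trips its own inversion to 1e-10", {
  withr::with_seed(8, {
    for (i in 1:50) {
      k_true <- runif(1, 0.5, 25); cap <- runif(1, 0.2, 2)
      psi_i <- runif(1, -2.5, -0.3); t_s <- runif(1, 5, 60)
      g <- gen_rehydration(k_true, cap, psi_i, t_s)
      out <- kleaf_eq1(g$trials, c_ft = cap, c_tlp = cap, psi_tlp = -99)
      expect_equal(out$kleaf, k_true, tolerance = 1e-10)
    }
  })
})

test_that("conductance depends only on the psi ratio", {
  base <- kleaf_eq1(data.frame(psi_i = -0.5, psi_f = -0.25, t_s = 20),
                    0.37, 1.49, -99)
  scaled <- kleaf_eq1(data.frame(psi_i = -1.5, psi_f = -0.75, t_s = 20),
                      0.37, 1.49, -99)
  expect_equal(base$kleaf, scaled$kleaf, tolerance = 1e-12)
})

test_that("maximum conductance averages the well-hydrated points only", {
  pts <- tibble::tibble(psi_i = c(-0.5, -0.6, -1.0), kleaf = c(16, 17, 10))
  expect_equal(max_kleaf(pts), 16.5)
  expect_equal(max_kleaf(pts[1, ]), 16)
  expect_lte(max_kleaf(pts), max(pts$kleaf))
  expect_error(max_kleaf(pts[3, ]), "well-hydrated")
})

test_that("the whole-leaf vulnerability fit recovers the generating midpoint", {
  psi <- seq(-2.5, -0.3, length.out = 30)
  pts <- gen_vc_observations("sigmoid", sigmoid_params(-1.35, 3), psi,
                             kmax = 16.4)$data
  vc <- fit_kleaf_vc(pts, n_boot = 60, seed = 2)
  expect_equal(vc$psi50_k, -1.35, tolerance = 1e-3)
  expect_equal(vc$fit$r2, 1, tolerance = 1e-9)

  noisy <- gen_vc_observations("sigmoid", sigmoid_params(-1.35, 3),
                               withr::with_seed(1, runif(40, -2.5, -0.3)),
                               noise_sd = 0.8, kmax = 16.4, seed = 1)$data
  vcn <- fit_kleaf_vc(noisy, n_boot = 300, seed = 1)
  expect_lte(vcn$ci$lo, -1.35)
  expect_gte(vcn$ci$hi, -1.35)

  flat <- tibble::tibble(psi_i = psi, kleaf = 0)
  expect_error(fit_kleaf_vc(flat, n_boot = 10, seed = 1), "converge")
})
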