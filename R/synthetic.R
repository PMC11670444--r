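#' Synthetic pressure-volume curve with closed-form ground truth
#'
#' Simulates the dehydration isotherm of a linear-elastic "osmometer" leaf:
#' on a grid of symplastic relative water content `R` descending from just
#' below saturation, osmotic potential follows solute conservation
#' (`pi = pi0 / R`), turgor declines linearly with symplastic water deficit
#' (`P = max(0, -pi0 - eps_sym (1 - R))`), and `psi = P + pi`. Total relative
#' water content mixes in an apoplastic fraction
#' (`RWC = awf + (1 - awf) R`), and fresh mass is
#' `DW (1 + swc * RWC)`. The closed-form truth is
#' `R_tlp = 1 + pi0/eps_sym` and `psi_tlp = pi0 / R_tlp`.
#'
#' This generator exists to test the analyzer: real leaves need not have a
#' constant symplastic modulus.
#'
#' @param pi0 Osmotic potential at full turgor (MPa, < 0).
#' @param eps_sym Symplastic bulk modulus of elasticity (MPa, > 0).
#' @param awf Apoplastic water fraction in `[0, 1)`.
#' @param swc Saturated water content (g water per g dry mass).
#' @param dry_weight_g Leaf dry mass (g). The default (0.00369 g) is
#'   consistent with the default leaf area at a specific leaf area of
#'   18.9 mm^2 mg^-1, and yields full-turgor and post-turgor-loss
#'   capacitances near 0.4 and 1.5 mol m-2 MPa-1.
#' @param leaf_area_mm2 Leaf area (mm^2).
#' @param n_points Number of points on the curve.
#' @param noise_sd_mass Gaussian SD added to fresh masses (g).
#' @param seed Integer seed (masses only; the grid is deterministic).
#' @param rwc_sym_min Symplastic RWC at the dry end of the grid (must lie
#'   beyond the turgor loss point).
#' @return List with `curve` (a [pv_curve()]), `data` (tibble `psi_mpa`,
#'   `fresh_mass_g`) and `truth` (generator name, parameters, closed-form
#'   `psi_tlp`, `rwc_sym_tlp`, `rwc_tlp_total`, `eps_total`, seed).
#' @examples
#' gen_pv_curve(pi0 = -1.5, eps_sym = 9)$truth$psi_tlp  # -1.8
#' @export
gen_pv_curve <- function(pi0 = -1.5, eps_sym = 9, awf = 0.386, swc = 2.4,
                         dry_weight_g = 0.00369, leaf_area_mm2 = 69.7,
                         n_points = 40, noise_sd_mass = 0, seed = NULL,
                         rwc_sym_min = 0.6) {
  if (pi0 >= 0) stop_input("`pi0` must be < 0")
  if (eps_sym <= 0) stop_input("`eps_sym` must be > 0")
  if (awf < 0 || awf >= 1) stop_input("`awf` must be in [0, 1)")
  rwc_sym_tlp <- 1 + pi0 / eps_sym
  if (rwc_sym_tlp <= 0) stop_input("parameters give non-positive symplastic RWC at turgor loss")
  if (rwc_sym_min >= rwc_sym_tlp) {
    stop_input("`rwc_sym_min` must lie beyond the turgor loss point (", round(rwc_sym_tlp, 3), ")")
  }
  rs <- seq(1, rwc_sym_min, length.out = n_points + 1)[-1]
  turgor <- pmax(0, -pi0 - eps_sym * (1 - rs))
  psi <- turgor + pi0 / rs
  rwc_tot <- awf + (1 - awf) * rs
  mass <- dry_weight_g * (1 + swc * rwc_tot)
  sat_mass <- dry_weight_g * (1 + swc)
  if (noise_sd_mass > 0) {
    mass <- with_seed_if(seed, mass + rnorm(n_points, 0, noise_sd_mass))
  }
  data <- tibble::tibble(psi_mpa = psi, fresh_mass_g = mass)
  curve <- pv_curve(data, leaf_area_mm2 = leaf_area_mm2,
                    dry_weight_g = dry_weight_g,
                    saturated_mass_g = max(sat_mass, max(mass)))
  truth <- list(generator = "gen_pv_curve", pi0 = pi0, eps_sym = eps_sym,
                awf = awf, swc = swc, dry_weight_g = dry_weight_g,
                leaf_area_mm2 = leaf_area_mm2,
                psi_tlp = pi0 / rwc_sym_tlp, rwc_sym_tlp = rwc_sym_tlp,
                rwc_tlp_total = awf + (1 - awf) * rwc_sym_tlp,
                eps_total = eps_sym / (1 - awf), seed = seed)
  list(curve = curve, data = data, truth = truth)
}

#' Osmometer-model parameters from turgor-loss quantities
#'
#' Inverse parameterization of [gen_pv_curve()]: given the turgor loss point
#' and the symplastic relative water content there, returns the osmotic
#' potential at full turgor (`pi0 = psi_tlp * rwc_sym_tlp`) and the
#' symplastic modulus (`eps_sym = -pi0 / (1 - rwc_sym_tlp)`).
#'
#' @param psi_tlp Turgor loss point (MPa, < 0).
#' @param rwc_sym_tlp Symplastic RWC at turgor loss, in (0, 1).
#' @return List with `pi0` and `eps_sym`.
#' @export
pv_params_from_tlp <- function(psi_tlp, rwc_sym_tlp) {
  if (psi_tlp >= 0) stop_input("`psi_tlp` must be < 0")
  if (rwc_sym_tlp <= 0 || rwc_sym_tlp >= 1) stop_input("`rwc_sym_tlp` must be in (0, 1)")
  pi0 <- psi_tlp * rwc_sym_tlp
  list(pi0 = pi0, eps_sym = -pi0 / (1 - rwc_sym_tlp))
}

#' Synthetic rehydration trials with known conductance
#'
#' Inverts the rehydration-kinetics relation: a leaf of capacitance `C`
#' (mol m-2 MPa-1) rehydrating for `t` seconds at conductance `K`
#' (mmol s-1 m-2 MPa-1) relaxes to
#' `psi_f = psi_i * exp(-(K/1000) * t / C)`.
#'
#' @param k_true True conductance (mmol s-1 m-2 MPa-1), >= 0; scalar or one
#'   value per trial (e.g. a declining vulnerability profile).
#' @param capacitance Leaf capacitance used in the inversion
#'   (mol m-2 MPa-1); scalar or one value per trial.
#' @param psi_i Initial water potentials (MPa, < 0); one trial each.
#' @param t_s Rehydration time(s) in seconds (recycled).
#' @param noise_sd_psi Gaussian SD added to `psi_f` (MPa).
#' @param seed Integer seed.
#' @return List with `trials` (tibble `psi_check_a`, `psi_check_b`, `psi_i`,
#'   `psi_f`, `t_s`) and `truth`.
#' @export
gen_rehydration <- function(k_true = 16.4, capacitance = 0.37,
                            psi_i = seq(-0.5, -2.4, by = -0.1), t_s = 20,
                            noise_sd_psi = 0, seed = NULL) {
  if (any(k_true < 0)) stop_input("`k_true` must be >= 0")
  n <- length(psi_i)
  t_s <- rep_len(t_s, n)
  k_true <- rep_len(k_true, n)
  capacitance <- rep_len(capacitance, n)
  psi_f <- psi_i * exp(-(k_true / 1000) * t_s / capacitance)
  if (noise_sd_psi > 0) {
    psi_f <- with_seed_if(seed, {
      cand <- psi_f + rnorm(n, 0, noise_sd_psi)
      pmin(pmax(cand, psi_i), -1e-4)  # keep within (psi_i, 0)
    })
  }
  trials <- tibble::tibble(psi_check_a = psi_i, psi_check_b = psi_i,
                           psi_i = psi_i, psi_f = psi_f, t_s = t_s)
  list(trials = trials,
       truth = list(generator = "gen_rehydration", k_true = k_true,
                    capacitance = capacitance, seed = seed))
}

#' Synthetic vulnerability-curve observations
#'
#' Samples a Weibull embolism curve (percent, clipped to `[0, 100]`) or a
#' sigmoidal conductance-decline curve (clipped to `>= 0`) on a grid of water
#' potentials, with additive Gaussian noise.
#'
#' @param model `"weibull"` or `"sigmoid"`.
#' @param params A [weibull_params()] or [sigmoid_params()] object.
#' @param psi_grid Water potentials (MPa, < 0).
#' @param noise_sd Gaussian SD on the response.
#' @param kmax Maximum conductance (sigmoid model only).
#' @param seed Integer seed.
#' @return List with `data` (tibble: `psi`/`percent` for Weibull,
#'   `psi_i`/`kleaf` for sigmoid) and `truth` (including the closed-form
#'   `psi50`).
#' @export
gen_vc_observations <- function(model = c("weibull", "sigmoid"), params,
                                psi_grid, noise_sd = 0, kmax = 16.4,
                                seed = NULL) {
  model <- match.arg(model)
  if (any(psi_grid >= 0)) stop_input("`psi_grid` must be < 0")
  n <- length(psi_grid)
  if (model == "weibull") {
    y <- 100 * weibull_fraction(-psi_grid, params)
    if (noise_sd > 0) y <- with_seed_if(seed, y + rnorm(n, 0, noise_sd))
    y <- pmin(pmax(y, 0), 100)
    data <- tibble::tibble(psi = psi_grid, percent = y, method = "synthetic")
    class(data) <- c("ov_curve", class(data))
    psi50 <- -weibull_px(params, 50)
  } else {
    y <- kmax * sigmoid_relcond(psi_grid, params)
    if (noise_sd > 0) y <- with_seed_if(seed, y + rnorm(n, 0, noise_sd))
    y <- pmax(y, 0)
    data <- tibble::tibble(psi_i = psi_grid, kleaf = y)
    psi50 <- params$psi50
  }
  list(data = data,
       truth = list(generator = "gen_vc_observations", model = model,
                    params = unclass(params), kmax = kmax, psi50 = psi50,
                    noise_sd = noise_sd, seed = seed))
}

#' Regular grid of labeled vein segments for stack simulation
#'
#' Horizontal veins at evenly spaced rows, each split into fixed-length
#' segments with unique integer labels. The defaults (12 veins of 4-px
#' segments on a 96-px grid) give enough independent embolism events for
#' stable curve fits and, at 0.02 mm per pixel, a vein length density of
#' about 6.2 mm mm-2. Segments must not be smaller than the detector's
#' minimum component size.
#'
#' @param nrow,ncol Image size in pixels.
#' @param n_veins Number of parallel veins.
#' @param segment_len Segment length (px).
#' @return Integer matrix (0 = background, k = segment id).
#' @export
gen_vein_template <- function(nrow = 96, ncol = 96, n_veins = 12,
                              segment_len = 4) {
  tpl <- matrix(0L, nrow, ncol)
  rows <- round(seq(4, nrow - 3, length.out = n_veins))
  id <- 0L
  for (r in rows) {
    starts <- seq(1, ncol, by = segment_len)
    for (s in starts) {
      id <- id + 1L
      tpl[r, s:min(s + segment_len - 1L, ncol)] <- id
    }
  }
  tpl
}

#' Synthetic optical-vulnerability image stack with scripted embolism events
#'
#' Each vein segment of the template is assigned an embolism tension drawn
#' from a Weibull distribution; the segment brightens by `event_intensity`
#' in the first frame whose interpolated water potential has passed its
#' threshold. Gaussian pixel noise is added on top of a constant background.
#' Segments already past threshold at the first frame are bright from the
#' start and never counted as events; segments never reached stay dark.
#'
#' @param vein_template Integer matrix of segment labels (0 = background) as
#'   from [gen_vein_template()], or a binary matrix (connected components
#'   become segments).
#' @param event_psi_model A [weibull_params()] for the tension thresholds.
#' @param psi_series Data frame `time_s`, `psi_mpa` covering the imaging
#'   period; default: linear decline from -0.5 to -8 MPa over the stack.
#' @param n_frames Number of frames.
#' @param frame_interval_s Seconds between frames (default 300, i.e. 5 min).
#' @param event_intensity Brightening per event (intensity units).
#' @param noise_sd_intensity Gaussian pixel noise SD.
#' @param pixel_size_mm Physical pixel size.
#' @param seed Integer seed.
#' @return List with `stack` (an [ov_stack()]), `truth` (ground-truth trace
#'   tibble `time`, `new_px`, `cum_px`; segment tensions and event frames;
#'   parameters; seed) and `template`.
#' @export
gen_ov_stack <- function(vein_template = gen_vein_template(),
                         event_psi_model = weibull_params(4.768, 3),
                         psi_series = NULL, n_frames = 40,
                         frame_interval_s = 300, event_intensity = 0.2,
                         noise_sd_intensity = 0, pixel_size_mm = 0.02,
                         seed = NULL) {
  tpl <- vein_template
  if (all(tpl %in% c(0, 1))) tpl <- label8(tpl != 0)  # blank template -> blank stack
  times <- (seq_len(n_frames) - 1) * frame_interval_s
  if (is.null(psi_series)) {
    psi_series <- tibble::tibble(time_s = c(0, max(times)), psi_mpa = c(-0.5, -8))
  }
  psi_frames <- psi_at(times, psi_series)
  seg_ids <- sort(unique(tpl[tpl > 0L]))
  n_seg <- length(seg_ids)

  out <- with_seed_if(seed, {
    tensions <- rweibull(n_seg, shape = event_psi_model$shape_c,
                         scale = event_psi_model$scale_b)
    event_frame <- vapply(tensions, function(tau) {
      hit <- which(psi_frames <= -tau)
      if (length(hit) == 0) NA_integer_ else hit[1]
    }, integer(1))
    seg_px <- lapply(seg_ids, function(id) which(tpl == id))
    base <- matrix(0.3, nrow(tpl), ncol(tpl))
    frames <- lapply(seq_len(n_frames), function(i) {
      f <- base
      lit <- which(!is.na(event_frame) & event_frame <= i)
      for (s in lit) f[seg_px[[s]]] <- f[seg_px[[s]]] + event_intensity
      if (noise_sd_intensity > 0) {
        f <- f + matrix(rnorm(length(f), 0, noise_sd_intensity), nrow(f))
      }
      f
    })
    list(tensions = tensions, event_frame = event_frame,
         seg_px = seg_px, frames = frames)
  })

  seg_sizes <- vapply(out$seg_px, length, integer(1))
  new_px <- integer(n_frames)
  countable <- !is.na(out$event_frame) & out$event_frame >= 2L
  for (s in which(countable)) {
    new_px[out$event_frame[s]] <- new_px[out$event_frame[s]] + seg_sizes[s]
  }
  truth_trace <- tibble::tibble(time = times, new_px = new_px,
                                cum_px = cumsum(new_px))
  stack <- ov_stack(out$frames, times, pixel_size_mm)
  list(stack = stack,
       truth = list(generator = "gen_ov_stack", trace = truth_trace,
                    tensions = out$tensions, event_frame = out$event_frame,
                    event_psi_model = unclass(event_psi_model),
                    psi50 = -weibull_px(event_psi_model, 50),
                    event_intensity = event_intensity,
                    noise_sd_intensity = noise_sd_intensity, seed = seed),
       template = tpl, psi_series = psi_series)
}

#' Synthetic gas-exchange data with known closure threshold
#'
#' Drought-group conductances follow a log-logistic decline with zero lower
#' asymptote and multiplicative lognormal noise (unit mean, coefficient of
#' variation `noise_cv`); control plants sit near -1.0 MPa at the upper
#' asymptote. The closed-form truth for the water potential of 95% closure
#' (relative to a reference `g_max = upper_g`) is
#' `-ed50 * 19^(1/slope_b)`.
#'
#' @param upper_g Upper conductance asymptote (mmol m-2 s-1).
#' @param slope_b Log-logistic steepness.
#' @param ed50 Tension at 50% closure (MPa).
#' @param n_drought,n_control Group sizes.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param psi_range Range (MPa) of drought-group water potentials (uniform).
#' @param seed Integer seed.
#' @return List with `data` (tibble `psi`, `g_leaf`, `group`) and `truth`
#'   (including `psi_g95`).
#' @export
gen_stomatal <- function(upper_g = 400, slope_b = 6, ed50 = 1.108,
                         n_drought = 60, n_control = 10, noise_cv = 0.05,
                         psi_range = c(-2.5, -0.3), seed = NULL) {
  if (slope_b <= 0) stop_input("`slope_b` must be > 0")
  params <- loglogistic_params(0, upper_g, slope_b, ed50)
  out <- with_seed_if(seed, {
    psi_d <- runif(n_drought, min(psi_range), max(psi_range))
    g_d <- loglogistic_g(psi_d, params)
    psi_c <- pmin(rnorm(n_control, -1.0, 0.05), -0.5)
    g_c <- rep(upper_g, n_control)
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      fac <- function(n) exp(rnorm(n, -sdlog^2 / 2, sdlog))
      g_d <- g_d * fac(n_drought)
      g_c <- g_c * fac(n_control)
    }
    tibble::tibble(
      psi = c(psi_d, psi_c),
      g_leaf = c(g_d, g_c),
      group = rep(c("drought", "control"), c(n_drought, n_control))
    )
  })
  list(data = out,
       truth = list(generator = "gen_stomatal", upper_g = upper_g,
                    slope_b = slope_b, ed50 = ed50, noise_cv = noise_cv,
                    psi_g95 = -ed50 * 19^(1 / slope_b), seed = seed))
}

#' Generate a complete synthetic study bundle
#'
#' Produces every input the trait pipeline consumes — five pressure-volume
#' curves, rehydration trials, three optical-vulnerability stacks (one per
#' water-potential method) and a gas-exchange table — with one master seed
#' and a combined truth record. Defaults mirror the trait values the
#' generators are parameterized around (SWC 2.4, pi0 -1.5 MPa, AWF 0.386,
#' C_FT 0.37 mol m-2 MPa-1, K_max 16.4, 50% embolism near -4.2 MPa, 95%
#' closure near -1.81 MPa).
#'
#' @param seed Master integer seed.
#' @param n_pv_leaves Number of pressure-volume curves.
#' @param noise Logical: add realistic measurement noise (default TRUE).
#' @return List with `pv` (list of [gen_pv_curve()] results), `rehydration`,
#'   `ov` (named list of [gen_ov_stack()] results), `stomatal`, and `truth`.
#' @export
gen_study_bundle <- function(seed = 1, n_pv_leaves = 5, noise = TRUE) {
  s <- as.integer(seed)
  base <- gen_pv_curve()  # noise-free reference leaf
  mass_noise <- 0.005 * (1 - base$truth$awf) * base$truth$swc * base$truth$dry_weight_g
  pv <- lapply(seq_len(n_pv_leaves), function(i) {
    gen_pv_curve(n_points = 40, noise_sd_mass = if (noise) mass_noise else 0,
                 seed = s + i)
  })
  ref <- analyze_pv(base$curve)
  psi_i <- rep(seq(-0.5, -2.4, by = -0.1), 2)
  kleaf_model <- sigmoid_params(-1.35, 3)
  reh <- gen_rehydration(
    k_true = 16.4 * sigmoid_relcond(psi_i, kleaf_model),
    capacitance = ifelse(psi_i > ref$psi_tlp, ref$c_leaf_ft, ref$c_leaf_tlp),
    psi_i = psi_i,
    noise_sd_psi = if (noise) 0.005 else 0, seed = s + 20)
  reh$truth$psi50_k <- kleaf_model$psi50
  reh$truth$k_max <- 16.4
  methods <- c("pressure_chamber", "dewpoint_hygrometer", "psychrometer")
  ov <- lapply(seq_along(methods), function(i) {
    gen_ov_stack(noise_sd_intensity = if (noise) 0.01 else 0, seed = s + 30 + i)
  })
  names(ov) <- methods
  stom <- gen_stomatal(noise_cv = if (noise) 0.05 else 0, seed = s + 40)
  list(pv = pv, rehydration = reh, ov = ov, stomatal = stom,
       truth = list(seed = s, psi_tlp = pv[[1]]$truth$psi_tlp,
                    pi0 = pv[[1]]$truth$pi0,
                    psi50_xe = ov[[1]]$truth$psi50,
                    psi_g95 = stom$truth$psi_g95,
                    psi50_k = reh$truth$psi50_k,
                    k_max = reh$truth$k_max))
}
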