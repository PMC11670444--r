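#' Construct an optical-vulnerability image stack
#'
#' Time-lapse transmitted-light frames of a dehydrating leaf. Embolism events
#' appear as abrupt local intensity changes between consecutive frames.
#'
#' @param frames A list of numeric matrices (grayscale intensities) of
#'   identical dimensions, or a 3D array with frames along the third margin.
#' @param timestamps Seconds from the start of imaging, strictly increasing,
#'   one per frame.
#' @param pixel_size_mm Physical pixel size (mm per pixel).
#' @return An object of class `ov_stack`.
#' @export
ov_stack <- function(frames, timestamps, pixel_size_mm = 1) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  }
  if (!is.list(frames) || length(frames) < 2) {
    stop_input("`frames` must hold at least 2 frames")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_input("all frames must have identical dimensions")
  }
  if (length(timestamps) != length(frames) || any(diff(timestamps) <= 0)) {
    stop_input("`timestamps` must be strictly increasing, one per frame")
  }
  check_number(pixel_size_mm, "pixel_size_mm")
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 pixel_size_mm = pixel_size_mm),
            class = "ov_stack")
}

#' @export
print.ov_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<ov_stack> %d frames of %dx%d px, %.0f s span, %.4g mm/px\n",
              length(x$frames), d[1], d[2], diff(range(x$timestamps)),
              x$pixel_size_mm))
  invisible(x)
}

# zero-filled shift of a matrix by (dr, dc)
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# label connected components of a logical matrix under 8-connectivity;
# returns an integer matrix of labels (0 = background)
label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(FALSE, nr + 2, nc + 2)
  padded[2:(nr + 1), 2:(nc + 1)] <- mask
  lab <- matrix(0L, nr + 2, nc + 2)
  nrp <- nr + 2
  offsets <- c(-1L, 1L, -nrp, nrp, -nrp - 1L, -nrp + 1L, nrp - 1L, nrp + 1L)
  todo <- which(padded)
  current <- 0L
  for (seed_px in todo) {
    if (lab[seed_px] != 0L) next
    current <- current + 1L
    frontier <- seed_px
    lab[frontier] <- current
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, offsets, `+`)))
      nb <- nb[padded[nb] & lab[nb] == 0L]
      lab[nb] <- current
      frontier <- nb
    }
  }
  lab[2:(nr + 1), 2:(nc + 1)]
}

#' Detect embolism events in an optical-vulnerability stack
#'
#' For each consecutive frame pair the absolute intensity difference is
#' thresholded and cleaned of small connected components (8-connectivity);
#' surviving pixels are counted as new embolism events and accumulated over
#' frames.
#'
#' @param stack An [ov_stack()].
#' @param diff_threshold Intensity threshold applied to the absolute frame
#'   difference (strictly greater-than). `NULL` (default) sets it to 3 times
#'   the robust noise SD ([stats::mad()] of the signed differences) estimated
#'   from the first (up to) 5 frame pairs.
#' @param min_component_px Minimum surviving connected-component size in
#'   pixels (default 4).
#' @return An `embolism_trace` tibble with one row per frame: `time`,
#'   `new_px`, `cum_px`; the final cumulative count is carried in the
#'   `total_px` attribute.
#' @export
detect_events <- function(stack, diff_threshold = NULL, min_component_px = 4) {
  stopifnot(inherits(stack, "ov_stack"))
  n <- length(stack$frames)
  diffs <- lapply(seq_len(n - 1), function(i) {
    stack$frames[[i + 1]] - stack$frames[[i]]
  })
  if (is.null(diff_threshold)) {
    first <- diffs[seq_len(min(5, length(diffs)))]
    diff_threshold <- 3 * mad(unlist(first))
  }
  new_px <- integer(n)
  for (i in seq_along(diffs)) {
    mask <- abs(diffs[[i]]) > diff_threshold
    if (any(mask) && min_component_px > 1) {
      lab <- label8(mask)
      sizes <- tabulate(lab[lab > 0L])
      keep <- which(sizes >= min_component_px)
      mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
    }
    new_px[i + 1] <- sum(mask)
  }
  trace <- tibble::tibble(time = stack$timestamps, new_px = new_px,
                          cum_px = cumsum(new_px))
  attr(trace, "total_px") <- sum(new_px)
  attr(trace, "diff_threshold") <- diff_threshold
  class(trace) <- c("embolism_trace", class(trace))
  trace
}

#' Interpolate a water-potential series at given times
#'
#' Piecewise-linear interpolation of a concurrent water-potential record at
#' arbitrary times. Extrapolation beyond the record is refused.
#'
#' @param times Seconds from start; must lie within the record's time span.
#' @param series Data frame with columns `time_s` (strictly increasing) and
#'   `psi_mpa` (< 0).
#' @return Water potentials (MPa) at `times`.
#' @export
psi_at <- function(times, series) {
  if (!all(c("time_s", "psi_mpa") %in% names(series))) {
    stop_input("`series` must have columns time_s and psi_mpa")
  }
  if (nrow(series) < 2 || any(diff(series$time_s) <= 0)) {
    stop_input("`series` needs >= 2 samples with strictly increasing time")
  }
  outside <- times < min(series$time_s) | times > max(series$time_s)
  if (any(outside)) {
    stop_input("cannot extrapolate water potential for ", sum(outside),
               " time(s) outside the series range")
  }
  approx(series$time_s, series$psi_mpa, xout = times)$y
}

#' Build an optical vulnerability curve from a trace and a Psi series
#'
#' Converts cumulative embolized pixel counts to percent of the experiment's
#' final cumulative area and attaches the concurrently measured leaf water
#' potential by linear interpolation in time. Frames outside the water
#' potential record are dropped with a warning.
#'
#' @param trace An `embolism_trace` from [detect_events()].
#' @param series A water-potential series (see [psi_at()]).
#' @param method Label for the water-potential method (e.g.
#'   `"pressure_chamber"`, `"dewpoint_hygrometer"`, `"psychrometer"`).
#' @return An `ov_curve` tibble: `psi`, `percent`, `time`, `method`.
#' @export
build_ov_curve <- function(trace, series, method = "pooled") {
  total <- attr(trace, "total_px") %||% max(trace$cum_px)
  if (total == 0) stop_input("no embolism detected (total cumulative area is zero)")
  inside <- trace$time >= min(series$time_s) & trace$time <= max(series$time_s)
  if (any(!inside)) {
    warn(paste0(sum(!inside), " frame(s) outside the water-potential record dropped"))
  }
  kept <- trace[inside, , drop = FALSE]
  out <- tibble::tibble(
    psi = psi_at(kept$time, series),
    percent = 100 * kept$cum_px / total,
    time = kept$time,
    method = method
  )
  class(out) <- c("ov_curve", class(out))
  out
}

#' Fit an optical vulnerability curve
#'
#' Weibull fit (on tension) of percent embolized area versus water potential;
#' the water potential at 50% embolism is the negated fitted 50% tension,
#' with a percentile-bootstrap confidence interval.
#'
#' @param curve An `ov_curve` (or any data frame with `psi` and `percent`),
#'   >= 6 observations spanning the 50% point.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return List of class `ov_fit`: `fit` (a `vc_fit`), `psi50_xe`, `ci`
#'   (a `boot_ci` on `psi50_xe`), `method`.
#' @export
fit_ov <- function(curve, n_boot = 1000, seed = NULL) {
  d <- tibble::tibble(x = curve$psi, y = curve$percent)
  fit <- fit_curve(d, "weibull")
  if (!fit$converged) stop_input("optical vulnerability fit did not converge")
  stat <- function(df) {
    f <- fit_curve(df, "weibull")
    if (!f$converged) return(NA_real_)
    fitted_psi50(f)
  }
  ci <- bootstrap_ci(d, stat, n_boot = n_boot, seed = seed)
  method <- if ("method" %in% names(curve)) curve$method[1] else "pooled"
  structure(list(fit = fit, psi50_xe = fitted_psi50(fit), ci = ci,
                 method = method), class = "ov_fit")
}

#' @export
print.ov_fit <- function(x, ...) {
  cat(sprintf("<ov_fit> [%s] psi50_xe = %.3f MPa  95%% CI [%.3f, %.3f]  R2 = %.3f\n",
              x$method, x$psi50_xe, x$ci$lo, x$ci$hi, x$fit$r2))
  invisible(x)
}

#' Pool per-method optical vulnerability curves and compare their fits
#'
#' Fits each per-method curve, fits the pooled union of observations, and
#' flags pairwise differences in the 50%-embolism water potential where the
#' bootstrap confidence intervals do not overlap.
#'
#' @param curves Named list of `ov_curve` objects (one per water-potential
#'   method).
#' @param n_boot,seed Passed to [fit_ov()] (the seed is varied per fit).
#' @return List of class `ov_comparison`: `per_method` (named list of
#'   `ov_fit`), `pooled_curve`, `pooled_fit`, and `comparisons` (tibble with
#'   `method_a`, `method_b`, `different`).
#' @export
pool_and_compare <- function(curves, n_boot = 1000, seed = NULL) {
  if (length(curves) < 1) stop_input("need at least one curve")
  if (is.null(names(curves))) {
    names(curves) <- vapply(curves, function(cv) {
      if ("method" %in% names(cv)) as.character(cv$method[1]) else "unnamed"
    }, character(1))
  }
  seeds <- if (is.null(seed)) vector("list", length(curves) + 1) else
    as.list(seed + seq_len(length(curves) + 1))
  fits <- lapply(seq_along(curves), function(i) {
    fit_ov(curves[[i]], n_boot = n_boot, seed = seeds[[i]])
  })
  names(fits) <- names(curves)
  pooled_curve <- dplyr::bind_rows(curves) |> dplyr::mutate(method = "pooled")
  class(pooled_curve) <- unique(c("ov_curve", class(pooled_curve)))
  pooled_fit <- fit_ov(pooled_curve, n_boot = n_boot,
                       seed = seeds[[length(seeds)]])
  pairs <- utils::combn(names(fits), 2, simplify = FALSE)
  comparisons <- purrr::map_dfr(pairs, function(p) {
    tibble::tibble(method_a = p[1], method_b = p[2],
                   different = cis_overlap(fits[[p[1]]]$ci, fits[[p[2]]]$ci))
  })
  structure(list(per_method = fits, pooled_curve = pooled_curve,
                 pooled_fit = pooled_fit, comparisons = comparisons),
            class = "ov_comparison")
}

# Zhang-Suen binary thinning to 1-px centerlines
skeletonize <- function(mask) {
  m <- mask != 0
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift_mat(m, -1, 0); p3 <- shift_mat(m, -1, 1)
      p4 <- shift_mat(m, 0, 1);  p5 <- shift_mat(m, 1, 1)
      p6 <- shift_mat(m, 1, 0);  p7 <- shift_mat(m, 1, -1)
      p8 <- shift_mat(m, 0, -1); p9 <- shift_mat(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- if (step == 1) {
        p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      del <- m & b >= 2 & b <= 6 & a == 1 & cond
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Vein length density from a binary vein mask
#'
#' Thins the mask to 1-pixel centerlines (Zhang-Suen), measures skeleton
#' length as the pixel count with a `sqrt(2)` weighting of diagonal steps
#' (`L = N_px + (sqrt(2) - 1) * N_diagonal_pairs`, in pixels), and divides by
#' leaf area.
#'
#' @param mask Binary matrix (non-zero = vein). May be a full vein mask (for
#'   total vein density) or a cumulative embolism mask (for embolized vein
#'   density).
#' @param pixel_size_mm Physical pixel size (mm per pixel).
#' @param leaf_area_mm2 Leaf area (mm^2), > 0.
#' @param thin Set `FALSE` if `mask` is already a 1-px skeleton.
#' @return Density (mm of vein per mm^2 of leaf).
#' @examples
#' m <- matrix(0, 20, 110); m[10, 6:105] <- 1
#' vein_length_density(m, pixel_size_mm = 0.01, leaf_area_mm2 = 1)  # 1.0
#' @export
vein_length_density <- function(mask, pixel_size_mm, leaf_area_mm2, thin = TRUE) {
  check_number(pixel_size_mm, "pixel_size_mm")
  check_number(leaf_area_mm2, "leaf_area_mm2")
  if (leaf_area_mm2 <= 0) stop_input("`leaf_area_mm2` must be > 0")
  m <- mask != 0
  if (!any(m)) {
    warn("empty vein mask: density is 0")
    return(0)
  }
  skel <- if (thin) skeletonize(m) else m
  n_px <- sum(skel)
  d_pairs <- sum(skel & shift_mat(skel, 1, 1)) + sum(skel & shift_mat(skel, 1, -1))
  length_mm <- (n_px + (sqrt(2) - 1) * d_pairs) * pixel_size_mm
  length_mm / leaf_area_mm2
}
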