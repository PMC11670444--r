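#' @name io
#' @title Delimited-text readers and writers
#'
#' @description
#' All tabular artifacts travel as comma-separated UTF-8 text with a mandatory
#' header row, `.` decimal separator, water potentials in MPa (negative) and
#' times in seconds. Readers reject files with unknown columns unless
#' `permissive = TRUE`; small key-value metadata rides in leading `# key: value`
#' comment lines. Numeric round trips through [readr] are exact (shortest
#' float representation).
NULL

check_columns <- function(df, required, optional = character(), permissive = FALSE,
                          what = "file") {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_input(what, " is missing required column(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), c(required, optional))
  if (length(extra) && !permissive) {
    stop_input(what, " has unknown column(s): ", paste(extra, collapse = ", "),
               " (set permissive = TRUE to ignore)")
  }
  df[intersect(c(required, optional), names(df))]
}

read_csv_meta <- function(path) {
  lines <- readr::read_lines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      val <- suppressWarnings(as.numeric(m[3]))
      meta[[m[2]]] <- if (is.na(val)) m[3] else val
    }
  }
  body <- readr::read_csv(I(paste(lines[!grepl("^#", lines)], collapse = "\n")),
                          show_col_types = FALSE, progress = FALSE)
  list(meta = meta, data = body)
}

write_csv_meta <- function(data, path, meta = list()) {
  header <- vapply(names(meta), function(k) paste0("# ", k, ": ", meta[[k]]),
                   character(1))
  body <- readr::format_csv(data)
  readr::write_lines(c(header, sub("\n$", "", body)), path)
  invisible(path)
}

#' Read one pressure-volume curve from CSV
#'
#' Expects columns `psi_mpa` and `fresh_mass_g` plus metadata either in
#' leading comment lines (`# leaf_area_mm2: 69.7` etc.) or as arguments
#' (arguments win).
#'
#' @param path CSV file path.
#' @param leaf_area_mm2,dry_weight_g,saturated_mass_g Leaf metadata; override
#'   any in-file metadata.
#' @param permissive Allow unknown columns.
#' @return A [pv_curve()].
#' @export
read_pv_csv <- function(path, leaf_area_mm2 = NULL, dry_weight_g = NULL,
                        saturated_mass_g = NULL, permissive = FALSE) {
  parsed <- read_csv_meta(path)
  df <- check_columns(parsed$data, c("psi_mpa", "fresh_mass_g"),
                      permissive = permissive, what = basename(path))
  area <- leaf_area_mm2 %||% parsed$meta$leaf_area_mm2
  dw <- dry_weight_g %||% parsed$meta$dry_weight_g
  sat <- saturated_mass_g %||% parsed$meta$saturated_mass_g
  if (is.null(area) || is.null(dw)) {
    stop_input(basename(path), ": leaf_area_mm2 and dry_weight_g must be given ",
               "as arguments or `# key: value` metadata lines")
  }
  pv_curve(df, leaf_area_mm2 = area, dry_weight_g = dw, saturated_mass_g = sat)
}

#' Write a pressure-volume curve to CSV (metadata in comment lines)
#'
#' @param curve A [pv_curve()].
#' @param path Output path.
#' @export
write_pv_csv <- function(curve, path) {
  stopifnot(inherits(curve, "pv_curve"))
  write_csv_meta(
    tibble::tibble(psi_mpa = curve$points$psi, fresh_mass_g = curve$points$mass_g),
    path,
    meta = list(schema = "pv_curve_v1",
                leaf_area_mm2 = curve$leaf_area_mm2,
                dry_weight_g = curve$dry_weight_g,
                saturated_mass_g = curve$saturated_mass_g))
}

#' Read rehydration trials from CSV
#'
#' Columns: `psi_check_a`, `psi_check_b`, `psi_i`, `psi_f`, `t_s`.
#'
#' @inheritParams read_pv_csv
#' @return Tibble of trials.
#' @export
read_rehydration_csv <- function(path, permissive = FALSE) {
  check_columns(read_csv_meta(path)$data,
                c("psi_i", "psi_f", "t_s"),
                optional = c("psi_check_a", "psi_check_b"),
                permissive = permissive, what = basename(path))
}

#' Read a water-potential time series from CSV
#'
#' Columns: `time_s`, `psi_mpa`, optional `method`.
#'
#' @inheritParams read_pv_csv
#' @return Tibble usable by [psi_at()].
#' @export
read_psi_series_csv <- function(path, permissive = FALSE) {
  check_columns(read_csv_meta(path)$data, c("time_s", "psi_mpa"),
                optional = "method", permissive = permissive,
                what = basename(path))
}

#' Read gas-exchange observations from CSV
#'
#' Columns: `psi_mpa`, `g_mmol`, `group` (`control`/`drought`); returned with
#' the column names the stomatal functions use (`psi`, `g_leaf`, `group`).
#'
#' @inheritParams read_pv_csv
#' @return Tibble for [stomatal_response()].
#' @export
read_gas_exchange_csv <- function(path, permissive = FALSE) {
  df <- check_columns(read_csv_meta(path)$data, c("psi_mpa", "g_mmol", "group"),
                      permissive = permissive, what = basename(path))
  if (!all(df$group %in% c("control", "drought"))) {
    stop_input(basename(path), ": `group` must be 'control' or 'drought'")
  }
  tibble::tibble(psi = df$psi_mpa, g_leaf = df$g_mmol, group = df$group)
}

#' Read an optical-vulnerability stack from a multi-page TIFF
#'
#' @param tiff_path Multi-page grayscale TIFF.
#' @param timestamps_csv CSV with column `time_s` (one row per frame);
#'   may carry `# pixel_size_mm:` metadata.
#' @param pixel_size_mm Overrides metadata.
#' @return An [ov_stack()].
#' @export
read_ov_stack <- function(tiff_path, timestamps_csv, pixel_size_mm = NULL) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # first channel of RGB(A)
    p
  })
  parsed <- read_csv_meta(timestamps_csv)
  ts <- check_columns(parsed$data, "time_s", what = basename(timestamps_csv))
  px <- pixel_size_mm %||% parsed$meta$pixel_size_mm %||% 1
  ov_stack(frames, ts$time_s, pixel_size_mm = px)
}

#' Write an optical-vulnerability stack as multi-page TIFF + timestamps CSV
#'
#' Intensities are clipped to `[0, 1]` and stored as 32-bit float, so image
#' round trips are exact to single precision (~1e-7), unlike the CSV
#' artifacts which round-trip exactly.
#'
#' @param stack An [ov_stack()].
#' @param tiff_path,timestamps_csv Output paths.
#' @export
write_ov_stack <- function(stack, tiff_path, timestamps_csv) {
  stopifnot(inherits(stack, "ov_stack"))
  frames <- lapply(stack$frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, tiff_path, bits.per.sample = 32)
  write_csv_meta(tibble::tibble(time_s = stack$timestamps), timestamps_csv,
                 meta = list(schema = "ov_timestamps_v1",
                             pixel_size_mm = stack$pixel_size_mm))
}

#' Write an embolism trace (with optional curve columns) to CSV
#'
#' @param trace An `embolism_trace` or `ov_curve`.
#' @param path Output path.
#' @export
write_trace_csv <- function(trace, path) {
  write_csv_meta(tibble::as_tibble(trace), path,
                 meta = list(schema = "embolism_trace_v1",
                             total_px = attr(trace, "total_px") %||% NA))
}

#' Serialize a fitted curve (with bootstrap CI) to JSON
#'
#' @param fit A `vc_fit`, `ov_fit` or `kleaf_vc` object.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  rec <- if (inherits(fit, "vc_fit")) {
    list(model = fit$model, params = as.list(fit$coef), r2 = fit$r2,
         n_obs = fit$n_obs, converged = fit$converged)
  } else if (inherits(fit, "ov_fit")) {
    list(model = "weibull", method = fit$method, psi50_xe = fit$psi50_xe,
         params = as.list(fit$fit$coef), r2 = fit$fit$r2,
         ci_lo = fit$ci$lo, ci_hi = fit$ci$hi, n_boot = fit$ci$n_boot,
         seed = fit$ci$seed)
  } else if (inherits(fit, "kleaf_vc")) {
    list(model = "sigmoid", psi50_k = fit$psi50_k,
         params = as.list(fit$fit$coef), r2 = fit$fit$r2,
         ci_lo = fit$ci$lo, ci_hi = fit$ci$hi, n_boot = fit$ci$n_boot,
         seed = fit$ci$seed)
  } else stop_input("unsupported fit object")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
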