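#' Run the full leaf-hydraulics trait pipeline
#'
#' Executes the stages in dependency order — pressure-volume elaboration,
#' rehydration-kinetics conductance (which needs the capacitances and turgor
#' loss point from the previous stage), optical vulnerability, stomatal
#' response — and assembles the derived threshold sequence including the
#' stomatal safety margin. A failing stage is recorded in `$errors` and the
#' remaining independent stages still run.
#'
#' @param bundle Study inputs, either as produced by [gen_study_bundle()] or
#'   a list with the same shape: `pv` (list of [pv_curve()] objects, file
#'   paths, or `gen_pv_curve()` results), `rehydration` (trials data frame,
#'   path, or `gen_rehydration()` result), `ov` (named list; each element a
#'   `gen_ov_stack()` result or a list with `stack` and `psi_series`), and
#'   `stomatal` (data frame, path, or `gen_stomatal()` result).
#' @param seed Master integer seed for the bootstrap stages.
#' @param n_boot_vc Bootstrap replicates for the vulnerability fits
#'   (default 1000).
#' @param n_boot_g Bootstrap replicates for the stomatal closure estimate
#'   (default 999).
#' @param diff_threshold,min_component_px Passed to [detect_events()].
#' @return A `trait_report` list: `pv_traits` (per leaf), `pv_summary`,
#'   `kleaf_points`, `kleaf_max`, `kleaf` (the fitted `kleaf_vc`), `ov` (an
#'   `ov_comparison`), `stomatal` (a `stomatal_result` row), `ssm`,
#'   `thresholds` (ordered tibble of the critical water potentials),
#'   `errors`, `seed`, `version`.
#' @export
run_pipeline <- function(bundle, seed = 1, n_boot_vc = 1000, n_boot_g = 999,
                         diff_threshold = NULL, min_component_px = 4) {
  errors <- list()
  note_error <- function(stage, e) {
    errors[[stage]] <<- conditionMessage(e)
    NULL
  }
  as_curve <- function(el) {
    if (inherits(el, "pv_curve")) el
    else if (is.character(el)) read_pv_csv(el)
    else if (is.list(el) && inherits(el$curve, "pv_curve")) el$curve
    else stop_input("cannot interpret pressure-volume input")
  }

  pv_traits <- tryCatch({
    curves <- lapply(bundle$pv, as_curve)
    dplyr::bind_rows(lapply(curves, analyze_pv))
  }, error = function(e) note_error("pv", e))
  pv_summary <- if (!is.null(pv_traits)) pv_traits_summary(pv_traits)

  kleaf_points <- kleaf_fit <- kleaf_max_val <- NULL
  if (!is.null(pv_traits)) {
    kleaf_points <- tryCatch({
      reh <- bundle$rehydration
      trials <- if (is.character(reh)) read_rehydration_csv(reh)
                else if (is.data.frame(reh)) reh
                else reh$trials
      kleaf_eq1(trials,
                c_ft = mean(pv_traits$c_leaf_ft),
                c_tlp = mean(pv_traits$c_leaf_tlp),
                psi_tlp = mean(pv_traits$psi_tlp))
    }, error = function(e) note_error("rehydration", e))
  } else errors[["rehydration"]] <- "skipped: pressure-volume stage failed"
  if (!is.null(kleaf_points)) {
    kleaf_max_val <- tryCatch(max_kleaf(kleaf_points),
                              error = function(e) note_error("rehydration", e))
    kleaf_fit <- tryCatch(
      fit_kleaf_vc(kleaf_points, n_boot = n_boot_vc, seed = seed + 1),
      error = function(e) note_error("rehydration", e))
  }

  ov_cmp <- tryCatch({
    curves <- lapply(bundle$ov, function(el) {
      stack <- if (inherits(el, "ov_stack")) el else el$stack
      series <- el$psi_series %||% el$series
      trace <- detect_events(stack, diff_threshold = diff_threshold,
                             min_component_px = min_component_px)
      build_ov_curve(trace, series)
    })
    for (i in seq_along(curves)) curves[[i]]$method <- names(bundle$ov)[i]
    pool_and_compare(curves, n_boot = n_boot_vc, seed = seed + 100)
  }, error = function(e) note_error("optical", e))
  psi50_xe <- if (!is.null(ov_cmp)) ov_cmp$pooled_fit$psi50_xe

  stomatal <- tryCatch({
    st <- bundle$stomatal
    gx <- if (is.character(st)) read_gas_exchange_csv(st)
          else if (is.data.frame(st)) st
          else st$data
    stomatal_response(gx, n_boot = n_boot_g, seed = seed + 200,
                      psi50_xe = psi50_xe)
  }, error = function(e) note_error("stomatal", e))

  ssm <- if (!is.null(stomatal) && !is.null(psi50_xe)) stomatal$ssm[1]
  thresholds <- tibble::tibble(
    threshold = c("psi_tlp", "psi50_k", "psi_g95", "psi50_xe"),
    psi_mpa = c(if (!is.null(pv_traits)) mean(pv_traits$psi_tlp) else NA_real_,
                if (!is.null(kleaf_fit)) kleaf_fit$psi50_k else NA_real_,
                if (!is.null(stomatal)) stomatal$psi_g95_mean[1] else NA_real_,
                psi50_xe %||% NA_real_))

  structure(list(
    pv_traits = pv_traits, pv_summary = pv_summary,
    kleaf_points = kleaf_points, kleaf_max = kleaf_max_val, kleaf = kleaf_fit,
    ov = ov_cmp, stomatal = stomatal, ssm = ssm,
    thresholds = thresholds, errors = errors, seed = seed,
    version = as.character(utils::packageVersion("leafhydraulics"))
  ), class = "trait_report")
}

#' @export
print.trait_report <- function(x, ...) {
  cat("<trait_report> leafhydraulics", x$version, " (seed", x$seed, ")\n")
  if (!is.null(x$pv_summary)) {
    cat("-- pressure-volume traits (mean over", nrow(x$pv_traits), "leaves) --\n")
    print(as.data.frame(x$pv_summary), digits = 3)
  }
  if (!is.null(x$kleaf_max)) cat(sprintf("K_leaf max: %.1f mmol s-1 m-2 MPa-1\n", x$kleaf_max))
  if (!is.null(x$kleaf)) print(x$kleaf)
  if (!is.null(x$ov)) print(x$ov$pooled_fit)
  if (!is.null(x$stomatal)) {
    cat(sprintf("psi_g95: %.3f MPa [%.3f, %.3f]\n", x$stomatal$psi_g95_mean,
                x$stomatal$psi_g95_lo, x$stomatal$psi_g95_hi))
  }
  if (!is.null(x$ssm)) cat(sprintf("stomatal safety margin: %.2f MPa\n", x$ssm))
  if (length(x$errors)) {
    cat("stage errors:\n")
    for (nm in names(x$errors)) cat("  ", nm, ": ", x$errors[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a trait report to JSON
#'
#' @param report A `trait_report` from [run_pipeline()].
#' @param path Output path.
#' @export
write_trait_report <- function(report, path) {
  stopifnot(inherits(report, "trait_report"))
  rec <- list(
    version = report$version, seed = report$seed,
    pv_summary = report$pv_summary,
    kleaf_max = report$kleaf_max,
    psi50_k = if (!is.null(report$kleaf))
      list(value = report$kleaf$psi50_k, ci = c(report$kleaf$ci$lo, report$kleaf$ci$hi),
           r2 = report$kleaf$fit$r2),
    psi50_xe = if (!is.null(report$ov)) {
      per <- lapply(report$ov$per_method, function(f)
        list(value = f$psi50_xe, ci = c(f$ci$lo, f$ci$hi), r2 = f$fit$r2))
      per$pooled <- list(value = report$ov$pooled_fit$psi50_xe,
                         ci = c(report$ov$pooled_fit$ci$lo, report$ov$pooled_fit$ci$hi),
                         r2 = report$ov$pooled_fit$fit$r2)
      per
    },
    stomatal = report$stomatal,
    ssm = report$ssm,
    thresholds = report$thresholds,
    errors = report$errors
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  invisible(path)
}
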