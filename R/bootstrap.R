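#' Percentile bootstrap confidence interval for a fitted-curve statistic
#'
#' Resamples the rows of `data` with replacement (same size as the input),
#' applies `statistic` to each resample, and reports the 2.5% and 97.5%
#' percentiles of the resulting distribution. Resamples on which `statistic`
#' errors or returns a non-finite value are redrawn from the same RNG stream;
#' the redraw count is kept in the result. If fewer than `n_boot` successful
#' replicates are obtained within `2 * n_boot` attempts (i.e. more than half
#' fail), an error is raised.
#'
#' @param data A data frame; rows are the resampling unit.
#' @param statistic Function taking a (resampled) data frame and returning one
#'   finite number, e.g. a fit-and-extract closure.
#' @param n_boot Number of successful bootstrap replicates (default 1000).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return An object of class `boot_ci`: list with `point` (statistic on the
#'   full data), `lo`, `hi`, `boot_mean`, `n_boot`, `seed`, `n_redrawn`, and
#'   the replicate values `stats`.
#' @examples
#' d <- data.frame(x = 1:20, y = (1:20) * 2)
#' bootstrap_ci(d, function(df) ls_slope <- coef(lm(y ~ x, df))[[2]],
#'              n_boot = 50, seed = 1)
#' @export
bootstrap_ci <- function(data, statistic, n_boot = 1000, seed = NULL) {
  if (!is.data.frame(data) || nrow(data) == 0) stop_input("`data` must be a non-empty data frame")
  if (n_boot < 1) stop_input("`n_boot` must be >= 1")
  n <- nrow(data)
  point <- statistic(data)
  if (!is.finite(point)) stop_input("`statistic` failed on the full data")

  stats_out <- numeric(n_boot)
  res <- with_seed_if(seed, {
    got <- 0L; attempts <- 0L; failed <- 0L
    max_attempts <- 2L * n_boot
    while (got < n_boot && attempts < max_attempts) {
      attempts <- attempts + 1L
      idx <- sample.int(n, n, replace = TRUE)
      val <- tryCatch(statistic(data[idx, , drop = FALSE]),
                      error = function(e) NA_real_)
      if (length(val) == 1L && is.finite(val)) {
        got <- got + 1L
        stats_out[got] <- val
      } else {
        failed <- failed + 1L
      }
    }
    list(stats = stats_out, got = got, failed = failed)
  })
  if (res$got < n_boot) {
    stop_input("more than 50% of bootstrap resamples failed to fit (",
               res$failed, " failures)")
  }
  qs <- unname(quantile(res$stats, c(0.025, 0.975)))
  structure(list(point = point, lo = qs[1], hi = qs[2],
                 boot_mean = mean(res$stats), n_boot = n_boot,
                 seed = seed, n_redrawn = res$failed, stats = res$stats),
            class = "boot_ci")
}

#' Are two bootstrap confidence intervals significantly different?
#'
#' Two quantities are flagged as significantly different when their 95%
#' confidence intervals do not overlap.
#'
#' @param a,b `boot_ci` objects (or any lists with `lo` and `hi`).
#' @return `TRUE` iff the intervals are disjoint.
#' @export
cis_overlap <- function(a, b) {
  stopifnot(is.numeric(a$lo), is.numeric(a$hi), is.numeric(b$lo), is.numeric(b$hi),
            a$lo <= a$hi, b$lo <= b$hi)
  a$hi < b$lo || b$hi < a$lo
}

#' @export
print.boot_ci <- function(x, ...) {
  cat(sprintf("<boot_ci> point %.4g  95%% CI [%.4g, %.4g]  (n_boot = %d, redrawn = %d)\n",
              x$point, x$lo, x$hi, x$n_boot, x$n_redrawn))
  invisible(x)
}

#' @method tidy boot_ci
#' @export
tidy.boot_ci <- function(x, ...) {
  tibble::tibble(estimate = x$point, conf.low = x$lo, conf.high = x$hi,
                 boot_mean = x$boot_mean, n_boot = x$n_boot,
                 n_redrawn = x$n_redrawn)
}
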