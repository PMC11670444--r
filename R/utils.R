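#' @importFrom rlang %||% abort warn
#' @importFrom stats approx coef lm median predict quantile rnorm runif rweibull
#'   setNames mad sd
#' @importFrom utils head tail
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's stream;
# seed = NULL means "use whatever stream is active".
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) force(expr) else withr::with_seed(as.integer(seed), expr)
}

stop_input <- function(...) {
  abort(paste0(...), class = "leafhydraulics_input_error")
}

check_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop_input("`", name, "` must be a single finite number")
  }
  invisible(x)
}

# least-squares slope/intercept/r2 without lm() overhead or perfect-fit warnings
ls_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_))
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  ss_tot <- sum((y - my)^2)
  ss_res <- sum((y - intercept - slope * x)^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  list(slope = slope, intercept = intercept, r2 = r2)
}

# molar mass of water, g mol^-1
MOLAR_MASS_WATER <- 18.015
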