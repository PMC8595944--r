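# internal helpers shared across modules

# validation error naming the offending field
abort_field <- function(field, msg) {
  rlang::abort(sprintf("invalid `%s`: %s", field, msg), class = "osanet_validation_error")
}

assert_scalar_number <- function(x, field, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_field(field, "must be a single finite number")
  }
  if (x < lower || x > upper) {
    abort_field(field, sprintf("must be in [%s, %s]", format(lower), format(upper)))
  }
  invisible(x)
}

# derive a reproducible substream seed from a master seed and a fixed offset;
# kept below 2^31 - 1 so it is always a valid R integer seed
substream_seed <- function(master, offset) {
  as.integer((as.numeric(master) + 10007 * as.numeric(offset)) %% 2147483647)
}

# run code under a temporary RNG state restored on exit (so library code does
# not perturb the caller's stream); seed = NULL leaves the current stream alone
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Spearman-to-Pearson copula conversion
#'
#' Converts a target Spearman rank correlation into the Pearson correlation a
#' bivariate Gaussian copula must carry so that the induced rank correlation
#' matches the target: `rho_P = 2 sin(pi * rho_S / 6)` (the inverse of
#' `rho_S = (6/pi) asin(rho_P / 2)`).
#'
#' @param rho_s Spearman correlation target(s) in `[-1, 1]`.
#' @return Pearson correlation(s) of the same shape.
#' @export
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)
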