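#' Round half away from zero
#'
#' Report rounding used throughout: one-decimal percentages and island sizes
#' are rounded half-up (0.05 rounds to 0.1), matching the convention of the
#' printed occupancy and island tables, rather than the round-half-even rule
#' of [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(99.0740741, 1)  # 99.1
#' round_half_up(0.25, 1)        # 0.3
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # small epsilon guards against 0.5 landing just below itself in binary
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Run code with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' seeded operations do not perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == floor(x) && x >= 0
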