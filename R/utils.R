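#' Round half away from zero
#'
#' Base [round()] follows IEC 60559 round-half-to-even ("banker's rounding"),
#' which maps 0.665 to 0.66. Published PMC tables use conventional half-up
#' rounding (2/3 becomes 0.67), so the package rounds with this helper
#' everywhere a reported two-decimal value is produced.
#'
#' A tiny epsilon (1e-9) compensates for binary floating point representing
#' quantities such as `(2/3) * 100` fractionally below their decimal value.
#' All scores handled here are ratios of small integers, far from any point
#' where the epsilon could flip a genuine half-down case.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(2 / 3, 2) # 0.67
#' round_half_up(0.125, 2) # 0.13
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
# Mersenne-Twister is fixed explicitly so seeds are portable across sessions
# regardless of the user's RNGkind().
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

# Collect validation messages; abort with all of them at once so users see
# every violation in a bad schema or table, not just the first.
abort_invalid <- function(messages, what) {
  rlang::abort(
    c(sprintf("Invalid %s:", what), stats::setNames(messages, rep("x", length(messages)))),
    class = "pmcindex_validation_error"
  )
}
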