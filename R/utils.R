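#' Round half away from zero
#'
#' Commercial ("half-up") rounding to a fixed number of decimal places, as
#' used for all displayed currency and FTE figures. Base R's [round()] rounds
#' half to even, which is the wrong convention for printed dollar amounts.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (0 for whole dollars, 2 for cents).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(26153.846)   # 26154
#' round_half_up(0.30769, 2)  # 0.31
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Scalar finite non-negative number check used by all validators.
is_nonneg_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0
}

# Format a number as US currency for Markdown output: $1,234 or $9.33.
fmt_currency <- function(x, digits = 0) {
  ifelse(is.na(x), "N/A",
         paste0("$", formatC(round_half_up(x, digits), format = "f",
                             digits = digits, big.mark = ",")))
}

fmt_number <- function(x, digits = 0) {
  ifelse(is.na(x), "N/A",
         formatC(round_half_up(x, digits), format = "f", digits = digits,
                 big.mark = ","))
}

# Run an expression with a locally seeded RNG, restoring the caller's RNG
# state afterwards so simulation helpers never clobber the global stream.
with_local_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
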