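#' Round half away from zero
#'
#' Base R's `round()` rounds halves to even; clinical tables conventionally
#' round halves up. Used for all printed percentages and summaries.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded with ties going away from zero.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.25), 0:1 * 0)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * trunc(abs(x) * m + 0.5 + 1e-9) / m
}

# percentage of count/total, half-up at one decimal (Table-1 convention)
pct1 <- function(count, total) round_half_up(100 * count / total, 1)

stop_if <- function(cond, msg) {
  if (cond) abort(msg, call = NULL)
  invisible(NULL)
}

# draw n sub-seeds deterministically from the current RNG state; keeps every
# stage independently reproducible from one top-level seed
split_seeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n)
}
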