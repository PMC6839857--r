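# Decimal-rounding helpers used when reporting at fixed precision.
#
# Published forensic tables round haplotype match probability half-up and
# truncate haplotype diversity; base round() uses banker's rounding, so both
# are implemented explicitly. A 1e-9 guard absorbs binary floating-point
# representation error on exact decimal halves (e.g. 408/160000 * 1e4 == 25.5).

#' Round half away from zero at a fixed number of decimals
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return `x` rounded with halves going away from zero.
#' @export
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Truncate (round toward zero) at a fixed number of decimals
#'
#' @inheritParams round_half_up
#' @return `x` truncated toward zero.
#' @export
round_down <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 1e-9) / p
}

# format a numeric at fixed decimals (half-up), as character
fmt_num <- function(x, digits = 4) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

# deterministic sub-seed derivation from the current RNG stream
draw_subseed <- function() {
  sample.int(.Machine$integer.max - 1L, 1L)
}
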