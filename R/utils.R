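# Species handled by the analysis. Observer records may carry an "other"
# bucket which default screening removes.
.species3 <- c("fur_seal", "sperm_whale", "orca")
.species_all <- c(.species3, "other")

#' Round half away from zero
#'
#' Report tables are conventionally printed with halves rounded up (base
#' `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.year <- function(d) as.integer(format(d, "%Y"))
.month <- function(d) as.integer(format(d, "%m"))

.assert_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, min, max))
  }
  invisible(x)
}
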