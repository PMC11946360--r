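#' Round half away from zero
#'
#' Fixed-decimal rounding with the half-up convention used throughout the
#' package's summary tables (base \code{round()} rounds half to even, which
#' would mis-render boundary cells such as 0.435).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up to \code{digits} decimals.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a panel, rounded for table display
#'
#' @param count Count (may be fractional, e.g. a mean of per-sample counts).
#' @param n Panel size the count is taken out of.
#' @param digits Decimal places (default 2, matching the summary tables).
#' @return \code{100 * count / n}, rounded half-up.
#' @export
asPct <- function(count, n, digits = 2) {
  stopifnot(n > 0)
  roundHalfUp(100 * count / n, digits)
}

## internal: locus key used for depth lookups
.lockey <- function(chrom, pos) paste(chrom, pos, sep = ":")

.msg <- function(...) message("[ExomeScreen] ", ...)

#' @importFrom methods new validObject is slot
#' @importFrom stats median rbinom rgamma rpois runif setNames
#' @importFrom utils read.delim write.table
#' @importFrom graphics plot arrows
#' @importFrom grDevices pdf dev.off
NULL
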