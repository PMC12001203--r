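#' Round half away from zero at a fixed number of decimals
#'
#' Base R's `round()` rounds half to even; campaign report tables use
#' conventional half-up rounding at the precision printed in each cell, so the
#' behaviour is pinned down here once.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(2.5)    # 3, where round(2.5) gives 2
#' round_half_up(2.345, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  scale <- 10^digits
  # small epsilon guards against values like 82.954999... stored just below .5
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

abort_crm <- function(msg, class) {
  rlang::abort(msg, class = c(class, "crmscreen_error"))
}

`%||%` <- rlang::`%||%`

# vapply shorthands used throughout
vchr <- function(x, f, ...) vapply(x, f, character(1), ...)
vnum <- function(x, f, ...) vapply(x, f, numeric(1), ...)
vlgl <- function(x, f, ...) vapply(x, f, logical(1), ...)
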