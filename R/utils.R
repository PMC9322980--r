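#' Round half away from zero
#'
#' Decimal rounding with ties going up in absolute value, as used for all
#' reported table values (base [round()] uses round-half-even, which does not
#' match how registry tables are conventionally printed).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' roundHalfUp(0.0005, 3) # 0.001
#' round(0.0005, 3)       # 0 (banker's rounding)
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# right-pad strings to length n with a fill character
padRight <- function(x, n, fill) {
  d <- pmax(0L, n - nchar(x))
  paste0(x, strrep(fill, d))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
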