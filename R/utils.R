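#' Round half away from zero to the nearest non-negative integer
#'
#' Copy numbers are reported as integers; ties (x.5) round up, and negative
#' continuous estimates are clamped to zero before rounding.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @examples
#' roundHalfUp(c(2.4, 2.5, -0.2))
#' @export
roundHalfUp <- function(x) {
  as.integer(floor(pmax(x, 0) + 0.5))
}

# stop() with a consistent prefix so workflow wrappers can map errors to exit codes
.fail <- function(...) stop(..., call. = FALSE)

.assertScalarPositive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    .fail(name, " must be a single positive finite number")
  invisible(x)
}
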