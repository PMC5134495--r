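#' @useDynLib lenslessSR, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd median
#' @keywords internal
"_PACKAGE"

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Round half away from zero
#'
#' Commercial-rounding helper used wherever reported values are rounded
#' (R's `round()` rounds half to even, which does not match how counting
#' reports are conventionally printed).
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return `x` rounded with ties going away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_validation <- function(...) {
  stop(structure(class = c("lenslessSR_validation", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_io <- function(...) {
  stop(structure(class = c("lenslessSR_io", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
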