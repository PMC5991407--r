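# Internal helpers shared across modules.

# Valid NDVI range for MODIS-style vegetation indices.
NDVI_MIN <- -0.2
NDVI_MAX <- 1.0

#' Clip values to the valid NDVI range
#'
#' @param x numeric vector.
#' @return `x` with every element forced into `[-0.2, 1.0]`.
#' @keywords internal
clip_ndvi <- function(x) {
  x[x < NDVI_MIN] <- NDVI_MIN
  x[x > NDVI_MAX] <- NDVI_MAX
  x
}

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library functions never perturb user RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-unit seed from a master seed, kept within 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 7919) %% 2147483647)
}

#' Round half away from zero
#'
#' Presentation rounding used for effectiveness rates: ties go away from
#' zero (2.675 -> 2.68), unlike [round()] which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Population (divisor N) standard deviation.
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}
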