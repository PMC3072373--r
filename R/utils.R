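# Small shared helpers.

#' Round half away from zero
#'
#' Commercial rounding at a fixed number of decimals, used for all printed
#' percentages so that values like 71.875 render as 71.9 (base `round()`
#' rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples roundHalfUp(c(71.875, 42.53), c(1, 0))
#' @export
roundHalfUp <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Deterministic sub-seed for a named output table, derived from the master
# seed. Kept well below 2^31.
.subSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 99991L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

# Two-sample pooled-variance Student t on tiny replicate groups, with the
# deterministic degenerate rule used throughout classification: when both
# groups have zero variance the p-value is undefined (NA) and magnitude
# criteria alone decide.
.pooledT <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  d <- mean(x) - mean(y)
  if (sp2 == 0) return(list(t = NA_real_, p = NA_real_, diff = d))
  tt <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, p = 2 * stats::pt(-abs(tt), df = n1 + n2 - 2), diff = d)
}

# Relative standard deviation (SD/mean) of a replicate vector; NA when the
# mean is zero.
.relSD <- function(x) {
  m <- mean(x)
  if (m == 0) return(NA_real_)
  stats::sd(x) / m
}
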