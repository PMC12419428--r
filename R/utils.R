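# Internal helpers shared across modules.

# 97.5% normal quantile fixed so rendered confidence intervals round-trip
# exactly against 3-decimal report tables.
Z975 <- 1.959964

# Two-sided normal p-value from an estimate and its standard error.
p_normal <- function(beta, se) {
  2 * stats::pnorm(-abs(beta / se))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random number stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Overflow-safe log(sum(exp(x))).
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Overflow-safe log(exp(a) - exp(b)) for a >= b. Rounding can leave b >= a
# when the two sums are numerically identical; clamp to -Inf with a warning.
logdiff <- function(a, b) {
  if (b >= a) {
    if (b > a) {
      warning("logdiff: second term exceeds first (rounding); clamping to -Inf")
    }
    return(-Inf)
  }
  a + log1p(-exp(b - a))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tsmr <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "tsmr_error")))
}
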