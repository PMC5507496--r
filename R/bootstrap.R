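# Internal bootstrap machinery shared by the evaluation surface.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Two-sided sign-crossing bootstrap p-value for H0: statistic == 0,
# clamped to [1/B, 1]; bound = TRUE when no resample crossed zero.
signCrossP <- function(resamples, alternative = "two.sided") {
  B <- length(resamples)
  nLow <- sum(resamples <= 0)
  nHigh <- sum(resamples >= 0)
  p <- switch(alternative,
    two.sided = 2 * min(nLow, nHigh) / B,
    less = nHigh / B,
    greater = nLow / B,
    stop("unknown alternative"))
  bound <- p == 0
  list(p = min(max(p, 1 / B), 1), bound = bound)
}

# Assemble a BootstrapResult from observed statistic + resamples.
makeBootstrapResult <- function(statistic, estimate, resamples, seed,
                                level = 0.95,
                                alternative = "two.sided") {
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(resamples, c(alpha, 1 - alpha),
                               na.rm = TRUE, type = 7))
  pv <- signCrossP(resamples[!is.na(resamples)], alternative)
  new("BootstrapResult", statistic = statistic, estimate = estimate,
      ciLow = ci[1], ciHigh = ci[2], pValue = pv$p, pBound = pv$bound,
      nResamples = as.integer(length(resamples)),
      seed = as.integer(seed), level = level,
      resamples = as.numeric(resamples))
}

# Draw B bootstrap index vectors of size n, applying fn(idx, b) per
# resample. Deterministic under the given seed.
bootApply <- function(n, B, seed, fn) {
  withSeed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      fn(idx, b)
    }, numeric(1))
  })
}
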