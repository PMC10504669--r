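# Seed the RNG for the calling function's scope and restore the previous
# state when that scope exits, so library code never perturbs user RNG flow.
local_rng <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) stop("seed is required")
  withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(seed)
}

# Adjusted Fisher-Pearson sample skewness (the convention used by
# scipy.stats.skew(bias=FALSE) / SAS / Excel). Returns 0 for constant
# vectors; requires n >= 3 for the bias adjustment.
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) stop("skewness needs at least 3 values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  g1 <- mean((x - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# Population variance (divide by n, not n - 1).
pop_var <- function(x) mean((x - mean(x))^2)
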