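# Internal numerical and plumbing helpers.

# Run `expr` under a local RNG state seeded with `seed`; restores the
# caller's RNG afterwards so simulations never disturb user randomness.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic fan-out of a user seed into per-stage seeds (< 2^31).
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed %% 100003L) * 131071 +
                as.numeric(index) * 2654435) %% 2147483647)
}

# FNV-1a hash over serialized R objects; stable fingerprint for manifests.
hashObject <- function(x) {
  bytes <- serialize(x, connection = NULL, version = 2L)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (as.numeric(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Trapezoidal integral of y sampled at uniform spacing dx.
trapezoid <- function(y, dx) {
  n <- length(y)
  if (n < 2L) return(0)
  dx * sum((y[-1] + y[-n]) / 2)
}

# Welch's two-sample t-test with a variance floor so degenerate
# (constant) groups still yield a defined statistic.
welchTest <- function(a, b, varFloor = 1e-12) {
  na <- length(a); nb <- length(b)
  va <- max(stats::var(a), varFloor)
  vb <- max(stats::var(b), varFloor)
  se2 <- va / na + vb / nb
  stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(stat), df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p.value = p)
}

# Two-sided Fisher exact p for a 2x2 table, built from the hypergeometric
# mass: sum the probabilities of all tables (fixed margins) no more
# probable than the observed one.
fisherExactP <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m, n, k)
  pObs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}
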