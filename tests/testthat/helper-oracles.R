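# Shared fixtures and independent oracles used across the suite.

suppressPackageStartupMessages(library(SummarizedExperiment))

# direct ZINB sampler, independent of the package generator
rzinb <- function(n, mu, theta, pi) {
  ifelse(stats::rbinom(n, 1, pi) == 1, 0L,
         stats::rnbinom(n, size = theta, mu = mu))
}

# closed-form NB zero probability
nbZeroProb <- function(mu, theta) (theta / (theta + mu))^theta

# grid-search oracle for the density minimum of a two-Gaussian mixture
# between its modes
mixtureMinimumOracle <- function(m1, m2, sd, p = 0.5, nGrid = 10000L) {
  xs <- seq(m1, m2, length.out = nGrid)
  dens <- p * stats::dnorm(xs, m1, sd) + (1 - p) * stats::dnorm(xs, m2, sd)
  xs[which.min(dens)]
}

# Benjamini-Hochberg adjustment written out directly from the step-up
# definition (independent of stats::p.adjust)
bhByHand <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# exhaustive nearest-neighbour distances: plain double loop
bruteNearest <- function(nodeXyz, synXyz) {
  apply(synXyz, 1, function(s) {
    min(sqrt(colSums((t(nodeXyz) - s)^2)))
  })
}

# unweighted NB likelihood-ratio test oracle built on MASS::glm.nb:
# dispersion from the alternative fit, shared with the null fit
glmNbLrtOracle <- function(y, group, offset) {
  alt <- MASS::glm.nb(y ~ group + offset(offset))
  th <- alt$theta
  null <- stats::glm(y ~ offset(offset),
                     family = MASS::negative.binomial(th))
  altRef <- stats::glm(y ~ group + offset(offset),
                       family = MASS::negative.binomial(th))
  stat <- 2 * (stats::logLik(altRef) - stats::logLik(null))
  list(statistic = as.numeric(stat),
       p.value = stats::pchisq(as.numeric(stat), 1, lower.tail = FALSE),
       log2FC = unname(stats::coef(altRef)[2]) / log(2))
}

# small two-cluster expression fixture: n cells per cluster, nDiff
# genes shifted strongly in the second cluster. Shifted genes start
# from a low baseline so the library-size composition shift stays
# negligible and null genes remain null after normalization.
twoClusterFixture <- function(seed, n = 50, g = 300, nDiff = 0,
                              foldUp = 8) {
  set.seed(seed)
  muBase <- stats::rlnorm(g, log(2), 0.5)
  muB <- muBase
  if (nDiff > 0) {
    muBase[seq_len(nDiff)] <- 0.3
    muB <- muBase
    muB[seq_len(nDiff)] <- muBase[seq_len(nDiff)] * foldUp
  }
  cnt <- cbind(vapply(seq_len(n), function(i)
    stats::rnbinom(g, size = 2, mu = muBase), numeric(g)),
    vapply(seq_len(n), function(i)
      stats::rnbinom(g, size = 2, mu = muB), numeric(g)))
  rownames(cnt) <- sprintf("g%03d", seq_len(g))
  colnames(cnt) <- sprintf("c%03d", seq_len(2 * n))
  libs <- pmax(colSums(cnt), 1)
  norm <- log1p(t(t(cnt) / libs) * 1e4)
  list(counts = cnt, norm = norm,
       labels = rep(c("A", "B"), each = n))
}
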