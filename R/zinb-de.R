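# Zero-inflation-aware differential expression.
#
# Per-gene model: a count is zero with probability pi (technical
# dropout), otherwise NB(mu, theta). The EM fit yields posterior
# "observational weights" for zeros (probability the zero came from the
# NB component), which downweight technical zeros in a weighted
# negative binomial likelihood-ratio test between two conditions.

# weighted NB log-likelihood for an intercept-only mean model;
# mu is the common mean, w observation weights
nbWeightedLoglik <- function(y, w, mu, theta) {
  sum(w * stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
}

# weighted ML dispersion for fixed mu (vectorized over cells);
# profile over log(theta)
mlTheta <- function(y, w, mu, lower = 1e-3, upper = 1e6) {
  f <- function(lt) {
    th <- exp(lt)
    sum(w * stats::dnbinom(y, size = th, mu = mu, log = TRUE))
  }
  opt <- stats::optimize(f, c(log(lower), log(upper)), maximum = TRUE,
                         tol = 1e-8)
  exp(opt$maximum)
}

#' Fit a zero-inflated negative binomial to a count vector
#'
#' EM maximization of the ZINB likelihood. E-step: each zero count is
#' assigned its posterior probability of arising from the inflation
#' component, `z = pi / (pi + (1 - pi) f_NB(0))`. M-step: `pi` is the
#' mean posterior (closed form); `mu` is the `(1 - z)`-weighted mean
#' (the weighted NB ML solution for an intercept model); `theta` is
#' profiled by weighted ML. Iteration stops when the observed-data
#' log-likelihood changes by less than `tol` or after `maxIter`
#' rounds; the log-likelihood is asserted non-decreasing.
#'
#' @param y non-negative integer counts, length at least `minN`.
#' @param minN minimum number of cells (default 50).
#' @param maxIter,tol EM controls (defaults 2000 and 1e-6; genes
#'   whose fitted `pi` approaches the zero boundary converge
#'   sublinearly and need the larger iteration budget).
#' @return List of class `ZinbFit`: `mu`, `theta`, `pi`, `loglik`,
#'   `converged`, `nIter`, `degenerate` (all-zero input).
#' @examples
#' set.seed(1)
#' y <- ifelse(rbinom(500, 1, 0.3) == 1, 0L, rnbinom(500, size = 2, mu = 5))
#' fitZinb(y)[c("mu", "theta", "pi")]
#' @export
fitZinb <- function(y, minN = 50L, maxIter = 2000L, tol = 1e-6) {
  if (any(y < 0) || any(y != round(y)))
    stop("counts must be non-negative integers", call. = FALSE)
  n <- length(y)
  if (n < minN)
    stop("need at least ", minN, " cells, got ", n, call. = FALSE)
  if (all(y == 0)) {
    return(structure(list(mu = 0, theta = NA_real_, pi = NA_real_,
                          loglik = 0, converged = FALSE, nIter = 0L,
                          degenerate = TRUE), class = "ZinbFit"))
  }
  zeros <- y == 0L
  if (!any(zeros)) {
    # no zeros: pi pinned at 0, plain NB ML
    mu <- mean(y)
    theta <- if (stats::var(y) <= mu + 1e-12) 1e6
             else mlTheta(y, rep(1, n), mu)
    ll <- nbWeightedLoglik(y, rep(1, n), mu, theta)
    return(structure(list(mu = mu, theta = theta, pi = 0, loglik = ll,
                          converged = TRUE, nIter = 0L,
                          degenerate = FALSE), class = "ZinbFit"))
  }

  obsLoglik <- function(mu, theta, pi) {
    p0 <- stats::dnbinom(0, size = theta, mu = mu)
    llZero <- log(pi + (1 - pi) * p0)
    llPos <- log1p(-pi) +
      stats::dnbinom(y[!zeros], size = theta, mu = mu, log = TRUE)
    sum(zeros) * llZero + sum(llPos)
  }

  pi <- mean(zeros) / 2
  mu <- mean(y) / (1 - pi)
  theta <- 1
  ll <- obsLoglik(mu, theta, pi)
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    # E-step
    p0 <- stats::dnbinom(0, size = theta, mu = mu)
    z <- rep(0, n)
    z[zeros] <- pi / (pi + (1 - pi) * p0)
    # M-step
    pi <- mean(z)
    w <- 1 - z
    mu <- sum(w * y) / sum(w)
    theta <- mlTheta(y, w, mu)
    llNew <- obsLoglik(mu, theta, pi)
    if (llNew < ll - 1e-8)
      stop("EM log-likelihood decreased: numerical failure",
           call. = FALSE)
    if (abs(llNew - ll) < tol) {
      ll <- llNew
      converged <- TRUE
      break
    }
    ll <- llNew
  }
  structure(list(mu = mu, theta = theta, pi = pi, loglik = ll,
                 converged = converged, nIter = iter,
                 degenerate = FALSE), class = "ZinbFit")
}

#' @export
print.ZinbFit <- function(x, ...) {
  if (x$degenerate) cat("ZinbFit: degenerate (all-zero gene)\n")
  else cat(sprintf(
    "ZinbFit: mu=%.4g theta=%.4g pi=%.4g loglik=%.4g (%s, %d iter)\n",
    x$mu, x$theta, x$pi, x$loglik,
    if (x$converged) "converged" else "not converged", x$nIter))
  invisible(x)
}

#' Observational weights from a ZINB fit
#'
#' Posterior probability that each observation arose from the NB
#' component: exactly 1 for non-zero counts; for zeros,
#' `(1 - pi) f_NB(0) / (pi + (1 - pi) f_NB(0))` with
#' `f_NB(0) = (theta / (theta + mu))^theta`. Zero weights decrease
#' monotonically in `pi` at fixed `(mu, theta)`.
#'
#' @param y the counts the fit was computed on.
#' @param fit a converged [fitZinb()] object.
#' @return Numeric weights in `(0, 1]`, one per observation.
#' @examples
#' # mu = 5, theta = 2, pi = 0.3: zero weight = .7*(2/7)^2/(.3+.7*(2/7)^2)
#' f <- structure(list(mu = 5, theta = 2, pi = 0.3, converged = TRUE,
#'                     degenerate = FALSE), class = "ZinbFit")
#' observationalWeights(c(0L, 3L), f)
#' @export
observationalWeights <- function(y, fit) {
  if (fit$degenerate || !fit$converged)
    stop("weights require a converged, non-degenerate ZINB fit",
         call. = FALSE)
  w <- rep(1, length(y))
  if (fit$pi > 0) {
    p0 <- (fit$theta / (fit$theta + fit$mu))^fit$theta
    w[y == 0] <- (1 - fit$pi) * p0 / (fit$pi + (1 - fit$pi) * p0)
  }
  w
}

# weighted ML fit of a single log-scale intercept b with offsets:
# maximize sum w * dnbinom(y; theta, mu = exp(b + o))
fitIntercept <- function(y, w, o, theta) {
  rate <- sum(w * y) / sum(w * exp(o))
  b0 <- log(max(rate, 1e-8))
  f <- function(b) sum(w * stats::dnbinom(y, size = theta,
                                          mu = exp(b + o), log = TRUE))
  opt <- stats::optimize(f, c(b0 - 8, b0 + 8), maximum = TRUE,
                         tol = 1e-9)
  list(b = opt$maximum, loglik = opt$objective)
}

#' Weighted negative binomial likelihood-ratio test
#'
#' Two-group differential expression test with observational weights
#' and library-size offsets. The weighted NB log-likelihood is
#' maximized under the null (one common intercept) and the alternative
#' (one intercept per group), with the dispersion profiled by weighted
#' ML under the alternative and shared by both fits — so the effective
#' sample size entering the dispersion estimate is the sum of the
#' weights. The statistic `2 * (llAlt - llNull)` is referred to a
#' chi-square distribution with 1 df. With all weights equal to 1 this
#' is the ordinary unweighted NB LRT.
#'
#' @param y counts for one gene across cells.
#' @param group two-level factor (or coercible); the reported log2 fold
#'   change is level 2 relative to level 1.
#' @param weights observational weights (default all 1).
#' @param offset per-cell log library-size offsets (default 0).
#' @return List: `log2FC`, `p.value`, `statistic`, `theta`,
#'   `meanWeight`, `skipped` (TRUE when a group carries no weight).
#' @examples
#' set.seed(1)
#' y <- rnbinom(100, size = 2, mu = rep(c(5, 20), each = 50))
#' weightedNbTest(y, rep(c("a", "b"), each = 50))$log2FC  # near 2
#' @export
weightedNbTest <- function(y, group, weights = rep(1, length(y)),
                           offset = rep(0, length(y))) {
  group <- factor(group)
  if (nlevels(group) != 2L)
    stop("group must have exactly two levels", call. = FALSE)
  if (any(table(group) < 3L))
    stop("each group needs at least 3 cells", call. = FALSE)
  g1 <- group == levels(group)[1L]
  g2 <- !g1
  if (sum(weights[g1]) <= 0 || sum(weights[g2]) <= 0) {
    return(list(log2FC = NA_real_, p.value = NA_real_,
                statistic = NA_real_, theta = NA_real_,
                meanWeight = mean(weights), skipped = TRUE))
  }

  fitAlt <- function(theta) {
    f1 <- fitIntercept(y[g1], weights[g1], offset[g1], theta)
    f2 <- fitIntercept(y[g2], weights[g2], offset[g2], theta)
    list(b1 = f1$b, b2 = f2$b, loglik = f1$loglik + f2$loglik)
  }
  prof <- function(lt) fitAlt(exp(lt))$loglik
  opt <- stats::optimize(prof, c(log(1e-3), log(1e6)), maximum = TRUE,
                         tol = 1e-6)
  theta <- exp(opt$maximum)
  alt <- fitAlt(theta)
  null <- fitIntercept(y, weights, offset, theta)
  stat <- max(0, 2 * (alt$loglik - null$loglik))
  list(log2FC = (alt$b2 - alt$b1) / log(2),
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       statistic = stat, theta = theta, meanWeight = mean(weights),
       skipped = FALSE)
}

#' Zero-inflation-weighted DE across genes and clusters
#'
#' Convenience wrapper running the full per-cluster pipeline: for each
#' cluster, and each gene expressed in at least `minCells` cells of the
#' cluster, fit the ZINB ([fitZinb()]), derive observational weights,
#' and run [weightedNbTest()] between the two conditions with log
#' library-size offsets. P-values are BH-adjusted within each cluster's
#' tested gene set.
#'
#' @param counts genes x cells count matrix.
#' @param condition per-cell two-level condition factor; log2FC is
#'   level 2 vs level 1.
#' @param clusters per-cell cluster labels (default: one pooled
#'   cluster).
#' @param classes optional per-cell class labels carried into the
#'   result for event summaries.
#' @param minCells genes detected in fewer cells within a cluster are
#'   not tested (default 10).
#' @param minN minimum cluster size per [fitZinb()] (default 50).
#' @return data.frame with one row per (gene, cluster): `gene`,
#'   `cluster`, `class`, `log2FC`, `p.value`, `padj`, `meanWeight`.
#' @export
runDifferentialExpression <- function(counts, condition, clusters = NULL,
                                      classes = NULL, minCells = 10L,
                                      minN = 50L) {
  condition <- factor(condition)
  if (nlevels(condition) != 2L)
    stop("condition must have two levels", call. = FALSE)
  if (is.null(clusters)) clusters <- rep("all", ncol(counts))
  clusters <- as.character(clusters)
  if (is.null(classes)) classes <- clusters
  libsize <- Matrix::colSums(counts)
  offset <- log(pmax(libsize, 1))
  offset <- offset - mean(offset)
  out <- list()
  for (cl in unique(clusters)) {
    sel <- clusters == cl
    if (sum(sel) < minN) next
    condCl <- droplevels(condition[sel])
    if (nlevels(condCl) != 2L || any(table(condCl) < 3L)) next
    sub <- counts[, sel, drop = FALSE]
    det <- Matrix::rowSums(sub > 0)
    genes <- rownames(sub)[det >= minCells]
    rows <- lapply(genes, function(g) {
      yg <- as.integer(sub[g, ])
      fit <- tryCatch(fitZinb(yg, minN = minN),
                      error = function(e) NULL)
      if (is.null(fit) || fit$degenerate || !fit$converged) return(NULL)
      w <- observationalWeights(yg, fit)
      tst <- weightedNbTest(yg, condCl, w, offset[sel])
      if (tst$skipped) return(NULL)
      data.frame(gene = g, cluster = cl,
                 class = classes[sel][1L],
                 log2FC = tst$log2FC, p.value = tst$p.value,
                 meanWeight = tst$meanWeight,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    if (is.null(res) || !nrow(res)) next
    res$padj <- stats::p.adjust(res$p.value, "BH")
    out[[cl]] <- res
  }
  if (!length(out))
    return(data.frame(gene = character(), cluster = character(),
                      class = character(), log2FC = numeric(),
                      p.value = numeric(), meanWeight = numeric(),
                      padj = numeric()))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Summarize DE events
#'
#' A DE event is a (gene, cluster) pair with `|log2FC| > fcCut` and
#' `padj < alpha`. Reports events per class split by direction (up-
#' and down-regulated in condition 2) and the set of genes passing in
#' at least one cluster; when several independent result tables are
#' supplied the union of passing genes counts each gene once.
#'
#' @param results a DE result data.frame (from
#'   [runDifferentialExpression()] or compatible), or a list of such
#'   tables whose gene-level calls are unioned.
#' @param fcCut,alpha event thresholds (defaults 1 and 0.05).
#' @return List with `events` (the passing rows), `perClass`
#'   (data.frame class / up / down / total) and `genes` (genes DE in
#'   at least one cluster, unioned across tables).
#' @export
summarizeDe <- function(results, fcCut = 1, alpha = 0.05) {
  tables <- if (is.data.frame(results)) list(results) else results
  pass <- lapply(tables, function(r) {
    if (!nrow(r)) return(r)
    r[abs(r$log2FC) > fcCut & r$padj < alpha & !is.na(r$padj), ,
      drop = FALSE]
  })
  events <- do.call(rbind, c(pass, make.row.names = FALSE))
  if (is.null(events))
    events <- data.frame(gene = character(), cluster = character(),
                         class = character(), log2FC = numeric(),
                         padj = numeric())
  # an event is one (gene, cluster); union across tables
  if (nrow(events))
    events <- events[!duplicated(events[, c("gene", "cluster")]), ,
                     drop = FALSE]
  perClass <- if (nrow(events)) {
    agg <- stats::aggregate(
      cbind(up = events$log2FC > 0, down = events$log2FC < 0),
      by = list(class = events$class), FUN = sum)
    agg$total <- agg$up + agg$down
    agg
  } else data.frame(class = character(), up = integer(),
                    down = integer(), total = integer())
  list(events = events, perClass = perClass,
       genes = unique(events$gene))
}
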