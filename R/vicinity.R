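# Astrocyte-synapse geometry: quality filtering, fine-process node
# selection, shortest-distance vicinity profiles by transmitter, and
# the bootstrap-of-means significance procedure.

#' Filter synapses on detection quality scores
#'
#' Keeps records with `cleftScore >= minCleft` and
#' `connectionScore >= minConnection` (inclusive thresholds). Records
#' with a missing score are dropped with a warning.
#'
#' @param synapses a [SynapseTable-class].
#' @param minCleft,minConnection score thresholds (defaults 50 and 33).
#' @return A filtered [SynapseTable-class].
#' @export
filterSynapses <- function(synapses, minCleft = 50, minConnection = 33) {
  d <- synapseData(synapses)
  bad <- is.na(d$cleftScore) | is.na(d$connectionScore)
  if (any(bad)) {
    warning(sum(bad), " record(s) with missing scores rejected")
  }
  keep <- !bad & d$cleftScore >= minCleft &
    d$connectionScore >= minConnection
  synapses[which(keep)]
}

#' Select fine-process skeleton nodes
#'
#' Nodes with radius strictly below `maxRadius` (default 300 nm),
#' excluding somata and main branches so that distances are measured
#' to the fine astrocytic processes that approach synapses.
#'
#' @param skeleton a [Skeleton-class].
#' @param maxRadius strict upper radius bound in nm.
#' @return data.frame of the retained nodes; warns when empty.
#' @export
fineProcessNodes <- function(skeleton, maxRadius = 300) {
  nd <- skeletonNodes(skeleton)
  out <- nd[nd$radius < maxRadius, , drop = FALSE]
  if (!nrow(out))
    warning("no nodes below ", maxRadius,
            " nm: downstream vicinity operations will refuse")
  out
}

# shortest Euclidean and Chebyshev distances from each synapse to any
# node; plain exhaustive search, chunked over synapses to bound memory
nearestNodeDistances <- function(nodeXyz, synXyz, chunk = 512L) {
  nS <- nrow(synXyz)
  euclid <- numeric(nS); cheb <- numeric(nS)
  for (start in seq(1L, nS, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nS)
    dx <- outer(synXyz[idx, 1], nodeXyz[, 1], "-")
    dy <- outer(synXyz[idx, 2], nodeXyz[, 2], "-")
    dz <- outer(synXyz[idx, 3], nodeXyz[, 3], "-")
    euclid[idx] <- sqrt(apply(dx^2 + dy^2 + dz^2, 1, min))
    cheb[idx] <- apply(pmax(abs(dx), abs(dy), abs(dz)), 1, min)
  }
  list(euclid = euclid, chebyshev = cheb)
}

#' Vicinity profile: synapse-to-process distances by transmitter
#'
#' Restricts synapses to the direct vicinity of the fine processes —
#' by default the union of axis-aligned boxes of half-width `halfWidth`
#' (2 um) centred on each fine node; `mode = "sphere"` uses a
#' `halfWidth`-radius ball instead — then computes each candidate's
#' shortest Euclidean distance to any fine node (node centre to
#' synapse point; exhaustive search). Distances are grouped by
#' predicted transmitter, with a Gaussian kernel density estimate
#' (Scott's bandwidth rule) per group.
#'
#' @param nodes data.frame of fine nodes ([fineProcessNodes()]), or a
#'   [Skeleton-class] (fine nodes are then selected at 300 nm).
#' @param synapses a quality-filtered [SynapseTable-class].
#' @param halfWidth vicinity half-width / radius in nm (default 2000).
#' @param mode `"box"` (default) or `"sphere"`.
#' @return List of class `VicinityProfile`: `distances` (named list of
#'   per-transmitter distance vectors, nm), `candidates` (row indices
#'   into `synapses`), `kde` (per-transmitter `density` objects),
#'   `mode`, `halfWidth`.
#' @export
vicinityProfile <- function(nodes, synapses, halfWidth = 2000,
                            mode = c("box", "sphere")) {
  mode <- match.arg(mode)
  if (methods::is(nodes, "Skeleton")) nodes <- fineProcessNodes(nodes)
  if (!nrow(nodes)) stop("no fine-process nodes supplied", call. = FALSE)
  d <- synapseData(synapses)
  if (!nrow(d)) stop("no synapses supplied", call. = FALSE)
  nodeXyz <- as.matrix(nodes[, c("x", "y", "z")])
  synXyz <- as.matrix(as.data.frame(d[, c("x", "y", "z")]))
  nn <- nearestNodeDistances(nodeXyz, synXyz)
  inVicinity <- if (mode == "box") nn$chebyshev <= halfWidth
                else nn$euclid <= halfWidth
  candidates <- which(inVicinity)
  dist <- nn$euclid[candidates]
  tx <- as.character(d$transmitter[candidates])
  distances <- split(dist, tx)
  kde <- lapply(distances, function(v) {
    if (length(v) >= 2L && stats::sd(v) > 0)
      stats::density(v, bw = stats::bw.nrd(v))
    else NULL
  })
  structure(list(distances = distances, candidates = candidates,
                 kde = kde, mode = mode, halfWidth = halfWidth),
            class = "VicinityProfile")
}

#' @export
print.VicinityProfile <- function(x, ...) {
  cat("VicinityProfile (", x$mode, ", half-width ", x$halfWidth,
      " nm): ", length(x$candidates), " synapses\n", sep = "")
  for (tx in names(x$distances)) {
    v <- x$distances[[tx]]
    cat(sprintf("  %-14s n=%4d  mean=%7.1f nm  sd=%6.1f\n", tx,
                length(v), mean(v), stats::sd(v)))
  }
  invisible(x)
}

#' Bootstrap-of-means comparison of two distance distributions
#'
#' For each group, draws `nBoot` resamples with replacement of the
#' group's own size and records the resample means; the two
#' bootstrap-mean distributions are then compared with a two-sided
#' Welch t-test (`p.boot`). Because
#' treating `nBoot` resample means as independent observations
#' inflates the degrees of freedom — the test is anticonservative for
#' samples from a common population — a plain two-sample Welch t-test
#' on the raw distances (`p.raw`) is reported alongside and should be
#' used wherever calibrated type-I error matters.
#'
#' Resampling indices are derived from `seed` per group, so identical
#' input vectors produce identical bootstrap distributions (and
#' `p.boot = 1`), and reruns are reproducible.
#'
#' @param a,b numeric distance vectors, each of length at least 10.
#' @param nBoot number of bootstrap resamples (default 10000).
#' @param seed integer seed for the resampling.
#' @return List: `bootMeansA`, `bootMeansB`, `p.boot`, `statBoot`,
#'   `p.raw`, `statRaw`, `meanDiff` (mean(a) - mean(b)).
#' @export
bootstrapMeanTest <- function(a, b, nBoot = 10000L, seed = 1L) {
  if (length(a) < 10L || length(b) < 10L)
    stop("each group needs at least 10 distances", call. = FALSE)
  bootMeans <- function(v) {
    n <- length(v)
    idx <- matrix(sample.int(n, n * nBoot, replace = TRUE), nrow = n)
    colMeans(matrix(v[idx], nrow = n))
  }
  bmA <- withSeed(seed, bootMeans(a))
  bmB <- withSeed(seed, bootMeans(b))
  boot <- welchTest(bmA, bmB)
  raw <- welchTest(a, b)
  list(bootMeansA = bmA, bootMeansB = bmB,
       p.boot = boot$p.value, statBoot = boot$statistic,
       p.raw = raw$p.value, statRaw = raw$statistic,
       meanDiff = mean(a) - mean(b))
}

#' Flag tripartite synapses
#'
#' A synapse is a tripartite synapse (TPS) when an astrocyte id
#' appears among its postsynaptic partners.
#'
#' @param synapses a [SynapseTable-class]; postsynaptic partners are
#'   the `;`-separated `postIds` column.
#' @param astrocyteIds character vector of astrocyte ids.
#' @return Logical vector, one flag per synapse record.
#' @export
classifyTps <- function(synapses, astrocyteIds) {
  d <- synapseData(synapses)
  vapply(strsplit(as.character(d$postIds), ";", fixed = TRUE),
         function(p) any(p %in% astrocyteIds), logical(1))
}

#' Transmitter composition of TPS vs vicinity synapses
#'
#' Per transmitter: its fraction among tripartite synapses and among
#' all synapses in the vicinity set, plus the enrichment (ratio of the
#' two fractions). Each fraction column sums to 1.
#'
#' @param synapses a [SynapseTable-class].
#' @param tpsFlags logical TPS flag per record ([classifyTps()]).
#' @param vicinityIdx indices of records in the vicinity set (default:
#'   all records).
#' @return data.frame with `transmitter`, `nTps`, `nVicinity`,
#'   `fracTps`, `fracVicinity`, `enrichment`.
#' @export
transmitterRatios <- function(synapses, tpsFlags,
                              vicinityIdx = seq_len(nSynapses(synapses))) {
  d <- synapseData(synapses)
  if (!any(tpsFlags))
    stop("TPS set is empty: ratios undefined", call. = FALSE)
  if (!length(vicinityIdx))
    stop("vicinity set is empty", call. = FALSE)
  tx <- as.character(d$transmitter)
  txLev <- sort(unique(tx[vicinityIdx]))
  nTps <- table(factor(tx[tpsFlags], txLev))
  nVic <- table(factor(tx[vicinityIdx], txLev))
  fracTps <- as.numeric(nTps) / sum(nTps)
  fracVic <- as.numeric(nVic) / sum(nVic)
  data.frame(transmitter = txLev, nTps = as.integer(nTps),
             nVicinity = as.integer(nVic), fracTps = fracTps,
             fracVicinity = fracVic,
             enrichment = ifelse(fracVic > 0, fracTps / fracVic, NA),
             stringsAsFactors = FALSE)
}
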