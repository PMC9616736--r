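#' Configuration for the synthetic astrocyte anatomy generator
#'
#' Generates a branched random-walk skeleton (only node positions and
#' radii matter downstream, not biological arbor shape) and synapse
#' point clouds whose distance-to-process distributions differ by
#' presynaptic transmitter. A configurable fraction of synapses lists
#' the astrocyte as a postsynaptic partner (planted tripartite
#' synapses).
#'
#' @param seed integer seed.
#' @param nNodes number of skeleton nodes.
#' @param stepSd random-walk step standard deviation per axis (nm);
#'   the default keeps typical inter-node spacing above the planted
#'   synapse offsets so that a synapse's nearest node is usually its
#'   anchor and the per-transmitter offsets survive in the realized
#'   nearest-node distances.
#' @param branchProb probability that a new node branches off a random
#'   earlier node instead of extending the current tip.
#' @param coarseFrac fraction of nodes given radii of at least 300 nm
#'   (somata / main branches, drawn uniform in `coarseRadius`); the
#'   rest draw uniform in `fineRadius`.
#' @param fineRadius,coarseRadius radius ranges in nm.
#' @param synapseCounts named counts per transmitter.
#' @param offsets named mean distance (nm) of each transmitter's
#'   synapses from their anchoring fine node; defaults follow the
#'   magnitudes reported for the fly protocerebrum (glutamate 962,
#'   GABA 971, acetylcholine 1061 nm).
#' @param distanceSd Gaussian spread of planted distances (nm).
#' @param cleftScoreMean,cleftScoreSd,connScoreMean,connScoreSd score
#'   distributions (clipped at 0); defaults straddle the quality
#'   thresholds so filtering removes a realistic share.
#' @param tpsFraction fraction of synapses planted as tripartite
#'   (astrocyte among postsynaptic partners); either a scalar or a
#'   named per-transmitter vector.
#' @param astrocyteId id string used for the skeleton and TPS partners.
#' @return List of class `SimAnatomyConfig`.
#' @export
simAnatomyConfig <- function(seed = 1L, nNodes = 2000L, stepSd = 2500,
                             branchProb = 0.1, coarseFrac = 0.05,
                             fineRadius = c(20, 299),
                             coarseRadius = c(300, 1000),
                             synapseCounts = c(glutamate = 500,
                                               GABA = 500,
                                               acetylcholine = 500),
                             offsets = c(glutamate = 962, GABA = 971,
                                         acetylcholine = 1061),
                             distanceSd = 300,
                             cleftScoreMean = 70, cleftScoreSd = 20,
                             connScoreMean = 50, connScoreSd = 15,
                             tpsFraction = 0.1,
                             astrocyteId = "astro1") {
  if (nNodes < 2L) stop("need at least 2 skeleton nodes", call. = FALSE)
  if (any(synapseCounts <= 0))
    stop("synapse counts must be positive", call. = FALSE)
  if (!all(names(synapseCounts) %in% names(offsets)))
    stop("every transmitter needs a distance offset", call. = FALSE)
  if (is.null(names(tpsFraction)) && length(tpsFraction) != 1L)
    stop("tpsFraction must be scalar or named per transmitter",
         call. = FALSE)
  structure(list(seed = as.integer(seed), nNodes = as.integer(nNodes),
                 stepSd = stepSd, branchProb = branchProb,
                 coarseFrac = coarseFrac, fineRadius = fineRadius,
                 coarseRadius = coarseRadius,
                 synapseCounts = synapseCounts, offsets = offsets,
                 distanceSd = distanceSd,
                 cleftScoreMean = cleftScoreMean,
                 cleftScoreSd = cleftScoreSd,
                 connScoreMean = connScoreMean,
                 connScoreSd = connScoreSd,
                 tpsFraction = tpsFraction,
                 astrocyteId = astrocyteId),
            class = "SimAnatomyConfig")
}

#' Simulate an astrocyte skeleton and synapse cloud with ground truth
#'
#' @param config a [simAnatomyConfig()] object.
#' @return List with `skeleton` ([Skeleton-class]), `synapses`
#'   ([SynapseTable-class]) and `truth` (planted per-synapse anchor
#'   node, planted distance, TPS flag, and the per-transmitter
#'   offsets).
#' @examples
#' sim <- simulateAnatomy(simAnatomyConfig(nNodes = 200,
#'   synapseCounts = c(glutamate = 50, acetylcholine = 50)))
#' sim$skeleton
#' @export
simulateAnatomy <- function(config = simAnatomyConfig()) {
  stopifnot(inherits(config, "SimAnatomyConfig"))
  withSeed(config$seed, {
    n <- config$nNodes
    xyz <- matrix(0, n, 3)
    parent <- integer(n); parent[1L] <- -1L
    tip <- 1L
    for (i in 2:n) {
      from <- if (stats::runif(1) < config$branchProb)
        sample.int(i - 1L, 1L) else tip
      xyz[i, ] <- xyz[from, ] + stats::rnorm(3, 0, config$stepSd)
      parent[i] <- from
      tip <- i
    }
    nCoarse <- round(config$coarseFrac * n)
    radius <- stats::runif(n, config$fineRadius[1], config$fineRadius[2])
    if (nCoarse > 0) {
      coarse <- sample.int(n, nCoarse)
      radius[coarse] <- stats::runif(nCoarse, config$coarseRadius[1],
                                     config$coarseRadius[2])
    }
    skeleton <- Skeleton(data.frame(id = seq_len(n), parent = parent,
                                    x = xyz[, 1], y = xyz[, 2],
                                    z = xyz[, 3], radius = radius),
                         astrocyteId = config$astrocyteId)

    fine <- which(radius < 300)
    if (!length(fine))
      stop("generated skeleton has no fine-process nodes", call. = FALSE)
    txs <- names(config$synapseCounts)
    tpsFrac <- if (length(config$tpsFraction) == 1L &&
                   is.null(names(config$tpsFraction)))
      stats::setNames(rep(config$tpsFraction, length(txs)), txs)
    else config$tpsFraction
    rows <- list(); truthRows <- list()
    synId <- 0L
    for (tx in txs) {
      k <- config$synapseCounts[[tx]]
      anchor <- sample(fine, k, replace = TRUE)
      dist <- pmax(0, stats::rnorm(k, config$offsets[[tx]],
                                   config$distanceSd))
      dir <- matrix(stats::rnorm(3 * k), k, 3)
      dir <- dir / sqrt(rowSums(dir^2))
      pos <- xyz[anchor, , drop = FALSE] + dir * dist
      nTps <- round(tpsFrac[[tx]] * k)
      isTps <- c(rep(TRUE, nTps), rep(FALSE, k - nTps))[sample.int(k)]
      post <- ifelse(isTps,
                     paste0("n", synId + seq_len(k), ";",
                            config$astrocyteId),
                     paste0("n", synId + seq_len(k)))
      rows[[tx]] <- data.frame(
        preId = paste0("pre", synId + seq_len(k)),
        postIds = post,
        x = pos[, 1], y = pos[, 2], z = pos[, 3],
        cleftScore = pmax(0, stats::rnorm(k, config$cleftScoreMean,
                                          config$cleftScoreSd)),
        connectionScore = pmax(0, stats::rnorm(k, config$connScoreMean,
                                               config$connScoreSd)),
        transmitter = tx, stringsAsFactors = FALSE)
      truthRows[[tx]] <- data.frame(transmitter = tx,
                                    anchorNode = anchor,
                                    plantedDistance = dist,
                                    isTps = isTps)
      synId <- synId + k
    }
    synapses <- SynapseTable(do.call(rbind, rows))
    truth <- do.call(rbind, truthRows)
    rownames(truth) <- NULL
    list(skeleton = skeleton, synapses = synapses,
         truth = list(synapses = truth, offsets = config$offsets,
                      tpsFraction = tpsFrac, nFineNodes = length(fine)))
  })
}
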