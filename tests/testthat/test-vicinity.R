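synapseFixture <- function(n, seed = 1, extent = 5000) {
  set.seed(seed)
  SynapseTable(data.frame(
    preId = paste0("pre", seq_len(n)),
    postIds = paste0("n", seq_len(n)),
    x = runif(n, -extent, extent), y = runif(n, -extent, extent),
    z = runif(n, -extent, extent),
    cleftScore = runif(n, 0, 100), connectionScore = runif(n, 0, 100),
    transmitter = sample(c("glutamate", "acetylcholine"), n, TRUE),
    stringsAsFactors = FALSE))
}

test_that("synapse quality filter is inclusive at the thresholds", {
  d <- data.frame(preId = paste0("p", 1:4), postIds = "n1",
                  x = 0, y = 0, z = 0,
                  cleftScore = c(50, 49.9, 0, 80),
                  connectionScore = c(33, 100, 100, 32.9),
                  transmitter = "glutamate")
  kept <- filterSynapses(SynapseTable(d))
  expect_equal(synapseData(kept)$preId, c("p1"))
  # planted pass counts recovered exactly
  d2 <- d[rep(1, 100), ]
  d2$cleftScore <- c(rep(60, 40), rep(10, 60))
  expect_equal(nSynapses(filterSynapses(SynapseTable(d2))), 40L)
  # missing scores are rejected with a warning
  d$cleftScore[2] <- NA
  expect_warning(f <- filterSynapses(SynapseTable(d)), "missing")
  expect_equal(nSynapses(f), 1L)
})

test_that("fine process selection uses a strict 300 nm radius bound", {
  nd <- data.frame(id = 1:4, parent = c(-1, 1, 2, 3), x = 0, y = 0,
                   z = 0, radius = c(299, 300, 301, 50))
  sk <- Skeleton(nd)
  fine <- fineProcessNodes(sk)
  expect_setequal(fine$id, c(1, 4))
  coarseOnly <- Skeleton(data.frame(id = 1, parent = -1, x = 0, y = 0,
                                    z = 0, radius = 400))
  expect_warning(fineProcessNodes(coarseOnly), "no nodes")
  # generator radius mix gives the exact planted count
  sim <- simulateAnatomy(simAnatomyConfig(seed = 13, nNodes = 400,
                                          coarseFrac = 0.1,
                                          synapseCounts = c(glutamate = 20)))
  expect_equal(nrow(fineProcessNodes(sim$skeleton)), 400L - 40L)
})

test_that("vicinity distances equal exhaustive brute force", {
  set.seed(21)
  nodes <- data.frame(id = 1:50, parent = -1,
                      x = runif(50, -3000, 3000),
                      y = runif(50, -3000, 3000),
                      z = runif(50, -3000, 3000), radius = 100)
  syn <- synapseFixture(200, seed = 22)
  prof <- vicinityProfile(nodes, syn, halfWidth = 1e9)
  oracle <- bruteNearest(as.matrix(nodes[, c("x", "y", "z")]),
                         as.matrix(as.data.frame(
                           synapseData(syn)[, c("x", "y", "z")])))
  got <- unsplit(prof$distances,
                 as.character(synapseData(syn)$transmitter))
  expect_equal(got, oracle, tolerance = 1e-12)
  # a synapse exactly at a node has distance zero
  d0 <- as.data.frame(synapseData(syn))
  d0$x[1] <- nodes$x[7]; d0$y[1] <- nodes$y[7]; d0$z[1] <- nodes$z[7]
  p0 <- vicinityProfile(nodes, SynapseTable(d0), halfWidth = 1e9)
  expect_equal(min(unlist(p0$distances)), 0)
})

test_that("box and sphere vicinity modes gate candidates correctly", {
  nodes <- data.frame(id = 1, parent = -1, x = 0, y = 0, z = 0,
                      radius = 100)
  # corner point: inside the 2 um box but outside the 2 um ball
  d <- data.frame(preId = c("a", "b", "c"), postIds = "n",
                  x = c(1900, 1900, 2100), y = c(1900, 1900, 0),
                  z = c(1900, 1900, 0),
                  cleftScore = 60, connectionScore = 60,
                  transmitter = "glutamate")
  syn <- SynapseTable(d)
  pBox <- vicinityProfile(nodes, syn, mode = "box")
  pSph <- vicinityProfile(nodes, syn, mode = "sphere")
  expect_equal(length(pBox$candidates), 2L)   # corner pair kept
  expect_equal(length(pSph$candidates), 0L)   # all beyond 2000 nm radius
})

test_that("vicinity profile is invariant under rigid motion", {
  set.seed(23)
  nodes <- data.frame(id = 1:30, parent = -1,
                      x = runif(30, -2000, 2000),
                      y = runif(30, -2000, 2000),
                      z = runif(30, -2000, 2000), radius = 100)
  syn <- synapseFixture(100, seed = 24, extent = 2500)
  p1 <- vicinityProfile(nodes, syn, mode = "sphere")
  # rotate both clouds about z and translate
  th <- 0.7; R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0,
                           0, 0, 1), 3)
  shift <- c(500, -300, 800)
  rot <- function(m) sweep(as.matrix(m) %*% t(R), 2, -shift)
  nodes2 <- nodes
  nodes2[, c("x", "y", "z")] <- rot(nodes[, c("x", "y", "z")])
  d2 <- as.data.frame(synapseData(syn))
  d2[, c("x", "y", "z")] <- rot(d2[, c("x", "y", "z")])
  p2 <- vicinityProfile(nodes2, SynapseTable(d2), mode = "sphere")
  expect_equal(sort(unlist(p1$distances)), sort(unlist(p2$distances)),
               tolerance = 1e-9)
})

test_that("bootstrap means are consistent and identical inputs give p 1", {
  set.seed(31)
  a <- rnorm(200, 1000, 300)
  bt <- bootstrapMeanTest(a, a, nBoot = 2000, seed = 5)
  expect_equal(bt$p.boot, 1)               # same resamples both groups
  expect_equal(bt$meanDiff, 0)
  # mean of bootstrap means within 2 SEM of the sample mean
  sem <- sd(a) / sqrt(length(a))
  expect_lt(abs(mean(bt$bootMeansA) - mean(a)), 2 * sem)
  expect_error(bootstrapMeanTest(a[1:5], a), "at least 10")
})

test_that("bootstrap/Welch procedure detects a 100 nm planted shift", {
  hits <- vapply(1:20, function(s) {
    set.seed(200 + s)
    a <- rnorm(500, 900, 300)
    b <- rnorm(500, 1000, 300)
    bootstrapMeanTest(a, b, nBoot = 2000, seed = s)$p.boot < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("raw-distance Welch test is calibrated under the null", {
  set.seed(33)
  ps <- replicate(200, {
    a <- rnorm(200, 1000, 300)
    b <- rnorm(200, 1000, 300)
    thirstState:::welchTest(a, b)$p.value
  })
  rate <- mean(ps < 0.05)
  mcErr <- 2 * sqrt(0.05 * 0.95 / 200)
  expect_lte(rate, 0.05 + mcErr + 1e-12)
  # cross-check the Welch implementation against stats::t.test
  a <- rnorm(50); b <- rnorm(60, 0.5)
  expect_equal(thirstState:::welchTest(a, b)$p.value,
               t.test(a, b)$p.value, tolerance = 1e-12)
})

test_that("TPS flags follow postsynaptic partner membership", {
  d <- data.frame(preId = c("p1", "p2", "p3"),
                  postIds = c("n1;astroA", "n2", "astroB"),
                  x = 0, y = 0, z = 0, cleftScore = 60,
                  connectionScore = 60, transmitter = "glutamate")
  syn <- SynapseTable(d)
  expect_identical(classifyTps(syn, c("astroA", "astroB")),
                   c(TRUE, FALSE, TRUE))
  expect_identical(classifyTps(syn, "astroZ"), rep(FALSE, 3))
  # deterministic rerun
  expect_identical(classifyTps(syn, "astroA"),
                   classifyTps(syn, "astroA"))
})

test_that("transmitter ratios normalize and recover planted enrichment", {
  # single-transmitter input: both fractions one, enrichment one
  d <- data.frame(preId = paste0("p", 1:10),
                  postIds = c(rep("n;astro1", 3), rep("n", 7)),
                  x = 0, y = 0, z = 0, cleftScore = 60,
                  connectionScore = 60, transmitter = "glutamate")
  syn <- SynapseTable(d)
  r <- transmitterRatios(syn, classifyTps(syn, "astro1"))
  expect_equal(r$fracTps, 1)
  expect_equal(r$enrichment, 1)
  expect_error(transmitterRatios(syn, rep(FALSE, 10)), "empty")
  # planted 2x glutamate enrichment among TPS
  sim <- simulateAnatomy(simAnatomyConfig(
    seed = 35, nNodes = 300,
    synapseCounts = c(glutamate = 400, acetylcholine = 400),
    tpsFraction = c(glutamate = 0.2, acetylcholine = 0.1)))
  tps <- classifyTps(sim$synapses, "astro1")
  rt <- transmitterRatios(sim$synapses, tps)
  glu <- rt[rt$transmitter == "glutamate", ]
  ach <- rt[rt$transmitter == "acetylcholine", ]
  expect_equal(glu$enrichment / ach$enrichment, 2, tolerance = 0.05)
  # fractions sum to one per column
  expect_equal(sum(rt$fracTps), 1)
  expect_equal(sum(rt$fracVicinity), 1)
})

test_that("planted transmitter offsets survive into group distances", {
  sim <- simulateAnatomy(simAnatomyConfig(
    seed = 37, synapseCounts = c(glutamate = 500, acetylcholine = 500)))
  prof <- vicinityProfile(sim$skeleton, filterSynapses(sim$synapses))
  expect_lt(mean(prof$distances$glutamate),
            mean(prof$distances$acetylcholine))
  bt <- bootstrapMeanTest(prof$distances$glutamate,
                          prof$distances$acetylcholine,
                          nBoot = 2000, seed = 1)
  expect_lt(bt$p.boot, 0.05)
})
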