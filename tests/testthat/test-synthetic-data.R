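test_that("count generator is deterministic and respects doublet rate", {
  cfg <- simCountsConfig(seed = 11, nGenes = 400, nCells = 150,
                         doubletRate = 0.1)
  sce1 <- simulateCounts(cfg)
  sce2 <- simulateCounts(cfg)
  expect_identical(as.matrix(assay(sce1, "counts")),
                   as.matrix(assay(sce2, "counts")))
  expect_identical(colData(sce1)$trueClass, colData(sce2)$trueClass)
  expect_equal(sum(colData(sce1)$isDoublet), round(0.1 * 150))

  sce0 <- simulateCounts(simCountsConfig(seed = 11, nGenes = 400,
                                         nCells = 100, doubletRate = 0))
  expect_false(any(colData(sce0)$isDoublet))
  # every cell appears exactly once in the truth
  expect_equal(nrow(colData(sce0)), 100L)
  expect_false(anyDuplicated(colData(sce0)$barcode) > 0)
})

test_that("generated zero fraction matches the NB closed form when pi = 0", {
  sce <- simulateCounts(simCountsConfig(seed = 5, nGenes = 500,
                                        nCells = 2000, doubletRate = 0,
                                        pi = 0))
  cnt <- as.matrix(assay(sce, "counts"))
  rd <- rowData(sce)
  bg <- rd$geneGroup == "background"
  obs <- rowMeans(cnt[bg, ] == 0)
  expe <- nbZeroProb(rd$mu[bg], rd$theta[bg])
  se <- sqrt(expe * (1 - expe) / ncol(cnt))
  # within 3 standard errors for almost all genes (Monte-Carlo error)
  expect_gt(mean(abs(obs - expe) <= 3 * pmax(se, 1e-4)), 0.98)
})

test_that("generated count moments match ZINB expectations", {
  mu <- 5; theta <- 2; pi <- 0.2
  sce <- simulateCounts(simCountsConfig(seed = 7, nGenes = 200,
                                        nCells = 2000, doubletRate = 0,
                                        muMeanLog = log(mu), muSdLog = 0,
                                        theta = theta, pi = pi))
  rd <- rowData(sce)
  bg <- which(rd$geneGroup == "background")
  cnt <- as.matrix(assay(sce, "counts"))[bg, ]
  emean <- (1 - pi) * mu
  evar <- (1 - pi) * mu * (1 + mu / theta + pi * mu)
  seMean <- sqrt(evar / ncol(cnt))
  expect_gt(mean(abs(rowMeans(cnt) - emean) <= 3 * seMean), 0.95)
  # pooled variance close to the ZINB variance
  expect_lt(abs(mean(apply(cnt, 1, var)) / evar - 1), 0.05)
})

test_that("condition effect multiplies means by 2^log2FC for DE genes", {
  de <- data.frame(gene = c("gene0100", "gene0101"), log2FC = c(2, -1))
  sce <- simulateCounts(simCountsConfig(seed = 9, nGenes = 400,
                                        nCells = 3000, doubletRate = 0,
                                        deSpec = de))
  cnt <- as.matrix(assay(sce, "counts"))
  cond <- colData(sce)$condition
  for (i in seq_len(nrow(de))) {
    m1 <- mean(cnt[de$gene[i], cond == "sated"])
    m2 <- mean(cnt[de$gene[i], cond == "dehydrated12h"])
    expect_equal(log2(m2 / m1), de$log2FC[i], tolerance = 0.35)
  }
})

test_that("trace generator plants categories at configured fractions", {
  cfg <- simTracesConfig(seed = 2, nCells = 200)
  ts1 <- simulateTraces(cfg)
  ts2 <- simulateTraces(cfg)
  expect_identical(traces(ts1), traces(ts2))
  tab <- table(cellData(ts1)$truthCategory)
  expect_equal(as.integer(tab[c("activated", "no_change", "inhibited")]),
               c(36, 96, 68))
  # 60 s at 5.92 Hz -> 355 frames
  ts3 <- simulateTraces(simTracesConfig(seed = 1, nCells = 2,
                                        baselineSeconds = 20,
                                        drugSeconds = 25,
                                        postSeconds = 15))
  expect_equal(nFrames(ts3), floor(60 * 5.92))
  expect_equal(nFrames(ts3), 355L)
})

test_that("zero-amplitude traces are indistinguishable from baseline", {
  ts <- simulateTraces(simTracesConfig(seed = 4, nCells = 150,
                                       amplitudes = c(activated = 0,
                                                      no_change = 0,
                                                      inhibited = 0)))
  calls <- classifyResponses(ts)
  # windowed means differ only by noise: overwhelmingly no_change
  expect_gt(mean(calls$category == "no_change"), 0.9)
})

test_that("trace generator rejects invalid configurations", {
  expect_error(simTracesConfig(frameRate = 0), "frame rate")
  expect_error(simTracesConfig(drugSeconds = -1), "positive")
  expect_error(simTracesConfig(fractions = c(activated = 0.5,
                                             no_change = 0.5,
                                             inhibited = 0.5)), "sum")
})

test_that("anatomy generator is deterministic with planted structure", {
  cfg <- simAnatomyConfig(seed = 3, nNodes = 300,
                          synapseCounts = c(glutamate = 80, GABA = 60))
  s1 <- simulateAnatomy(cfg)
  s2 <- simulateAnatomy(cfg)
  expect_identical(skeletonNodes(s1$skeleton), skeletonNodes(s2$skeleton))
  expect_identical(as.data.frame(synapseData(s1$synapses)),
                   as.data.frame(synapseData(s2$synapses)))
  # radius mix is exact: coarseFrac of nodes at >= 300 nm
  nd <- skeletonNodes(s1$skeleton)
  expect_equal(sum(nd$radius >= 300), round(0.05 * 300))
  # planted TPS fraction is exact per transmitter
  tps <- classifyTps(s1$synapses, "astro1")
  tx <- synapseData(s1$synapses)$transmitter
  expect_equal(sum(tps[tx == "glutamate"]), round(0.1 * 80))
  expect_equal(sum(tps[tx == "GABA"]), round(0.1 * 60))
})

test_that("zero TPS fraction yields an empty TPS set", {
  sim <- simulateAnatomy(simAnatomyConfig(seed = 8, nNodes = 200,
                                          synapseCounts = c(glutamate = 50),
                                          tpsFraction = 0))
  expect_equal(sum(classifyTps(sim$synapses, "astro1")), 0L)
})

test_that("equal planted offsets leave no transmitter difference", {
  # under the generator's null the calibrated raw-distance comparison
  # should rarely reject
  ps <- vapply(1:12, function(s) {
    sim <- simulateAnatomy(simAnatomyConfig(
      seed = 100 + s, nNodes = 400,
      synapseCounts = c(glutamate = 150, acetylcholine = 150),
      offsets = c(glutamate = 1000, acetylcholine = 1000)))
    prof <- vicinityProfile(sim$skeleton, filterSynapses(sim$synapses))
    bootstrapMeanTest(prof$distances$glutamate,
                      prof$distances$acetylcholine,
                      nBoot = 200, seed = s)$p.raw
  }, numeric(1))
  expect_gte(mean(ps >= 0.05), 0.9)
})

test_that("config validation catches out-of-range parameters", {
  expect_error(simCountsConfig(doubletRate = 1), "doubletRate")
  expect_error(simCountsConfig(pi = 1.2), "ZINB")
  expect_error(simCountsConfig(classes = list(
    list(name = "a", fraction = 0.7, markers = "m1"),
    list(name = "b", fraction = 0.6, markers = "m2"))), "fractions")
  expect_error(simAnatomyConfig(nNodes = 1), "at least 2")
  expect_error(simAnatomyConfig(synapseCounts = c(glutamate = 0)),
               "positive")
})
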