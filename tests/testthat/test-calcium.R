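# constructed TraceSet: baseline 100, optional plateau during drug
plateauTraces <- function(levels, f0 = 100, onset = 30, offset = 55,
                          totalS = 100, rate = 5.92) {
  nF <- floor(totalS * rate)
  tFr <- (seq_len(nF) - 1) / rate
  m <- vapply(levels, function(lv) {
    f <- rep(f0, nF)
    f[tFr >= onset & tFr < offset] <- lv
    f
  }, numeric(nF))
  colnames(m) <- sprintf("cell%02d", seq_along(levels))
  TraceSet(m, frameRate = rate, drugOnset = onset, drugOffset = offset)
}

test_that("dF/F0 uses an 83-frame baseline and the ratio identity", {
  expect_equal(round(14 * 5.92), 83)
  ts <- plateauTraces(c(100, 150))
  dff <- computeDff(ts)
  expect_true(all(dff[, 1] == 0))                 # constant trace
  expect_equal(max(dff[, 2]), 0.5)                # plateau (150-100)/100
  # scale equivariance: multiplying raw F leaves dF/F0 unchanged
  ts2 <- TraceSet(traces(ts) * 7, frameRate = frameRate(ts),
                  drugOnset = 30, drugOffset = 55)
  expect_equal(computeDff(ts2), dff)
  # non-physical baseline
  bad <- TraceSet(matrix(0, 400, 1), drugOnset = 30, drugOffset = 55)
  expect_error(computeDff(bad), "baseline")
  expect_error(TraceSet(matrix(1, 400, 1), drugOnset = 10,
                        drugOffset = 30), "14")
})

test_that("response rule classifies against the pre-window sigma band", {
  ts <- plateauTraces(c(150, 60, 100))
  calls <- classifyResponses(ts)
  expect_identical(as.character(calls$category),
                   c("activated", "inhibited", "no_change"))
  # noiseless pre window: sigma 0, equal means -> no_change tie rule
  expect_equal(unname(calls$sigmaPre[3]), 0)
  # noisy case with post mean inside the sigma band
  set.seed(101)
  nF <- 600
  f <- 100 * (1 + rnorm(nF, 0, 0.1))
  ts2 <- TraceSet(matrix(f, ncol = 1), drugOnset = 30, drugOffset = 55)
  c2 <- classifyResponses(ts2)
  expect_identical(as.character(c2$category), "no_change")
})

test_that("classifier recovers planted categories at 5x noise amplitude", {
  ts <- simulateTraces(simTracesConfig(seed = 7, nCells = 300))
  calls <- classifyResponses(ts)
  truth <- cellData(ts)$truthCategory
  expect_gte(mean(calls$category[truth == "activated"] == "activated"),
             0.95)
  expect_gte(mean(calls$category[truth == "inhibited"] == "inhibited"),
             0.95)
  # recovered fractions close to the planted ones
  frac <- prop.table(table(calls$category))
  expect_lt(abs(frac[["activated"]] - 0.18), 0.06)
})

test_that("trace AUC matches closed forms and is additive", {
  skip_if_not_installed("pracma")
  rate <- 5.92
  # constant 1 over a 25 s window
  ts <- plateauTraces(200, onset = 30, offset = 55)
  aDuring <- traceAuc(ts, "during")
  expect_lt(abs(aDuring - 25), 1 / rate + 1e-9)
  # zero series
  ts0 <- plateauTraces(100)
  expect_equal(unname(traceAuc(ts0, "during")), 0)
  # linear ramp 0 -> 1 over 10 s integrates to ~5
  nF <- floor(60 * rate)
  tFr <- (seq_len(nF) - 1) / rate
  f <- rep(100, nF)
  sel <- tFr >= 20 & tFr <= 30
  f[sel] <- 100 * (1 + (tFr[sel] - 20) / 10)
  tsr <- TraceSet(matrix(f, ncol = 1), drugOnset = 20, drugOffset = 30)
  expect_lt(abs(traceAuc(tsr, "during") - 5), 1 / rate + 1e-9)
  # cross-check the trapezoid against an independent implementation
  dff <- computeDff(tsr)[, 1]
  idx <- (floor(20 * rate) + 1):(floor(30 * rate) + 1)
  expect_equal(unname(traceAuc(tsr, "during")),
               pracma::trapz(tFr[idx], dff[idx]))
  # exact additivity of adjacent windows
  set.seed(103)
  fz <- 100 * (1 + rnorm(nF, 0, 0.2))
  tsn <- TraceSet(matrix(fz, ncol = 1), drugOnset = 20, drugOffset = 30)
  total <- traceAuc(tsn, c(20, tFr[nF]))
  expect_equal(traceAuc(tsn, "during") + traceAuc(tsn, "after"),
               total)
  expect_error(traceAuc(tsn, c(59.9, 59.95)), "fewer than 2")
})

test_that("AUC onset normalization subtracts the onset value exactly", {
  set.seed(104)
  rate <- 5.92
  nF <- floor(60 * rate)
  f <- 100 * (1 + rnorm(nF, 0, 0.2))
  ts <- TraceSet(matrix(f, ncol = 1), drugOnset = 20, drugOffset = 30)
  aRaw <- traceAuc(ts, "during")
  aNorm <- traceAuc(ts, "during", normalizeAtOnset = TRUE)
  # shifting a series by a constant v changes its trapezoid integral
  # by v times the window span
  onsetFrame <- floor(20 * rate) + 1
  v <- computeDff(ts)[onsetFrame, 1]
  span <- (floor(30 * rate) - floor(20 * rate)) / rate
  expect_equal(unname(aNorm), unname(aRaw) - v * span, tolerance = 1e-9)
})

test_that("matched/mismatched contingency reproduces the exact Fisher test", {
  a <- rep(c("activated", "inhibited"), c(40, 40))
  b <- rep(c("activated", "inhibited", "activated", "inhibited"),
           c(30, 10, 10, 30))
  rc <- responseContingency(a, b)
  expect_equal(rc$oddsRatio, 9)
  expect_equal(rc$matched, 60)
  expect_equal(rc$p.value,
               fisher.test(matrix(c(30, 10, 10, 30), 2))$p.value)
  # independence table
  ai <- rep(c("activated", "inhibited"), each = 50)
  bi <- rep(rep(c("activated", "inhibited"), each = 25), 2)
  ri <- responseContingency(ai, bi)
  expect_equal(ri$oddsRatio, 1)
  expect_equal(ri$p.value, 1)
  # no_change cells are excluded from the 2x2
  rc2 <- responseContingency(c(a, "no_change"), c(b, "activated"))
  expect_equal(sum(rc2$table), 80)
  # 3x3 agreement mode
  r3 <- responseContingency(c(a, "no_change"), c(b, "no_change"),
                            mode = "3x3")
  expect_equal(r3$matched, 61)
})

test_that("Fisher p equals hypergeometric enumeration on many tables", {
  set.seed(105)
  for (i in 1:40) {
    n <- sample(10:200, 1)
    x <- as.vector(rmultinom(1, n, runif(4, 0.1, 1)))
    rc <- thirstState:::fisherExactP(x[1], x[2], x[3], x[4])
    ft <- fisher.test(matrix(x, 2, byrow = TRUE))$p.value
    expect_equal(rc, ft, tolerance = 1e-9)
  }
})

test_that("zero-margin tables get the Haldane-corrected odds ratio", {
  a <- rep("activated", 20)
  b <- rep(c("activated", "inhibited"), c(15, 5))
  rc <- responseContingency(a, b)
  expect_true(rc$haldane)
  expect_true(is.finite(rc$oddsRatio))
  expect_true(rc$p.value >= 0 && rc$p.value <= 1)
})

test_that("proportion shift tests use Bonferroni-corrected exact tests", {
  # identical proportions: corrected p near 1
  tabEq <- rbind(sated = c(activated = 40, no_change = 120, inhibited = 40),
                 thirsty = c(activated = 40, no_change = 120,
                             inhibited = 40))
  resEq <- proportionShiftTest(tabEq)
  expect_gte(min(resEq$p.bonferroni), 0.99)
  # two comparisons with raw p 0.03 -> corrected 0.06
  expect_equal(min(1, 0.03 * 2), 0.06)
  tab3 <- rbind(s1 = c(activated = 10, no_change = 90),
                s2 = c(activated = 10, no_change = 90),
                s3 = c(activated = 30, no_change = 70))
  res3 <- proportionShiftTest(tab3)
  expect_equal(nrow(res3), 3L)
  expect_equal(res3$p.bonferroni,
               pmin(1, res3$p.value * 3))
  expect_error(proportionShiftTest(tab3[1, , drop = FALSE]),
               "two non-empty")
})

test_that("a planted 18% to 34% activation shift is detected", {
  # mirrors the observed sated-vs-thirsty glutamate shift at n = 200
  hits <- vapply(1:10, function(s) {
    set.seed(110 + s)
    sated <- rbinom(1, 200, 0.18)
    thirsty <- rbinom(1, 200, 0.34)
    tab <- rbind(sated = c(activated = sated, rest = 200 - sated),
                 thirsty = c(activated = thirsty, rest = 200 - thirsty))
    proportionShiftTest(tab)$p.bonferroni < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
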