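# dF/F0 computation and windowed response classification for
# drug-application calcium imaging at a fixed frame rate.

# frame indices covering the `seconds`-long window that ends just
# before `onset` (pre) — round to the nearest frame, so 14 s at
# 5.92 Hz gives 83 frames
preWindowFrames <- function(onset, rate, seconds = 14) {
  nPre <- round(seconds * rate)
  onsetFrame <- floor(onset * rate) + 1L
  idx <- (onsetFrame - nPre):(onsetFrame - 1L)
  if (min(idx) < 1L)
    stop("trace too short: ", seconds,
         " s of pre-drug frames required", call. = FALSE)
  idx
}

postWindowFrames <- function(onset, rate, seconds = 25, nMax) {
  nPost <- round(seconds * rate)
  onsetFrame <- floor(onset * rate) + 1L
  idx <- onsetFrame:(onsetFrame + nPost - 1L)
  if (max(idx) > nMax)
    stop("trace too short: ", seconds,
         " s post-onset frames required", call. = FALSE)
  idx
}

#' Compute dF/F0 relative to a pre-drug baseline
#'
#' The baseline `F0` is the mean fluorescence over the 14 s window
#' immediately before drug onset (83 frames at 5.92 Hz); the returned
#' series is `(F - F0) / F0` per cell. Because the series is a ratio,
#' rescaling the raw fluorescence leaves it unchanged.
#'
#' @param ts a [TraceSet-class].
#' @param baselineSeconds baseline window length (default 14 s).
#' @return Matrix of dF/F0 values, frames x cells.
#' @examples
#' f <- matrix(100, 400, 2)
#' ts <- TraceSet(f, drugOnset = 30, drugOffset = 55)
#' range(computeDff(ts))   # all zero
#' @export
computeDff <- function(ts, baselineSeconds = 14) {
  stopifnot(methods::is(ts, "TraceSet"))
  pre <- preWindowFrames(ts@drugOnset, ts@frameRate, baselineSeconds)
  f0 <- colMeans(ts@traces[pre, , drop = FALSE])
  if (any(f0 <= 0))
    stop("non-physical baseline: F0 <= 0 for cell(s) ",
         paste(which(f0 <= 0), collapse = ", "), call. = FALSE)
  sweep(sweep(ts@traces, 2, f0, "-"), 2, f0, "/")
}

#' Classify drug responses from dF/F0 windows
#'
#' Implements the windowed response rule: with the pre-drug mean
#' normalized to 0 per cell, a cell is `activated` when the post-onset
#' mean exceeds the pre-window standard deviation, `inhibited` when it
#' falls below its negative, and `no_change` otherwise. The pre window
#' is the 14 s before onset; the post window the 25 s from onset. A
#' zero-variance pre window with equal means is called `no_change`.
#'
#' @param ts a [TraceSet-class].
#' @param preSeconds,postSeconds window lengths (defaults 14 and 25 s).
#' @return `DataFrame` with `category` (factor activated / no_change /
#'   inhibited), `muPre` (raw pre mean), `sigmaPre` (sample sd of the
#'   pre window) and `muPost` (post mean after pre-normalization to 0),
#'   one row per cell.
#' @export
classifyResponses <- function(ts, preSeconds = 14, postSeconds = 25) {
  dff <- computeDff(ts, preSeconds)
  pre <- preWindowFrames(ts@drugOnset, ts@frameRate, preSeconds)
  post <- postWindowFrames(ts@drugOnset, ts@frameRate, postSeconds,
                           nrow(dff))
  muPre <- colMeans(dff[pre, , drop = FALSE])
  sigmaPre <- apply(dff[pre, , drop = FALSE], 2, stats::sd)
  muPost <- colMeans(dff[post, , drop = FALSE]) - muPre
  category <- rep("no_change", ncol(dff))
  category[muPost > sigmaPre] <- "activated"
  category[muPost < -sigmaPre] <- "inhibited"
  DataFrame(category = factor(category,
                              levels = c("activated", "no_change",
                                         "inhibited")),
            muPre = muPre, sigmaPre = sigmaPre, muPost = muPost,
            row.names = colnames(ts@traces))
}

#' Area under the dF/F0 curve over a window
#'
#' Trapezoidal integral of each cell's dF/F0 series over a time window
#' at the frame spacing `1/frameRate`, in units of dF/F0 x seconds.
#' Windows sharing a boundary are exactly additive:
#' `AUC(during) + AUC(after) = AUC(during + after)`.
#'
#' @param ts a [TraceSet-class].
#' @param window `"during"` (onset to offset), `"after"` (offset to end
#'   of recording), or a numeric `c(start, end)` in seconds.
#' @param normalizeAtOnset shift each cell's series so the value at
#'   drug onset equals 0 before integrating (default `FALSE`).
#' @return Named numeric vector of areas, one per cell.
#' @export
traceAuc <- function(ts, window = "during", normalizeAtOnset = FALSE) {
  dff <- computeDff(ts)
  rate <- ts@frameRate
  tFrames <- (seq_len(nrow(dff)) - 1L) / rate
  win <- if (is.character(window)) {
    switch(match.arg(window, c("during", "after")),
           during = c(ts@drugOnset, ts@drugOffset),
           after = c(ts@drugOffset, tFrames[length(tFrames)]))
  } else as.numeric(window)
  # frame-index bounds, so adjacent windows share their boundary frame
  # and areas are exactly additive
  startFrame <- max(1L, floor(win[1] * rate) + 1L)
  endFrame <- min(nrow(dff), floor(win[2] * rate) + 1L)
  sel <- startFrame:endFrame
  if (length(sel) < 2L)
    stop("window [", win[1], ", ", win[2], "] s covers fewer than 2 frames",
         call. = FALSE)
  if (normalizeAtOnset) {
    onsetFrame <- floor(ts@drugOnset * rate) + 1L
    dff <- sweep(dff, 2, dff[onsetFrame, ], "-")
  }
  apply(dff[sel, , drop = FALSE], 2, trapezoid, dx = 1 / rate)
}

#' Matched vs mismatched response contingency between two drugs
#'
#' Cross-tabulates per-cell response calls for two drugs. The default
#' `"2x2"` mode restricts to cells that were activated or inhibited
#' under both drugs and forms the 2x2 table of drug-A direction by
#' drug-B direction; "matched" means the same direction for both. The
#' odds ratio is the cross-product `ad/bc` (with a Haldane-Anscombe
#' 0.5 correction and a note when a margin is zero) and the two-sided
#' p-value is the exact Fisher probability computed from the
#' hypergeometric distribution. A `"3x3"` agreement mode tabulates all
#' three categories and reports a chi-square test instead.
#'
#' @param callsA,callsB per-cell category vectors (values among
#'   activated / no_change / inhibited), same cells, same order.
#' @param mode `"2x2"` (default) or `"3x3"`.
#' @return List with `table`, `matched`, `mismatched`, and for the 2x2
#'   mode `oddsRatio`, `p.value`, `haldane`; the 3x3 mode reports a
#'   chi-square `p.value`.
#' @examples
#' a <- rep(c("activated", "inhibited"), c(40, 40))
#' b <- rep(c("activated", "inhibited", "activated", "inhibited"),
#'          c(30, 10, 10, 30))
#' responseContingency(a, b)$oddsRatio   # 9
#' @export
responseContingency <- function(callsA, callsB, mode = c("2x2", "3x3")) {
  mode <- match.arg(mode)
  callsA <- as.character(callsA); callsB <- as.character(callsB)
  if (length(callsA) != length(callsB))
    stop("call vectors must align cell-by-cell", call. = FALSE)
  if (mode == "3x3") {
    lev <- c("activated", "no_change", "inhibited")
    tab <- table(factor(callsA, lev), factor(callsB, lev))
    matched <- sum(diag(tab))
    p <- tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
                  error = function(e) NA_real_)
    return(list(table = tab, matched = matched,
                mismatched = sum(tab) - matched, p.value = p))
  }
  lev <- c("activated", "inhibited")
  sel <- callsA %in% lev & callsB %in% lev
  tab <- table(factor(callsA[sel], lev), factor(callsB[sel], lev))
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  haldane <- any(rowSums(tab) == 0) || any(colSums(tab) == 0) ||
    (b * c == 0 && a * d == 0) || any(tab == 0)
  or <- if (haldane) ((a + .5) * (d + .5)) / ((b + .5) * (c + .5))
        else (a * d) / (b * c)
  list(table = tab, matched = a + d, mismatched = b + c,
       oddsRatio = or, p.value = fisherExactP(a, b, c, d),
       haldane = haldane)
}

#' Pairwise shift in response proportions across states
#'
#' For category counts tabulated per internal state (rows) and response
#' category (columns), collapses categories to responsive vs not and
#' tests every pair of states with the exact Fisher test, Bonferroni
#' correcting over the number of comparisons (p multiplied by the
#' comparison count, capped at 1).
#'
#' @param countTable matrix of counts, states x categories, with
#'   dimnames.
#' @param responsive category column(s) treated as "responsive"
#'   (default `"activated"`).
#' @return data.frame with one row per state pair: `stateA`, `stateB`,
#'   `p.value`, `p.bonferroni`.
#' @export
proportionShiftTest <- function(countTable, responsive = "activated") {
  countTable <- as.matrix(countTable)
  if (is.null(rownames(countTable)) || is.null(colnames(countTable)))
    stop("countTable needs state rownames and category colnames",
         call. = FALSE)
  keep <- rowSums(countTable) > 0
  countTable <- countTable[keep, , drop = FALSE]
  states <- rownames(countTable)
  if (length(states) < 2L)
    stop("need at least two non-empty states", call. = FALSE)
  respSel <- colnames(countTable) %in% responsive
  if (!any(respSel))
    stop("responsive category not found in table", call. = FALSE)
  pairs <- utils::combn(states, 2L)
  nComp <- ncol(pairs)
  res <- lapply(seq_len(nComp), function(k) {
    s1 <- pairs[1, k]; s2 <- pairs[2, k]
    r1 <- sum(countTable[s1, respSel]); n1 <- sum(countTable[s1, ])
    r2 <- sum(countTable[s2, respSel]); n2 <- sum(countTable[s2, ])
    p <- fisherExactP(r1, n1 - r1, r2, n2 - r2)
    data.frame(stateA = s1, stateB = s2, p.value = p,
               p.bonferroni = min(1, p * nComp),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
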