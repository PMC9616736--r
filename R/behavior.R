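# Behavioral index formulas: two-choice preference and capillary
# feeder (CAFE) consumption with evaporation correction.

#' Two-choice preference index
#'
#' `PI = (nA - nB) / (nA + nB)`, in `[-1, 1]`. The same formula serves
#' the humidity T-maze (wet vs dry arm) and food-choice assays. The
#' index is antisymmetric: `preferenceIndex(a, b) ==
#' -preferenceIndex(b, a)`.
#'
#' @param nA,nB non-negative counts in each option (vectorized).
#' @return Numeric preference index (option A positive).
#' @examples
#' preferenceIndex(30, 10)   # 0.5
#' @export
preferenceIndex <- function(nA, nB) {
  if (any(nA < 0) || any(nB < 0))
    stop("counts must be non-negative", call. = FALSE)
  total <- nA + nB
  if (any(total == 0))
    stop("preference index undefined: no flies counted", call. = FALSE)
  (nA - nB) / total
}

#' Evaporation-corrected CAFE consumption
#'
#' Corrected volume is the summed capillary consumption minus the mean
#' evaporation-control volume, floored at 0. The per-fly volume
#' divides by the number of survivors at the end of the assay
#' (`deathAdjust = "end"`, the default) or by the mean of the starting
#' and surviving counts (`"mean"`).
#'
#' @param volumes consumed volumes per capillary (uL).
#' @param evapControls volumes lost from fly-free control capillaries
#'   (uL); at least one required.
#' @param fliesStart,fliesEnd fly counts at assay start and end.
#' @param deathAdjust survivor normalization rule, `"end"` or
#'   `"mean"`.
#' @return List with `corrected` (uL) and `perFly` (uL/fly).
#' @examples
#' cafeConsumption(c(1.5, 1.5), 0.5, fliesStart = 12, fliesEnd = 10)
#' @export
cafeConsumption <- function(volumes, evapControls, fliesStart,
                            fliesEnd = fliesStart,
                            deathAdjust = c("end", "mean")) {
  deathAdjust <- match.arg(deathAdjust)
  if (!length(evapControls))
    stop("at least one evaporation control is required", call. = FALSE)
  if (any(volumes < 0) || any(evapControls < 0))
    stop("volumes must be non-negative", call. = FALSE)
  if (fliesEnd > fliesStart)
    stop("fliesEnd cannot exceed fliesStart", call. = FALSE)
  if (fliesEnd <= 0)
    stop("no surviving flies: per-fly volume undefined", call. = FALSE)
  corrected <- max(0, sum(volumes) - mean(evapControls))
  denom <- switch(deathAdjust, end = fliesEnd,
                  mean = (fliesStart + fliesEnd) / 2)
  list(corrected = corrected, perFly = corrected / denom)
}
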