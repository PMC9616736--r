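#' Configuration for the synthetic fluorescence trace generator
#'
#' Traces emulate single-cell calcium recordings during bath drug
#' application at a fixed frame rate: Gaussian noise around a baseline
#' fluorescence, plus — for planted `activated` / `inhibited` cells — a
#' sustained positive / negative step during the drug window. A
#' sustained step (rather than a kinetic transient) is the simplest
#' signal that exercises the windowed-mean classification rule, which
#' is insensitive to response shape.
#'
#' @param seed integer seed.
#' @param nCells number of traces.
#' @param frameRate acquisition rate in Hz (default 5.92).
#' @param baselineSeconds,drugSeconds,postSeconds segment durations;
#'   the drug window starts at `baselineSeconds` (default 20, 25, 20 s).
#' @param f0 baseline fluorescence (a.u.).
#' @param noiseSd per-frame Gaussian noise, in dF/F0 units.
#' @param amplitudes named step amplitudes (dF/F0 units) for
#'   `activated`, `no_change`, `inhibited`; the defaults put the
#'   activated step at five times the noise sd.
#' @param fractions named category fractions summing to 1; defaults
#'   follow the response proportions observed for glutamate in sated
#'   animals (roughly 18% activated, 48% no change, 34% inhibited).
#' @param drugName compound label.
#' @return List of class `SimTracesConfig`.
#' @export
simTracesConfig <- function(seed = 1L, nCells = 300L, frameRate = 5.92,
                            baselineSeconds = 20, drugSeconds = 25,
                            postSeconds = 20, f0 = 100, noiseSd = 0.1,
                            amplitudes = c(activated = 0.5,
                                           no_change = 0,
                                           inhibited = -0.5),
                            fractions = c(activated = 0.18,
                                          no_change = 0.48,
                                          inhibited = 0.34),
                            drugName = "glutamate") {
  if (frameRate <= 0) stop("frame rate must be positive", call. = FALSE)
  if (any(c(baselineSeconds, drugSeconds, postSeconds) <= 0))
    stop("segment durations must be positive", call. = FALSE)
  if (baselineSeconds < 14)
    stop("baseline must be at least 14 s for the F0 window",
         call. = FALSE)
  cats <- c("activated", "no_change", "inhibited")
  if (!all(cats %in% names(amplitudes)) ||
      !all(cats %in% names(fractions)))
    stop("amplitudes and fractions must name all three categories",
         call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions < 0))
    stop("category fractions must be non-negative and sum to 1",
         call. = FALSE)
  structure(list(seed = as.integer(seed), nCells = as.integer(nCells),
                 frameRate = frameRate,
                 baselineSeconds = baselineSeconds,
                 drugSeconds = drugSeconds, postSeconds = postSeconds,
                 f0 = f0, noiseSd = noiseSd,
                 amplitudes = amplitudes[cats],
                 fractions = fractions[cats], drugName = drugName),
            class = "SimTracesConfig")
}

#' Simulate fluorescence traces with planted response categories
#'
#' @param config a [simTracesConfig()] object.
#' @return A [TraceSet-class]; the planted category per cell is in
#'   `cellData(ts)$truthCategory`.
#' @examples
#' ts <- simulateTraces(simTracesConfig(nCells = 20))
#' table(cellData(ts)$truthCategory)
#' @export
simulateTraces <- function(config = simTracesConfig()) {
  stopifnot(inherits(config, "SimTracesConfig"))
  withSeed(config$seed, {
    rate <- config$frameRate
    totalS <- config$baselineSeconds + config$drugSeconds +
      config$postSeconds
    nF <- floor(totalS * rate)
    onset <- config$baselineSeconds
    offset <- onset + config$drugSeconds
    cats <- names(config$fractions)
    nPer <- floor(config$fractions * config$nCells)
    nPer[1L] <- nPer[1L] + (config$nCells - sum(nPer))
    truth <- sample(rep(cats, nPer))
    tFrames <- (seq_len(nF) - 1L) / rate
    inDrug <- tFrames >= onset & tFrames < offset
    dff <- vapply(seq_len(config$nCells), function(j) {
      step <- config$amplitudes[[truth[j]]] * inDrug
      step + stats::rnorm(nF, 0, config$noiseSd)
    }, numeric(nF))
    f <- config$f0 * (1 + dff)
    colnames(f) <- sprintf("cell%03d", seq_len(config$nCells))
    TraceSet(f, frameRate = rate, drugOnset = onset,
             drugOffset = offset, drugName = config$drugName,
             cellData = DataFrame(cell = colnames(f),
                                  truthCategory = truth,
                                  row.names = colnames(f)))
  })
}
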