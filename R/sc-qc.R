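#' Barcode-level QC thresholds
#'
#' Limits for barcode filtering: a barcode is kept when its detected
#' feature count lies in `[minFeatures, maxFeatures]`, its UMI total is
#' at most `maxUMIs`, and its mitochondrial / rRNA / ribosomal-protein
#' expression fractions are at most `maxMito` / `maxRrna` / `maxRibo`.
#' Boundary values are kept: only barcodes strictly outside the limits
#' are discarded.
#'
#' @param minFeatures,maxFeatures detected-gene limits (defaults 300 and
#'   4500).
#' @param maxUMIs UMI-total limit (default 20000).
#' @param maxMito,maxRrna,maxRibo expression-fraction limits (defaults
#'   0.15, 0.10, 0.15).
#' @return A list of class `QCThresholds`.
#' @export
qcThresholds <- function(minFeatures = 300L, maxFeatures = 4500L,
                         maxUMIs = 20000L, maxMito = 0.15,
                         maxRrna = 0.10, maxRibo = 0.15) {
  if (minFeatures >= maxFeatures)
    stop("minFeatures must be below maxFeatures", call. = FALSE)
  fr <- c(maxMito, maxRrna, maxRibo)
  if (any(fr < 0) || any(fr > 1))
    stop("fraction limits must be in [0, 1]", call. = FALSE)
  structure(list(minFeatures = minFeatures, maxFeatures = maxFeatures,
                 maxUMIs = maxUMIs, maxMito = maxMito,
                 maxRrna = maxRrna, maxRibo = maxRibo),
            class = "QCThresholds")
}

#' Per-cell QC metrics from a count matrix
#'
#' Computes, per barcode: detected features, UMI total, and the
#' expression fractions of genes matched by the mitochondrial, rRNA and
#' ribosomal-protein name patterns.
#'
#' @param counts gene x cell count matrix (sparse or dense) with gene
#'   names as rownames.
#' @param mitoPattern,rrnaPattern,riboPattern regular expressions
#'   selecting the housekeeping gene sets by name prefix.
#' @return `DataFrame` with columns `nFeatures`, `nUMIs`, `fracMito`,
#'   `fracRrna`, `fracRibo`.
#' @export
perCellQC <- function(counts, mitoPattern = "^mt:",
                      rrnaPattern = "^rRNA", riboPattern = "^Rp[LS]") {
  if (is.null(rownames(counts)))
    stop("counts must carry gene names as rownames", call. = FALSE)
  tot <- Matrix::colSums(counts)
  fracFor <- function(pattern) {
    sel <- grepl(pattern, rownames(counts))
    if (!any(sel)) return(rep(0, ncol(counts)))
    ifelse(tot > 0, Matrix::colSums(counts[sel, , drop = FALSE]) / tot, 0)
  }
  DataFrame(nFeatures = Matrix::colSums(counts > 0), nUMIs = tot,
            fracMito = fracFor(mitoPattern),
            fracRrna = fracFor(rrnaPattern),
            fracRibo = fracFor(riboPattern),
            row.names = colnames(counts))
}

#' Filter barcodes on QC metrics
#'
#' Applies the barcode-level QC rule: keep a cell iff
#' `minFeatures <= nFeatures <= maxFeatures`, `nUMIs <= maxUMIs`,
#' `fracMito <= maxMito`, `fracRrna <= maxRrna` and
#' `fracRibo <= maxRibo`. The mask depends only on the metrics, so the
#' operation is idempotent and order-independent.
#'
#' @param metrics a `DataFrame`/data.frame of per-cell metrics as
#'   returned by [perCellQC()], or a count matrix (metrics are then
#'   computed with default name patterns).
#' @param thresholds a [qcThresholds()] object.
#' @return Logical vector, `TRUE` for kept cells.
#' @examples
#' m <- S4Vectors::DataFrame(nFeatures = c(250, 1000), nUMIs = c(500, 3000),
#'                           fracMito = 0, fracRrna = 0, fracRibo = 0)
#' filterBarcodes(m)   # first cell discarded: fewer than 300 features
#' @export
filterBarcodes <- function(metrics, thresholds = qcThresholds()) {
  if (is.matrix(metrics) || methods::is(metrics, "Matrix"))
    metrics <- perCellQC(metrics)
  req <- c("nFeatures", "nUMIs", "fracMito", "fracRrna", "fracRibo")
  miss <- setdiff(req, colnames(metrics))
  if (length(miss))
    stop("missing QC metric column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  th <- thresholds
  keep <- metrics$nFeatures >= th$minFeatures &
    metrics$nFeatures <= th$maxFeatures &
    metrics$nUMIs <= th$maxUMIs &
    metrics$fracMito <= th$maxMito &
    metrics$fracRrna <= th$maxRrna &
    metrics$fracRibo <= th$maxRibo
  stats::setNames(as.logical(keep), rownames(metrics))
}

#' Estimate a bimodal expression threshold
#'
#' Kernel density estimate over the non-zero expression values of a
#' gene. When the density has at least two local maxima, the threshold
#' is the abscissa of the minimum-density point between the two highest
#' maxima — the saddle separating the low (leaky/contamination) mode
#' from the high (genuinely expressing) mode. Unimodal distributions
#' yield no threshold.
#'
#' @param values non-zero expression values (normalized/scaled layer).
#' @param minN minimum number of values required (default 50).
#' @param bw bandwidth rule: `"scott"` (default, `stats::bw.nrd`) or
#'   `"silverman"` (`stats::bw.nrd0`), or a numeric bandwidth.
#' @param nGrid density grid size.
#' @return List with `threshold` (numeric or `NA`), `modality`
#'   (`"bimodal"` or `"unimodal"`) and the `density` object.
#' @examples
#' set.seed(1)
#' v <- c(rnorm(500, 1, 0.3), rnorm(500, 4, 0.3))
#' estimateBimodalThreshold(v)$threshold   # near 2.5
#' @export
estimateBimodalThreshold <- function(values, minN = 50L, bw = "scott",
                                     nGrid = 512L) {
  values <- values[is.finite(values)]
  if (length(values) < minN)
    stop("insufficient data: need at least ", minN,
         " non-zero values, got ", length(values), call. = FALSE)
  bwVal <- if (is.numeric(bw)) bw
           else switch(match.arg(bw, c("scott", "silverman")),
                       scott = stats::bw.nrd(values),
                       silverman = stats::bw.nrd0(values))
  d <- stats::density(values, bw = bwVal, n = nGrid)
  y <- d$y
  n <- length(y)
  isMax <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
               y[2:(n - 1)] >= y[3:n], FALSE)
  peaks <- which(isMax)
  if (length(peaks) < 2L)
    return(list(threshold = NA_real_, modality = "unimodal", density = d))
  top2 <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  between <- lo:hi
  cut <- between[which.min(y[between])]
  list(threshold = d$x[cut], modality = "bimodal", density = d)
}

#' Default marker thresholds for co-expression doublet calling
#'
#' Thresholds on the normalized/scaled layer above which a class marker
#' is considered highly expressed. The defaults (glial `nrv2` 3,
#' cholinergic `VAChT` 1.5, glutamatergic `VGlut` 2.1, GABAergic
#' `Gad1` 2.3) are reference values estimated from the bimodal
#' non-zero expression distributions of a whole-brain atlas dataset;
#' on synthetic or new data they should be
#' re-estimated with [estimateBimodalThreshold()].
#'
#' @param thresholds named numeric vector, marker gene -> threshold.
#' @return Named numeric vector of class `MarkerThresholds`.
#' @export
markerThresholds <- function(thresholds = c(nrv2 = 3, VAChT = 1.5,
                                            VGlut = 2.1, Gad1 = 2.3)) {
  if (is.null(names(thresholds)) || any(!nzchar(names(thresholds))))
    stop("thresholds must be a named vector", call. = FALSE)
  if (any(thresholds < 0))
    stop("thresholds must be non-negative", call. = FALSE)
  structure(thresholds, class = c("MarkerThresholds", "numeric"))
}

#' Default Kenyon-cell subtype marker thresholds
#'
#' Subtype markers for mushroom-body Kenyon cells: `Ca-alpha1T`
#' (alpha/beta), `ab` (gamma), `CG8641` (alpha'/beta'), with reference
#' scaled-expression thresholds 1.5, 1.5 and 2.2.
#'
#' @param thresholds named numeric vector, marker gene -> threshold.
#' @return Named numeric vector of class `MarkerThresholds`.
#' @export
kcMarkerThresholds <- function(thresholds = c(`Ca-alpha1T` = 1.5,
                                              ab = 1.5, CG8641 = 2.2)) {
  markerThresholds(thresholds)
}

#' Flag doublets by marker co-expression
#'
#' A barcode is flagged a class doublet when strictly more than one of
#' the mutually exclusive class markers exceeds (strictly) its
#' threshold on the scaled layer. Within cells designated as Kenyon
#' cells, a second pass flags barcodes where more than one Kenyon
#' subtype marker exceeds its threshold. Reason codes record which
#' markers fired.
#'
#' @param scaled genes x cells matrix of normalized/scaled expression
#'   with gene names as rownames.
#' @param thresholds class-marker thresholds ([markerThresholds()]).
#' @param kcCells optional logical/index vector of Kenyon-designated
#'   cells for the subtype pass.
#' @param kcThresholds Kenyon subtype thresholds
#'   ([kcMarkerThresholds()]).
#' @return `DataFrame` with logical `isDoublet` and character `reason`
#'   (comma-joined fired markers, `NA` for singlets).
#' @examples
#' m <- rbind(nrv2 = c(3.2, 0), VAChT = c(0, 0), VGlut = c(2.5, 0),
#'            Gad1 = c(0, 0))
#' colnames(m) <- c("a", "b")
#' flagCoexpressionDoublets(m)$isDoublet   # TRUE, FALSE
#' @export
flagCoexpressionDoublets <- function(scaled,
                                     thresholds = markerThresholds(),
                                     kcCells = NULL,
                                     kcThresholds = kcMarkerThresholds()) {
  checkMarkers <- function(th) {
    miss <- setdiff(names(th), rownames(scaled))
    if (length(miss))
      stop("marker gene(s) absent from matrix: ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  checkMarkers(thresholds)
  nC <- ncol(scaled)
  fired <- scaled[names(thresholds), , drop = FALSE] >
    as.numeric(thresholds)
  nFired <- colSums(fired)
  isDoublet <- nFired >= 2L
  reason <- rep(NA_character_, nC)
  if (any(isDoublet)) {
    reason[isDoublet] <- vapply(which(isDoublet), function(j) {
      paste0("class-doublet:",
             paste(names(thresholds)[fired[, j]], collapse = ","))
    }, character(1))
  }
  if (!is.null(kcCells) && length(kcCells)) {
    checkMarkers(kcThresholds)
    kcIdx <- if (is.logical(kcCells)) which(kcCells) else as.integer(kcCells)
    kf <- scaled[names(kcThresholds), kcIdx, drop = FALSE] >
      as.numeric(kcThresholds)
    kcDoub <- colSums(kf) > 1L
    for (k in which(kcDoub)) {
      j <- kcIdx[k]
      tag <- paste0("KC-doublet:",
                    paste(names(kcThresholds)[kf[, k]], collapse = ","))
      reason[j] <- if (is.na(reason[j])) tag else paste(reason[j], tag,
                                                       sep = ";")
      isDoublet[j] <- TRUE
    }
  }
  DataFrame(isDoublet = unname(isDoublet), reason = reason,
            row.names = colnames(scaled))
}

#' Merge co-expression and external doublet calls
#'
#' Final doublet set is the union of the marker co-expression calls and
#' an optional external per-cell call set (e.g. a simulation-based
#' doublet scorer run upstream).
#'
#' @param coexpr logical vector of co-expression doublet calls.
#' @param external optional logical vector of external calls, same
#'   length and order.
#' @return List with `mask` (the union) and `summary` (counts per
#'   method, overlap, final count, fraction of all cells removed).
#' @export
mergeDoubletCalls <- function(coexpr, external = NULL) {
  coexpr <- as.logical(coexpr)
  if (is.null(external)) {
    final <- coexpr
    nExt <- 0L; nOv <- 0L
  } else {
    external <- as.logical(external)
    if (length(external) != length(coexpr))
      stop("coexpression and external call vectors differ in length",
           call. = FALSE)
    final <- coexpr | external
    nExt <- sum(external); nOv <- sum(coexpr & external)
  }
  list(mask = final,
       summary = list(nCoexpression = sum(coexpr), nExternal = nExt,
                      nOverlap = nOv, nFinal = sum(final),
                      fracRemoved = sum(final) / length(final)))
}
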