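#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

# ---------------------------------------------------------------------------
# TraceSet: fluorescence time series with a drug-application window
# ---------------------------------------------------------------------------

#' TraceSet: fluorescence traces with a drug window
#'
#' Container for raw fluorescence time series acquired at a fixed frame
#' rate, annotated with a single drug-application window. Columns are
#' cells (regions of interest), rows are frames. Per-cell annotations
#' (state, planted truth category, ...) live in `cellData`.
#'
#' @slot traces numeric matrix, frames x cells, raw fluorescence (a.u.).
#' @slot frameRate acquisition rate in Hz.
#' @slot drugOnset,drugOffset drug window boundaries in seconds from the
#'   start of the recording. The onset must leave room for a 14 s
#'   baseline window.
#' @slot drugName name of the applied compound.
#' @slot cellData a [S4Vectors::DataFrame] with one row per cell.
#'
#' @export
setClass("TraceSet", slots = c(
  traces = "matrix",
  frameRate = "numeric",
  drugOnset = "numeric",
  drugOffset = "numeric",
  drugName = "character",
  cellData = "DataFrame"
))

setValidity("TraceSet", function(object) {
  msg <- character()
  if (!is.numeric(object@traces) || !all(is.finite(object@traces)))
    msg <- c(msg, "traces must be a finite numeric matrix")
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  if (object@drugOffset <= object@drugOnset)
    msg <- c(msg, "drugOffset must exceed drugOnset")
  if (object@drugOnset < 14)
    msg <- c(msg, "drugOnset must be >= 14 s so a baseline window fits")
  if (nrow(object@cellData) != ncol(object@traces))
    msg <- c(msg, "cellData must have one row per trace column")
  if (length(msg)) msg else TRUE
})

#' Construct a TraceSet
#'
#' @param traces frames x cells matrix of raw fluorescence.
#' @param frameRate frames per second (default 5.92 Hz).
#' @param drugOnset,drugOffset drug window in seconds.
#' @param drugName compound label.
#' @param cellData optional per-cell `DataFrame`.
#' @return A [TraceSet-class] object.
#' @examples
#' f <- matrix(100, nrow = 400, ncol = 3)
#' ts <- TraceSet(f, drugOnset = 30, drugOffset = 55)
#' nCells(ts)
#' @export
TraceSet <- function(traces, frameRate = 5.92, drugOnset, drugOffset,
                     drugName = NA_character_, cellData = NULL) {
  traces <- as.matrix(traces)
  if (is.null(cellData)) {
    ids <- colnames(traces)
    if (is.null(ids)) ids <- sprintf("cell%03d", seq_len(ncol(traces)))
    cellData <- DataFrame(cell = ids)
  }
  new("TraceSet", traces = traces, frameRate = frameRate,
      drugOnset = drugOnset, drugOffset = drugOffset,
      drugName = as.character(drugName), cellData = cellData)
}

#' @describeIn TraceSet number of cells (trace columns)
#' @param x a `TraceSet`
#' @export
nCells <- function(x) ncol(x@traces)

#' @describeIn TraceSet number of frames per trace
#' @export
nFrames <- function(x) nrow(x@traces)

#' @describeIn TraceSet the raw trace matrix (frames x cells)
#' @export
traces <- function(x) x@traces

#' @describeIn TraceSet acquisition frame rate (Hz)
#' @export
frameRate <- function(x) x@frameRate

#' @describeIn TraceSet drug window, c(onset, offset) in seconds
#' @export
drugWindow <- function(x) c(onset = x@drugOnset, offset = x@drugOffset)

#' @describeIn TraceSet per-cell annotation DataFrame
#' @export
cellData <- function(x) x@cellData

setMethod("show", "TraceSet", function(object) {
  cat("TraceSet:", ncol(object@traces), "cells x",
      nrow(object@traces), "frames @", object@frameRate, "Hz\n")
  cat("  drug:", object@drugName, sprintf("[%g, %g] s\n",
      object@drugOnset, object@drugOffset))
  cat("  cellData columns:",
      paste(colnames(object@cellData), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# Skeleton: astrocyte process skeleton (SWC-like node table)
# ---------------------------------------------------------------------------

#' Skeleton: an astrocyte process skeleton
#'
#' Node table of a skeletonised astrocyte: node id, parent id (-1 for a
#' root), coordinates and local process radius, all in nanometres.
#'
#' @slot nodes data.frame with columns id, parent, x, y, z, radius.
#' @slot astrocyteId identifier of the source cell.
#' @export
setClass("Skeleton", slots = c(nodes = "data.frame",
                               astrocyteId = "character"))

setValidity("Skeleton", function(object) {
  nd <- object@nodes
  req <- c("id", "parent", "x", "y", "z", "radius")
  if (!all(req %in% colnames(nd)))
    return(paste("nodes must have columns:", paste(req, collapse = ", ")))
  msg <- character()
  if (nrow(nd) == 0L) msg <- c(msg, "skeleton has no nodes")
  if (any(!is.finite(as.matrix(nd[, c("x", "y", "z")]))))
    msg <- c(msg, "coordinates must be finite")
  if (any(nd$radius <= 0)) msg <- c(msg, "radii must be > 0")
  bad <- !(nd$parent %in% c(-1L, nd$id))
  if (any(bad)) msg <- c(msg, "parent ids must be -1 or valid node ids")
  if (anyDuplicated(nd$id)) msg <- c(msg, "node ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a Skeleton
#' @param nodes data.frame with id, parent, x, y, z, radius (nm).
#' @param astrocyteId source cell identifier.
#' @return A [Skeleton-class] object.
#' @export
Skeleton <- function(nodes, astrocyteId = "astro1") {
  new("Skeleton", nodes = as.data.frame(nodes),
      astrocyteId = as.character(astrocyteId))
}

#' @describeIn Skeleton the node table
#' @param x a `Skeleton`
#' @export
skeletonNodes <- function(x) x@nodes

#' @describeIn Skeleton the astrocyte identifier
#' @export
astrocyteId <- function(x) x@astrocyteId

setMethod("show", "Skeleton", function(object) {
  nd <- object@nodes
  cat("Skeleton", object@astrocyteId, ":", nrow(nd), "nodes, radius",
      sprintf("[%.0f, %.0f] nm\n", min(nd$radius), max(nd$radius)))
})

# ---------------------------------------------------------------------------
# SynapseTable: automatically detected synapses with quality scores
# ---------------------------------------------------------------------------

#' SynapseTable: detected synapses with scores and partners
#'
#' One row per synapse: presynaptic neuron id, postsynaptic partner ids
#' (a single `;`-separated string, which may include astrocyte ids),
#' cleft coordinates in nanometres, detection quality scores and the
#' predicted presynaptic transmitter.
#'
#' @slot data a [S4Vectors::DataFrame] with columns preId, postIds,
#'   x, y, z, cleftScore, connectionScore, transmitter.
#' @export
setClass("SynapseTable", slots = c(data = "DataFrame"))

setValidity("SynapseTable", function(object) {
  d <- object@data
  req <- c("preId", "postIds", "x", "y", "z", "cleftScore",
           "connectionScore", "transmitter")
  if (!all(req %in% colnames(d)))
    return(paste("missing columns:", paste(setdiff(req, colnames(d)),
                                           collapse = ", ")))
  msg <- character()
  if (any(!is.finite(as.matrix(as.data.frame(d[, c("x", "y", "z")])))))
    msg <- c(msg, "coordinates must be finite")
  sc <- c(d$cleftScore, d$connectionScore)
  if (any(sc[!is.na(sc)] < 0)) msg <- c(msg, "scores must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SynapseTable
#' @param data data.frame or DataFrame of synapse records.
#' @return A [SynapseTable-class] object.
#' @export
SynapseTable <- function(data) {
  new("SynapseTable", data = DataFrame(data))
}

#' @describeIn SynapseTable the underlying record table
#' @param x a `SynapseTable`
#' @export
synapseData <- function(x) x@data

#' @describeIn SynapseTable number of synapse records
#' @export
nSynapses <- function(x) nrow(x@data)

#' Subset a SynapseTable by row
#' @param x a `SynapseTable`
#' @param i row index
#' @param j,drop ignored
#' @param ... ignored
#' @export
setMethod("[", "SynapseTable", function(x, i, j, ..., drop = FALSE) {
  SynapseTable(x@data[i, , drop = FALSE])
})

setMethod("show", "SynapseTable", function(object) {
  d <- object@data
  cat("SynapseTable:", nrow(d), "synapses\n")
  if (nrow(d)) {
    tab <- table(d$transmitter)
    cat("  transmitters:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})
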