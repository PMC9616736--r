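# Readers and writers for the plain-text interchange formats: Matrix
# Market counts with gene/barcode label files, SWC skeletons, and CSV
# trace / synapse tables.

#' Write a count matrix as Matrix Market plus label files
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and, when cell
#' metadata is present, `cells.csv` into `dir`.
#'
#' @param sce a `SingleCellExperiment` (assay `counts`) or a sparse
#'   gene x cell matrix.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
writeCountsMM <- function(sce, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (methods::is(sce, "SingleCellExperiment")) {
    counts <- SummarizedExperiment::assay(sce, "counts")
    cells <- as.data.frame(SummarizedExperiment::colData(sce))
  } else {
    counts <- sce
    cells <- NULL
  }
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"), paths[1])
  writeLines(rownames(counts), paths[2])
  writeLines(colnames(counts), paths[3])
  if (!is.null(cells)) {
    p <- file.path(dir, "cells.csv")
    utils::write.csv(cells, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a Matrix Market count matrix with label files
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv` and optionally `cells.csv`.
#' @return A `SingleCellExperiment` with the `counts` assay (and cell
#'   metadata when present).
#' @export
readCountsMM <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  cellsPath <- file.path(dir, "cells.csv")
  cd <- if (file.exists(cellsPath))
    DataFrame(utils::read.csv(cellsPath), row.names = colnames(counts))
  else DataFrame(row.names = colnames(counts))
  SingleCellExperiment(assays = list(counts = counts), colData = cd)
}

#' Write a skeleton in SWC format
#'
#' Standard 7-column SWC (`id type x y z radius parent`), coordinates
#' and radii in nm, type 0, parent -1 for roots.
#'
#' @param skeleton a [Skeleton-class].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeSWC <- function(skeleton, path) {
  nd <- skeletonNodes(skeleton)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# SWC astrocyte skeleton %s (units nm)",
                     astrocyteId(skeleton)), con)
  writeLines(sprintf("%d 0 %.3f %.3f %.3f %.3f %d", nd$id, nd$x, nd$y,
                     nd$z, nd$radius, nd$parent), con)
  invisible(path)
}

#' Read an SWC skeleton
#'
#' @param path SWC file (7 columns, `#` comments).
#' @param astrocyteId id to attach to the skeleton.
#' @return A [Skeleton-class].
#' @export
readSWC <- function(path, astrocyteId = "astro1") {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  Skeleton(tab[, c("id", "parent", "x", "y", "z", "radius")],
           astrocyteId = astrocyteId)
}

#' Write traces as a long-format CSV
#'
#' Columns: `cell`, `frame` (1-based), `F` (raw fluorescence).
#'
#' @param ts a [TraceSet-class].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeTracesCSV <- function(ts, path) {
  m <- traces(ts)
  long <- data.frame(cell = rep(colnames(m), each = nrow(m)),
                     frame = rep(seq_len(nrow(m)), ncol(m)),
                     F = as.vector(m))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format trace CSV into a TraceSet
#'
#' @param path CSV with columns `cell`, `frame`, `F`.
#' @param frameRate,drugOnset,drugOffset,drugName acquisition metadata
#'   (not stored in the CSV).
#' @return A [TraceSet-class].
#' @export
readTracesCSV <- function(path, frameRate = 5.92, drugOnset,
                          drugOffset, drugName = NA_character_) {
  long <- utils::read.csv(path)
  cells <- unique(long$cell)
  m <- vapply(cells, function(cl) {
    sub <- long[long$cell == cl, ]
    sub$F[order(sub$frame)]
  }, numeric(sum(long$cell == cells[1])))
  colnames(m) <- cells
  TraceSet(m, frameRate = frameRate, drugOnset = drugOnset,
           drugOffset = drugOffset, drugName = drugName)
}

#' Write a synapse table as CSV
#' @param synapses a [SynapseTable-class].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeSynapsesCSV <- function(synapses, path) {
  utils::write.csv(as.data.frame(synapseData(synapses)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a synapse table from CSV
#' @param path CSV with the [SynapseTable-class] columns.
#' @return A [SynapseTable-class].
#' @export
readSynapsesCSV <- function(path) {
  SynapseTable(utils::read.csv(path, stringsAsFactors = FALSE))
}
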