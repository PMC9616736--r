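# End-to-end pipeline runner: simulate -> qc -> fuse -> de and
# simulate -> calcium / vicinity, with a reproducibility manifest.

pipelineStages <- c("simulate", "qc", "fuse", "de", "calcium",
                    "vicinity")

validatePipelineConfig <- function(config) {
  if (!is.list(config))
    stop("pipeline config must be a list (or YAML file path)",
         call. = FALSE)
  bad <- character()
  if (is.null(config$seed)) bad <- c(bad, "seed")
  if (is.null(config$stages)) bad <- c(bad, "stages")
  if (length(bad))
    stop("pipeline config is missing required key(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  unknown <- setdiff(config$stages, pipelineStages)
  if (length(unknown))
    stop("unknown pipeline stage(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  invisible(config)
}

#' Run the staged analysis pipeline
#'
#' Executes the requested stages in their declared order, writing each
#' stage's outputs under `outDir` and recording everything in a
#' manifest (`manifest.json`): config hash, seed, stages, output files
#' with record counts, and package version. A single global seed fans
#' out deterministically into per-stage seeds, so identical configs
#' reproduce identical outputs and individual stages can be re-run
#' independently.
#'
#' Stage semantics: `simulate` generates counts / traces / anatomy
#' (sections `simulate$counts`, `simulate$traces`,
#' `simulate$anatomy`, each a list of arguments for the corresponding
#' configuration constructor; present sections are run); `qc` filters
#' barcodes and flags co-expression doublets using the generator's
#' derived marker thresholds; `fuse` assigns clusters (truth classes
#' as the initial clustering) and fuses indistinct ones on a PCA-like
#' embedding of the scaled layer; `de` runs the zero-inflation
#' weighted test between the two conditions; `calcium` classifies
#' trace responses; `vicinity` computes the distance profile and the
#' bootstrap comparison of the two most abundant transmitters.
#'
#' @param config a nested list, or the path of a YAML file holding
#'   one. Required keys: `seed`, `stages` (subset of
#'   simulate / qc / fuse / de / calcium / vicinity).
#' @param outDir output directory, created if missing.
#' @return The manifest, invisibly also written as
#'   `<outDir>/manifest.json`.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  validatePipelineConfig(config)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  seed <- as.integer(config$seed)
  files <- data.frame(path = character(), stage = character(),
                      nRecords = integer(), stringsAsFactors = FALSE)
  addFile <- function(path, stage, n) {
    files[nrow(files) + 1L, ] <<- list(path, stage, as.integer(n))
  }
  state <- new.env(parent = emptyenv())

  runStage <- function(stage, idx) {
    stageSeed <- deriveSeed(seed, idx)
    switch(stage,
      simulate = {
        sim <- config$simulate
        if (!is.null(sim$counts)) {
          cfg <- do.call(simCountsConfig,
                         c(sim$counts, list(seed = stageSeed)))
          state$sce <- simulateCounts(cfg)
          dir <- file.path(outDir, "counts")
          for (p in writeCountsMM(state$sce, dir))
            addFile(p, stage, ncol(state$sce))
          truth <- metadata(state$sce)$groundTruth
          p <- file.path(outDir, "counts_truth.json")
          jsonlite::write_json(
            list(markerThresholds = as.list(truth$markerThresholds),
                 nDoublets = truth$nDoublets,
                 classNames = truth$classNames),
            p, auto_unbox = TRUE, digits = NA)
          addFile(p, stage, ncol(state$sce))
        }
        if (!is.null(sim$traces)) {
          cfg <- do.call(simTracesConfig,
                         c(sim$traces, list(seed = stageSeed)))
          state$ts <- simulateTraces(cfg)
          p <- file.path(outDir, "traces.csv")
          writeTracesCSV(state$ts, p)
          addFile(p, stage, nCells(state$ts))
        }
        if (!is.null(sim$anatomy)) {
          cfg <- do.call(simAnatomyConfig,
                         c(sim$anatomy, list(seed = stageSeed)))
          state$anatomy <- simulateAnatomy(cfg)
          p1 <- file.path(outDir, "skeleton.swc")
          writeSWC(state$anatomy$skeleton, p1)
          addFile(p1, stage,
                  nrow(skeletonNodes(state$anatomy$skeleton)))
          p2 <- file.path(outDir, "synapses.csv")
          writeSynapsesCSV(state$anatomy$synapses, p2)
          addFile(p2, stage, nSynapses(state$anatomy$synapses))
        }
      },
      qc = {
        if (is.null(state$sce))
          stop("qc stage requires simulated counts", call. = FALSE)
        sce <- state$sce
        keep <- filterBarcodes(
          perCellQC(SummarizedExperiment::assay(sce, "counts")),
          do.call(qcThresholds, config$qc$thresholds %||% list()))
        thr <- metadata(sce)$groundTruth$markerThresholds
        doub <- flagCoexpressionDoublets(
          SummarizedExperiment::assay(sce, "scaled"),
          markerThresholds(thr))
        merged <- mergeDoubletCalls(doub$isDoublet)
        res <- data.frame(barcode = colnames(sce), keepQC = keep,
                          isDoublet = merged$mask,
                          reason = doub$reason)
        p <- file.path(outDir, "qc.csv")
        utils::write.csv(res, p, row.names = FALSE)
        addFile(p, stage, nrow(res))
        state$qc <- res
        state$kept <- keep & !merged$mask
      },
      fuse = {
        if (is.null(state$sce))
          stop("fuse stage requires simulated counts", call. = FALSE)
        sel <- if (!is.null(state$kept)) state$kept
               else rep(TRUE, ncol(state$sce))
        sce <- state$sce[, sel]
        scaled <- SummarizedExperiment::assay(sce, "scaled")
        emb <- stats::prcomp(t(scaled), rank. = 10)$x
        labels <- SummarizedExperiment::colData(sce)$trueClass
        fused <- fuseClusters(
          SummarizedExperiment::assay(sce, "logcounts"), emb, labels,
          do.call(fusionConfig, config$fuse %||% list()))
        p <- file.path(outDir, "fused_labels.csv")
        utils::write.csv(data.frame(barcode = colnames(sce),
                                    cluster = fused$labels), p,
                         row.names = FALSE)
        addFile(p, stage, ncol(sce))
        p2 <- file.path(outDir, "fusion_log.csv")
        utils::write.csv(fused$log, p2, row.names = FALSE)
        addFile(p2, stage, nrow(fused$log))
        state$clusters <- stats::setNames(fused$labels, colnames(sce))
      },
      de = {
        if (is.null(state$sce))
          stop("de stage requires simulated counts", call. = FALSE)
        sel <- if (!is.null(state$kept)) state$kept
               else rep(TRUE, ncol(state$sce))
        sce <- state$sce[, sel]
        cl <- if (!is.null(state$clusters))
          state$clusters[colnames(sce)]
        else SummarizedExperiment::colData(sce)$trueClass
        condLevels <-
          metadata(state$sce)$groundTruth$config$conditions
        res <- runDifferentialExpression(
          SummarizedExperiment::assay(sce, "counts"),
          factor(SummarizedExperiment::colData(sce)$condition,
                 condLevels), clusters = cl)
        p <- file.path(outDir, "de_results.csv")
        utils::write.csv(res, p, row.names = FALSE)
        addFile(p, stage, nrow(res))
        summ <- summarizeDe(res)
        p2 <- file.path(outDir, "de_events.csv")
        utils::write.csv(summ$events, p2, row.names = FALSE)
        addFile(p2, stage, nrow(summ$events))
        state$de <- res
      },
      calcium = {
        if (is.null(state$ts))
          stop("calcium stage requires simulated traces", call. = FALSE)
        calls <- classifyResponses(state$ts)
        auc <- traceAuc(state$ts, "during")
        res <- data.frame(cell = rownames(calls),
                          category = as.character(calls$category),
                          muPost = calls$muPost,
                          sigmaPre = calls$sigmaPre, aucDuring = auc)
        p <- file.path(outDir, "response_calls.csv")
        utils::write.csv(res, p, row.names = FALSE)
        addFile(p, stage, nrow(res))
        state$calls <- res
      },
      vicinity = {
        if (is.null(state$anatomy))
          stop("vicinity stage requires simulated anatomy",
               call. = FALSE)
        syn <- filterSynapses(state$anatomy$synapses)
        prof <- vicinityProfile(state$anatomy$skeleton, syn)
        long <- data.frame(
          transmitter = rep(names(prof$distances),
                            lengths(prof$distances)),
          distance = unlist(prof$distances, use.names = FALSE))
        p <- file.path(outDir, "vicinity_profile.csv")
        utils::write.csv(long, p, row.names = FALSE)
        addFile(p, stage, nrow(long))
        txs <- names(sort(lengths(prof$distances),
                          decreasing = TRUE))[1:2]
        test <- bootstrapMeanTest(prof$distances[[txs[1]]],
                                  prof$distances[[txs[2]]],
                                  seed = stageSeed)
        tps <- classifyTps(syn,
                           astrocyteId(state$anatomy$skeleton))
        summary <- list(comparison = txs,
                        meanDiff = test$meanDiff,
                        p.boot = test$p.boot, p.raw = test$p.raw,
                        nTps = sum(tps))
        p2 <- file.path(outDir, "vicinity_test.json")
        jsonlite::write_json(summary, p2, auto_unbox = TRUE,
                             digits = NA)
        addFile(p2, stage, length(prof$candidates))
      },
      stop("unknown stage: ", stage, call. = FALSE))
  }

  for (i in seq_along(config$stages)) {
    stage <- config$stages[[i]]
    tryCatch(runStage(stage, i), error = function(e) {
      stop("pipeline failed at stage '", stage, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }

  manifest <- list(configHash = hashObject(config), seed = seed,
                   stages = as.character(config$stages), files = files,
                   version = as.character(
                     utils::packageVersion("thirstState")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
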