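#' @importFrom Matrix Diagonal Matrix
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment assay assays colData rowData
NULL

#' Configuration for the synthetic UMI count generator
#'
#' Builds a validated configuration for [simulateCounts()]. Counts are
#' drawn from a per-gene zero-inflated negative binomial
#' ZINB(mu, theta, pi): a zero with probability `pi`, otherwise
#' NB(mu, theta). Cells belong to major classes, each with exclusive
#' marker genes expressed at a high mode (`markerMu`) only within the
#' class; doublets are sums of two singlets of different classes. A
#' condition effect multiplies `mu` by `2^log2FC` for genes listed in
#' `deSpec`, and a configurable number of cells is planted as clear QC
#' violators for testing barcode filters.
#'
#' @param seed integer seed; identical configurations give identical output.
#' @param nGenes,nCells problem size.
#' @param classes list of `list(name=, fraction=, markers=)`; fractions
#'   must sum to at most 1 (any remainder becomes unmarked "other" cells).
#' @param doubletRate fraction of cells that are synthetic doublets,
#'   in `[0, 1)`.
#' @param muMeanLog,muSdLog log-normal parameters for baseline gene means.
#' @param theta,pi NB dispersion and zero-inflation probability for
#'   baseline genes (scalar or per-gene vector of length `nGenes`).
#' @param markerMu,markerTheta,markerPi ZINB parameters of marker genes
#'   within their own class (background expression is exactly zero, the
#'   mutual-exclusivity assumption behind co-expression doublet calling).
#' @param conditions two condition labels; `conditionFractions` their
#'   cell shares.
#' @param conditionFractions numeric length 2 summing to 1.
#' @param deSpec data.frame with columns `gene`, `log2FC`: true fold
#'   changes of condition 2 relative to condition 1.
#' @param qcViolators named integer vector with any of
#'   `low_features`, `high_umi`, `high_mito`, `high_rrna`, `high_ribo`:
#'   how many cells to plant as violators of each QC rule.
#' @param mitoFrac,rrnaFrac,riboFrac expected baseline share of total
#'   expression from mitochondrial / rRNA / ribosomal-protein genes
#'   (safely inside the QC limits of 0.15 / 0.10 / 0.15).
#' @return A list of class `SimCountsConfig`.
#' @export
simCountsConfig <- function(seed = 1L, nGenes = 2000L, nCells = 1000L,
                            classes = NULL, doubletRate = 0.05,
                            muMeanLog = log(1.5), muSdLog = 0.5,
                            theta = 2, pi = 0.1,
                            markerMu = 100, markerTheta = 5, markerPi = 0,
                            conditions = c("sated", "dehydrated12h"),
                            conditionFractions = c(0.5, 0.5),
                            deSpec = NULL,
                            qcViolators = c(low_features = 0L, high_umi = 0L,
                                            high_mito = 0L, high_rrna = 0L,
                                            high_ribo = 0L),
                            mitoFrac = 0.05, rrnaFrac = 0.03,
                            riboFrac = 0.07) {
  if (is.null(classes)) {
    classes <- list(
      list(name = "glia",          fraction = 0.25, markers = "nrv2"),
      list(name = "cholinergic",   fraction = 0.25, markers = "VAChT"),
      list(name = "glutamatergic", fraction = 0.25, markers = "VGlut"),
      list(name = "GABAergic",     fraction = 0.25, markers = "Gad1"))
  }
  fr <- vapply(classes, `[[`, numeric(1), "fraction")
  if (any(fr < 0) || sum(fr) > 1 + 1e-9)
    stop("class fractions must be non-negative and sum to at most 1",
         call. = FALSE)
  if (doubletRate < 0 || doubletRate >= 1)
    stop("doubletRate must be in [0, 1)", call. = FALSE)
  if (any(pi < 0) || any(pi >= 1) || any(theta <= 0) ||
      markerPi < 0 || markerPi >= 1 || markerTheta <= 0)
    stop("ZINB parameters out of range: need theta > 0 and pi in [0, 1)",
         call. = FALSE)
  if (abs(sum(conditionFractions) - 1) > 1e-9 ||
      length(conditions) != 2L)
    stop("need exactly two conditions with fractions summing to 1",
         call. = FALSE)
  full <- c(low_features = 0L, high_umi = 0L, high_mito = 0L,
            high_rrna = 0L, high_ribo = 0L)
  full[names(qcViolators)] <- as.integer(qcViolators)
  if (any(full < 0)) stop("qcViolators must be non-negative", call. = FALSE)
  if (!is.null(deSpec) &&
      !all(c("gene", "log2FC") %in% colnames(deSpec)))
    stop("deSpec needs columns gene, log2FC", call. = FALSE)
  structure(list(seed = as.integer(seed), nGenes = as.integer(nGenes),
                 nCells = as.integer(nCells), classes = classes,
                 doubletRate = doubletRate, muMeanLog = muMeanLog,
                 muSdLog = muSdLog, theta = theta, pi = pi,
                 markerMu = markerMu, markerTheta = markerTheta,
                 markerPi = markerPi, conditions = conditions,
                 conditionFractions = conditionFractions,
                 deSpec = deSpec, qcViolators = full,
                 mitoFrac = mitoFrac, rrnaFrac = rrnaFrac,
                 riboFrac = riboFrac),
            class = "SimCountsConfig")
}

# draw a block of ZINB counts: genes x cells given a dense mu matrix and
# per-gene theta / pi vectors
rzinbMatrix <- function(muMat, theta, pi) {
  nG <- nrow(muMat); nC <- ncol(muMat)
  y <- matrix(stats::rnbinom(nG * nC, size = theta, mu = as.vector(muMat)),
              nrow = nG)
  drop <- matrix(stats::rbinom(nG * nC, 1L, pi) == 1L, nrow = nG)
  y[drop] <- 0L
  y
}

#' Simulate a gene x cell UMI count matrix with planted ground truth
#'
#' Generates a sparse ZINB count matrix with class-specific marker
#' expression, synthetic doublets (sums of two singlets of different
#' classes), an optional planted condition effect, and optional planted
#' QC-rule violators. Also computes a log-normalized layer
#' (`log1p(count / libsize * 1e4)`) and a per-gene z-scaled layer, and
#' derives marker thresholds that exactly separate the marker-expressing
#' mode from the zero background on the scaled layer.
#'
#' @param config a [simCountsConfig()] object.
#' @return A [SingleCellExperiment::SingleCellExperiment] with assays
#'   `counts` (sparse), `logcounts` (sparse) and `scaled` (dense);
#'   per-cell truth in `colData` (`trueClass`, `isDoublet`,
#'   `qcViolation`, `condition`, `replicate`, `sex`); per-gene truth in
#'   `rowData` (`geneGroup`, `mu`, `theta`, `pi`, `log2FC`); and
#'   `metadata(sce)$groundTruth` holding the config, marker thresholds
#'   and doublet parent classes.
#' @examples
#' sce <- simulateCounts(simCountsConfig(nGenes = 300, nCells = 100))
#' table(colData(sce)$trueClass)
#' @export
simulateCounts <- function(config = simCountsConfig()) {
  stopifnot(inherits(config, "SimCountsConfig"))
  withSeed(config$seed, {
    nG <- config$nGenes; nC <- config$nCells
    classes <- config$classes
    markerGenes <- unlist(lapply(classes, `[[`, "markers"))
    if (anyDuplicated(markerGenes))
      stop("marker genes must be unique across classes", call. = FALSE)

    # gene table: special housekeeping groups first, markers, background
    nMito <- 20L; nRrna <- 10L; nRibo <- 30L
    if (nG < nMito + nRrna + nRibo + length(markerGenes) + 10L)
      stop("nGenes too small for the gene groups", call. = FALSE)
    geneGroup <- rep("background", nG)
    geneGroup[seq_len(nMito)] <- "mito"
    geneGroup[nMito + seq_len(nRrna)] <- "rrna"
    geneGroup[nMito + nRrna + seq_len(nRibo)] <- "ribo"
    markerIdx <- nMito + nRrna + nRibo + seq_along(markerGenes)
    geneGroup[markerIdx] <- "marker"
    geneNames <- sprintf("gene%04d", seq_len(nG))
    geneNames[geneGroup == "mito"] <- sprintf("mt:gene%03d", seq_len(nMito))
    geneNames[geneGroup == "rrna"] <- sprintf("rRNA:gene%03d",
                                              seq_len(nRrna))
    geneNames[geneGroup == "ribo"] <- sprintf("RpL%03d", seq_len(nRibo))
    geneNames[markerIdx] <- markerGenes

    mu <- stats::rlnorm(nG, config$muMeanLog, config$muSdLog)
    mu[geneGroup == "marker"] <- 0
    # rescale housekeeping groups to their target share of total expression
    bgSum <- sum(mu[geneGroup == "background"])
    restFrac <- 1 - config$mitoFrac - config$rrnaFrac - config$riboFrac
    total <- bgSum / restFrac
    scaleGroup <- function(mu, grp, frac) {
      sel <- geneGroup == grp
      mu[sel] <- mu[sel] * (frac * total / sum(mu[sel]))
      mu
    }
    mu <- scaleGroup(mu, "mito", config$mitoFrac)
    mu <- scaleGroup(mu, "rrna", config$rrnaFrac)
    mu <- scaleGroup(mu, "ribo", config$riboFrac)

    theta <- rep_len(config$theta, nG)
    pi <- rep_len(config$pi, nG)
    theta[markerIdx] <- config$markerTheta
    pi[markerIdx] <- config$markerPi

    # cell bookkeeping: deterministic class counts, then doublets
    nDoub <- round(config$doubletRate * nC)
    nSing <- nC - nDoub
    fr <- vapply(classes, `[[`, numeric(1), "fraction")
    perClass <- floor(fr * nSing)
    classNames <- vapply(classes, `[[`, character(1), "name")
    singClass <- rep(c(classNames, "other"),
                     c(perClass, nSing - sum(perClass)))
    condition <- sample(config$conditions, nC, replace = TRUE,
                        prob = config$conditionFractions)
    replicate <- sample(1:2, nC, replace = TRUE)
    sex <- sample(c("F", "M"), nC, replace = TRUE)

    # per-gene log2 fold change of condition 2 vs condition 1
    lfc <- stats::setNames(rep(0, nG), geneNames)
    if (!is.null(config$deSpec)) {
      miss <- setdiff(config$deSpec$gene, geneNames)
      if (length(miss))
        stop("deSpec genes not in gene table: ",
             paste(miss, collapse = ", "), call. = FALSE)
      lfc[config$deSpec$gene] <- config$deSpec$log2FC
    }

    muForCell <- function(cls, cond) {
      m <- mu
      ci <- match(cls, classNames)
      if (!is.na(ci)) {
        mk <- classes[[ci]]$markers
        m[match(mk, geneNames)] <- config$markerMu
      }
      if (cond == config$conditions[2L]) m <- m * 2^lfc
      m
    }

    singMu <- vapply(seq_len(nSing),
                     function(i) muForCell(singClass[i], condition[i]),
                     numeric(nG))
    singCounts <- rzinbMatrix(singMu, theta, pi)

    isDoublet <- c(rep(FALSE, nSing), rep(TRUE, nDoub))
    trueClass <- c(singClass, rep(NA_character_, nDoub))
    doubletParents <- character(nC)
    if (nDoub > 0) {
      if (length(classNames) < 2L)
        stop("doublets need at least two marker classes", call. = FALSE)
      doubCounts <- matrix(0L, nG, nDoub)
      for (j in seq_len(nDoub)) {
        pair <- sample(classNames, 2L)
        cond <- condition[nSing + j]
        cj <- rzinbMatrix(cbind(muForCell(pair[1], cond),
                                muForCell(pair[2], cond)), theta, pi)
        doubCounts[, j] <- cj[, 1L] + cj[, 2L]
        doubletParents[nSing + j] <- paste(sort(pair), collapse = "+")
        trueClass[nSing + j] <- doubletParents[nSing + j]
      }
      counts <- cbind(singCounts, doubCounts)
    } else {
      counts <- singCounts
    }

    # planted QC violators among singlets (never the marker doublets)
    qcViolation <- rep(NA_character_, nC)
    nViol <- sum(config$qcViolators)
    if (nViol > 0) {
      if (nViol > nSing)
        stop("more QC violators requested than singlet cells",
             call. = FALSE)
      violCells <- sample(seq_len(nSing), nViol)
      types <- rep(names(config$qcViolators), config$qcViolators)
      for (k in seq_along(violCells)) {
        j <- violCells[k]
        y <- counts[, j]
        switch(types[k],
          low_features = {
            keep <- sample(which(y > 0), min(100L, sum(y > 0)))
            y[-keep] <- 0L
          },
          high_umi = {
            y <- y * ceiling(22000 / max(sum(y), 1L))
          },
          high_mito = {
            sel <- geneGroup == "mito"
            y[sel] <- y[sel] + stats::rmultinom(
              1L, sum(y[!sel]), rep(1, sum(sel)))[, 1L]
          },
          high_rrna = {
            sel <- geneGroup == "rrna"
            y[sel] <- y[sel] + stats::rmultinom(
              1L, sum(y[!sel]), rep(1, sum(sel)))[, 1L]
          },
          high_ribo = {
            sel <- geneGroup == "ribo"
            y[sel] <- y[sel] + stats::rmultinom(
              1L, sum(y[!sel]), rep(1, sum(sel)))[, 1L]
          })
        counts[, j] <- y
        qcViolation[j] <- types[k]
      }
    }

    # shuffle cell order so planted structure is not positional
    ord <- sample(nC)
    counts <- counts[, ord, drop = FALSE]
    trueClass <- trueClass[ord]; isDoublet <- isDoublet[ord]
    condition <- condition[ord]; replicate <- replicate[ord]
    sex <- sex[ord]; qcViolation <- qcViolation[ord]
    doubletParents <- doubletParents[ord]

    barcodes <- sprintf("cell%05d", seq_len(nC))
    dimnames(counts) <- list(geneNames, barcodes)
    countsSp <- Matrix::Matrix(counts, sparse = TRUE)

    libsize <- Matrix::colSums(countsSp)
    sf <- ifelse(libsize > 0, 1e4 / libsize, 0)
    logcounts <- countsSp %*% Matrix::Diagonal(x = sf)
    logcounts <- log1p(logcounts)
    dimnames(logcounts) <- dimnames(countsSp)
    lc <- as.matrix(logcounts)
    rm0 <- rowMeans(lc)
    rsd <- sqrt(rowSums((lc - rm0)^2) / (nC - 1))
    scaled <- (lc - rm0) / ifelse(rsd > 0, rsd, 1)

    # marker thresholds on the scaled layer: midpoint between the zero
    # background and the lowest expressing value, per marker gene
    markerThresholds <- numeric(0)
    for (ci in seq_along(classes)) {
      cls <- classes[[ci]]
      inClass <- (!is.na(trueClass)) &
        (trueClass == cls$name | grepl(cls$name, trueClass, fixed = TRUE))
      for (mk in cls$markers) {
        v <- scaled[mk, ]
        expr <- inClass & counts[mk, ] > 0
        if (!any(expr) || all(expr)) next
        markerThresholds[mk] <-
          (max(v[!expr]) + min(v[expr])) / 2
      }
    }

    cd <- DataFrame(barcode = barcodes, condition = condition,
                    replicate = replicate, sex = sex,
                    trueClass = trueClass, isDoublet = isDoublet,
                    doubletParents = doubletParents,
                    qcViolation = qcViolation, row.names = barcodes)
    rd <- DataFrame(gene = geneNames, geneGroup = geneGroup,
                    mu = mu, theta = theta, pi = pi,
                    log2FC = unname(lfc), row.names = geneNames)
    sce <- SingleCellExperiment(
      assays = list(counts = countsSp, logcounts = logcounts,
                    scaled = scaled),
      colData = cd, rowData = rd)
    metadata(sce)$groundTruth <- list(
      config = config, markerThresholds = markerThresholds,
      nDoublets = nDoub, classNames = classNames)
    sce
  })
}
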