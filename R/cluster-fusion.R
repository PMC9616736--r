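#' Marker rules for major cell-class assignment
#'
#' Ordered rule list mapping marker programs to the seven major brain
#' cell classes. A cluster receives the first (highest-priority) class
#' whose marker genes all exceed their thresholds in the cluster's mean
#' scaled expression; clusters matching no rule are labelled "other".
#' Kenyon cells precede the fast-transmitter classes because they are
#' themselves cholinergic and would otherwise be absorbed by the
#' `VAChT` rule.
#'
#' @param threshold default mean-scaled-expression threshold applied to
#'   every rule gene.
#' @return List of rules, each `list(class=, genes=, threshold=)`.
#' @export
majorClassRules <- function(threshold = 1) {
  rule <- function(class, genes) list(class = class, genes = genes,
                                      threshold = threshold)
  list(rule("Kenyon", c("ey", "Dop1R2", "Pka-C1", "mub")),
       rule("glia", "CG10433"),
       rule("monoaminergic", "Vmat"),
       rule("cholinergic", "VAChT"),
       rule("glutamatergic", "VGlut"),
       rule("GABAergic", "Gad1"))
}

#' Assign clusters to major cell classes by marker expression
#'
#' @param clusterMeans genes x clusters matrix of mean scaled
#'   expression per cluster, gene names as rownames.
#' @param rules ordered rule list from [majorClassRules()].
#' @return Character vector of class labels, one per cluster.
#' @examples
#' m <- matrix(0, 9, 2, dimnames = list(
#'   c("ey","Dop1R2","Pka-C1","mub","Vmat","CG10433","VAChT","VGlut","Gad1"),
#'   c("c1","c2")))
#' m["VAChT", 1] <- 2
#' assignMajorClass(m)   # "cholinergic", "other"
#' @export
assignMajorClass <- function(clusterMeans, rules = majorClassRules()) {
  genes <- unique(unlist(lapply(rules, `[[`, "genes")))
  miss <- setdiff(genes, rownames(clusterMeans))
  if (length(miss))
    stop("marker gene(s) missing from cluster means: ",
         paste(miss, collapse = ", "), call. = FALSE)
  vapply(seq_len(ncol(clusterMeans)), function(j) {
    for (r in rules) {
      if (all(clusterMeans[r$genes, j] > r$threshold)) return(r$class)
    }
    "other"
  }, character(1))
}

#' Build a cluster tree from an embedding
#'
#' Per-cluster centroids in the embedding (e.g. PCA) space are linked
#' by average-linkage agglomeration on Euclidean centroid distances.
#' The tree depends only on the set of cells per cluster, not on cell
#' order.
#'
#' @param embedding cells x dimensions numeric matrix.
#' @param labels cluster label per cell (vector, coerced to character).
#' @return List of class `ClusterTree` with elements `hclust` (the
#'   merge structure), `centroids` (clusters x dims) and `sizes`.
#' @export
buildClusterTree <- function(embedding, labels) {
  embedding <- as.matrix(embedding)
  labels <- as.character(labels)
  if (nrow(embedding) != length(labels))
    stop("embedding rows must align with labels", call. = FALSE)
  sizes <- table(labels)
  if (any(sizes == 0L)) stop("cluster with 0 cells", call. = FALSE)
  if (length(sizes) < 2L)
    stop("need at least two clusters to build a tree", call. = FALSE)
  centroids <- rowsum(embedding, labels) / as.vector(sizes[sort(names(sizes))])
  centroids <- centroids[order(rownames(centroids)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(centroids), method = "average")
  structure(list(hclust = hc, centroids = centroids,
                 sizes = as.vector(sizes[rownames(centroids)])),
            class = "ClusterTree")
}

#' @export
print.ClusterTree <- function(x, ...) {
  cat("ClusterTree:", nrow(x$centroids), "clusters,",
      ncol(x$centroids), "dims; leaves:",
      paste(utils::head(rownames(x$centroids), 8), collapse = ", "),
      if (nrow(x$centroids) > 8) "..." else "", "\n")
  invisible(x)
}

# sibling leaf pairs of an hclust tree, ordered by merge height
# (most similar pairs first)
siblingLeafPairs <- function(hc) {
  m <- hc$merge
  sib <- which(m[, 1] < 0 & m[, 2] < 0)
  sib <- sib[order(hc$height[sib])]
  lapply(sib, function(i) hc$labels[-m[i, ]])
}

#' Configuration for cluster fusion
#'
#' @param minDeGenes fuse a sibling pair when fewer than this many
#'   protein-coding genes are differentially expressed between them
#'   (default 10).
#' @param alpha BH-adjusted p-value cutoff defining a DE gene
#'   (default 0.05).
#' @param proteinCoding optional character vector of protein-coding
#'   gene ids; `NULL` treats all genes as eligible.
#' @param minCellsPerCluster pairs with a smaller cluster are skipped
#'   (default 3).
#' @return List of class `FusionConfig`.
#' @export
fusionConfig <- function(minDeGenes = 10L, alpha = 0.05,
                         proteinCoding = NULL, minCellsPerCluster = 3L) {
  if (minDeGenes < 1L) stop("minDeGenes must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)",
                                     call. = FALSE)
  structure(list(minDeGenes = as.integer(minDeGenes), alpha = alpha,
                 proteinCoding = proteinCoding,
                 minCellsPerCluster = as.integer(minCellsPerCluster)),
            class = "FusionConfig")
}

# number of DE genes between two cell groups on the normalized layer:
# per-gene two-sample Wilcoxon rank-sum, BH adjusted across tested genes
countDeGenes <- function(normA, normB, alpha) {
  keep <- Matrix::rowSums(normA) + Matrix::rowSums(normB) > 0
  if (!any(keep)) return(0L)
  a <- as.matrix(normA[keep, , drop = FALSE])
  b <- as.matrix(normB[keep, , drop = FALSE])
  p <- vapply(seq_len(nrow(a)), function(g) {
    suppressWarnings(stats::wilcox.test(a[g, ], b[g, ],
                                        exact = FALSE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  sum(stats::p.adjust(p, "BH") < alpha)
}

#' Fuse indistinct sibling clusters on a centroid tree
#'
#' Iteratively rebuilds the centroid tree and, walking sibling leaf
#' pairs from the lowest merge upward, tests each pair gene-by-gene
#' with a two-sample Wilcoxon rank-sum test on the normalized layer
#' (restricted to protein-coding genes detected in at least one cell of
#' the pair, BH-adjusted within the tested set). A pair with fewer than
#' `minDeGenes` genes at adjusted p below `alpha` is fused (the merged
#' cluster keeps the larger member's label) and the tree is rebuilt;
#' iteration stops when no pair fuses. Cluster count never increases
#' and the procedure terminates in at most (initial clusters - 1)
#' fusions.
#'
#' @param norm genes x cells normalized expression matrix.
#' @param embedding cells x dims embedding used for the centroid tree.
#' @param labels initial cluster label per cell.
#' @param config a [fusionConfig()] object.
#' @return List with `labels` (final label per cell) and `log`
#'   (data.frame of tested pairs: members, sizes, DE-gene count,
#'   decision).
#' @export
fuseClusters <- function(norm, embedding, labels,
                         config = fusionConfig()) {
  labels <- as.character(labels)
  if (ncol(norm) != length(labels))
    stop("norm columns must align with labels", call. = FALSE)
  log <- data.frame(clusterA = character(), clusterB = character(),
                    nA = integer(), nB = integer(), nDeGenes = integer(),
                    decision = character(), stringsAsFactors = FALSE)
  if (!is.null(config$proteinCoding)) {
    pcSel <- rownames(norm) %in% config$proteinCoding
    if (!any(pcSel))
      stop("no protein-coding genes found in the matrix", call. = FALSE)
  } else pcSel <- rep(TRUE, nrow(norm))
  normPC <- norm[pcSel, , drop = FALSE]

  tested <- new.env(parent = emptyenv())  # memo: pair key -> nDE
  repeat {
    if (length(unique(labels)) < 2L) break
    tree <- buildClusterTree(embedding, labels)
    fusedThisRound <- FALSE
    for (pair in siblingLeafPairs(tree$hclust)) {
      a <- pair[1]; b <- pair[2]
      nA <- sum(labels == a); nB <- sum(labels == b)
      if (min(nA, nB) < config$minCellsPerCluster) {
        log[nrow(log) + 1L, ] <- list(a, b, nA, nB, NA_integer_,
                                      "skipped-small")
        next
      }
      key <- paste(sort(c(a, b)), collapse = "\r")
      nDE <- if (!is.null(tested[[key]])) tested[[key]] else {
        v <- countDeGenes(normPC[, labels == a, drop = FALSE],
                          normPC[, labels == b, drop = FALSE],
                          config$alpha)
        tested[[key]] <- v
        v
      }
      if (nDE < config$minDeGenes) {
        winner <- if (nA >= nB) a else b
        loser <- setdiff(c(a, b), winner)
        labels[labels == loser] <- winner
        log[nrow(log) + 1L, ] <- list(a, b, nA, nB, nDE, "fused")
        # drop memoized results that involve the grown cluster
        for (k in ls(tested)) {
          if (winner %in% strsplit(k, "\r", fixed = TRUE)[[1]])
            rm(list = k, envir = tested)
        }
        fusedThisRound <- TRUE
        break  # membership changed: rebuild the tree
      } else {
        log[nrow(log) + 1L, ] <- list(a, b, nA, nB, nDE, "kept")
      }
    }
    if (!fusedThisRound) break
  }
  list(labels = labels, log = log)
}
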