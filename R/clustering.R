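## Accessibility normalization (SPOT correction, log10, row scaling to a
## maximum of 10), k-means temporal clustering, cluster labelling and
## per-cluster summaries.

#' Normalize a raw accessibility matrix
#'
#' Applies, in order: division of each sample's densities by that
#' sample's SPOT score (library-quality correction), the transform
#' log10(density + 1), and row scaling so the maximum of each row is
#' exactly 10. All-zero rows are left at zero.
#'
#' @param raw DHS x stage matrix of maximum normalized densities.
#' @param spot per-sample SPOT scores in (0, 1], one per column.
#' @return matrix of transformed values in [0, 10].
#' @examples
#' normalizeDensity(matrix(c(2, 5, 9), 1), c(0.4, 0.5, 0.45))
#' @export
normalizeDensity <- function(raw, spot) {
  raw <- as.matrix(raw)
  if (length(spot) != ncol(raw))
    stop("one SPOT score per column is required")
  if (any(spot <= 0) || any(spot > 1))
    stop("SPOT scores must lie in (0, 1]")
  v <- sweep(raw, 2, spot, "/")
  v <- log10(v + 1)
  rmax <- apply(v, 1, max)
  pos <- rmax > 0
  ## (v / rmax) * 10 makes the row maximum exactly 10 in floating point
  v[pos, ] <- (v[pos, , drop = FALSE] / rmax[pos]) * 10
  v
}

#' Assemble a ranged accessibility experiment
#'
#' Bundles the master list, the raw density matrix and its normalized
#' transform into a `RangedSummarizedExperiment` with per-sample stage
#' and SPOT annotations.
#'
#' @param master GRanges of master DHSs (rows).
#' @param raw DHS x sample raw density matrix.
#' @param spot per-sample SPOT scores.
#' @param stages per-sample stage labels (defaults to column names).
#' @return a `RangedSummarizedExperiment` with assays `raw` and
#'   `transformed`.
#' @export
dhsExperiment <- function(master, raw, spot, stages = colnames(raw)) {
  SummarizedExperiment::SummarizedExperiment(
    assays = list(raw = raw, transformed = normalizeDensity(raw, spot)),
    rowRanges = master,
    colData = DataFrame(stage = stages, spot = spot))
}

#' k-means clustering of temporal accessibility profiles
#'
#' Partitions DHSs into `k` groups of similar temporal activity by
#' k-means (Lloyd iterations, Euclidean distance on the transformed
#' values, best of `nInit` random initializations by total within-cluster
#' sum of squares). Deterministic under a fixed seed.
#'
#' @param mat transformed DHS x stage matrix (rows named by DHS id).
#' @param k number of clusters (default 12).
#' @param seed RNG seed.
#' @param nInit random initializations.
#' @param maxIter maximum Lloyd iterations.
#' @return a [ClusterModel] with temporal labels from [labelClusters()].
#' @export
kmeansCluster <- function(mat, k = 12, seed = 1, nInit = 25,
                          maxIter = 300) {
  mat <- as.matrix(mat)
  if (k > nrow(mat)) stop("k exceeds the number of rows")
  fit <- function(alg) {
    set.seed(as.integer(seed))
    suppressWarnings(kmeans(mat, centers = k, iter.max = maxIter,
                            nstart = nInit, algorithm = alg))
  }
  ## Lloyd can abort on an empty cluster; Hartigan-Wong re-seeds instead
  km <- tryCatch(fit("Lloyd"), error = function(e) fit("Hartigan-Wong"))
  stages <- colnames(mat)
  if (is.null(stages)) stages <- paste0("stage", seq_len(ncol(mat)))
  new("ClusterModel", k = as.integer(k),
      assignments = setNames(as.integer(km$cluster), rownames(mat)),
      centroids = km$centers,
      labels = labelClusters(km$centers, stages),
      seed = as.integer(seed), totWithinss = km$tot.withinss)
}

#' Temporal label of cluster centroids
#'
#' Labels each centroid profile across the ordered stages:
#' `C` (constitutive) when the profile is flat within a relative
#' tolerance ((max - min)/max <= `flatTol`); `O` (other) when the profile
#' has an interior minimum below both ends (valley shape); otherwise
#' `E`/`M`/`L` by the stage of the maximum (first/interior/last).
#'
#' @param centroids cluster x stage matrix.
#' @param stages ordered stage labels.
#' @param flatTol relative flatness tolerance for `C` (default 0.2).
#' @return character vector of labels, one per centroid.
#' @export
labelClusters <- function(centroids, stages = colnames(centroids),
                          flatTol = 0.2) {
  centroids <- as.matrix(centroids)
  nS <- ncol(centroids)
  apply(centroids, 1, function(v) {
    mx <- max(v)
    if (mx <= 0) return("C")
    if ((mx - min(v)) / mx <= flatTol) return("C")
    imn <- which.min(v)
    if (imn > 1L && imn < nS && v[imn] < v[1L] && v[imn] < v[nS])
      return("O")
    imx <- which.max(v)
    if (imx == 1L) "E" else if (imx == nS) "L" else "M"
  })
}

#' Per-cluster summary table
#'
#' For each cluster: size, median transformed accessibility per stage,
#' percentage of member DHSs that are promoter DHSs, and for each ChIP'd
#' factor the percentage of that factor's total binding sites whose
#' occupied DHS lies in the cluster (shares across clusters sum to at
#' most 100).
#'
#' @param model a [ClusterModel].
#' @param mat the transformed matrix the model was fitted on.
#' @param promoterFlags named logical vector (by DHS id).
#' @param occupancyList named list of [occupancy()] results, one per
#'   factor.
#' @return data.frame with one row per cluster.
#' @export
clusterSummary <- function(model, mat, promoterFlags = NULL,
                           occupancyList = list()) {
  asg <- assignments(model)
  if (!is.null(promoterFlags) &&
      !all(names(asg) %in% names(promoterFlags)))
    stop("promoterFlags must cover every clustered DHS id")
  k <- model@k
  med <- t(vapply(seq_len(k), function(cl) {
    rows <- names(asg)[asg == cl]
    apply(mat[rows, , drop = FALSE], 2, median)
  }, numeric(ncol(mat))))
  colnames(med) <- paste0("median_", colnames(mat))
  out <- data.frame(cluster = seq_len(k), label = clusterLabels(model),
                    n = as.integer(table(factor(asg, levels = seq_len(k)))),
                    med, check.names = FALSE)
  if (!is.null(promoterFlags)) {
    out$pctPromoter <- vapply(seq_len(k), function(cl) {
      rows <- names(asg)[asg == cl]
      100 * mean(promoterFlags[rows])
    }, numeric(1))
  }
  for (f in names(occupancyList)) {
    occ <- occupancyList[[f]]
    occIds <- occ$calls$dhsId[occ$calls$status == "occupied"]
    tot <- occ$totalPeaks
    out[[paste0("pctSites_", f)]] <- vapply(seq_len(k), function(cl) {
      rows <- names(asg)[asg == cl]
      100 * sum(occIds %in% rows) / tot
    }, numeric(1))
  }
  out
}

#' Purity of a clustering against ground-truth labels
#'
#' Weighted mean over clusters of the fraction of members carrying the
#' cluster's majority truth label.
#'
#' @param model a [ClusterModel] (or an integer assignment vector).
#' @param truthLabels character vector of true labels, aligned with the
#'   assignments.
#' @return purity in [0, 1].
#' @export
clusterPurity <- function(model, truthLabels) {
  asg <- if (is(model, "ClusterModel")) assignments(model) else model
  stopifnot(length(asg) == length(truthLabels))
  tab <- table(asg, truthLabels)
  sum(apply(tab, 1, max)) / length(asg)
}
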