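## Per-TF motif presence on DHSs and cumulative hypergeometric enrichment
## with Bonferroni correction.

#' Motif presence of transcription factors on DHSs
#'
#' Flags a DHS for a TF when at least one motif hit linked to that TF,
#' with match p-value strictly below the scan threshold, overlaps the DHS
#' by at least 1 bp. Multiple motif models per TF are pooled by union;
#' hits carrying no TF link are skipped and counted.
#'
#' @param master GRanges of master DHSs (named).
#' @param hits GRanges of motif hits with metadata columns `matchP` and
#'   either `tf` or `motifId` resolvable through `tfMap`.
#' @param tfMap optional data.frame (`motifId`, `tf`) linking motif
#'   models to factors; a motif may map to several TFs and vice versa.
#' @param pThreshold match p-value threshold (default 1e-4).
#' @return logical DHS x TF matrix with attribute `skippedHits` (number
#'   of hits without a TF link).
#' @export
dhsMotifPresence <- function(master, hits, tfMap = NULL,
                             pThreshold = 1e-4) {
  tf <- mcols(hits)$tf
  hitIdx <- seq_along(hits)
  if (!is.null(tfMap)) {
    j <- match(mcols(hits)$motifId, tfMap$motifId)
    expanded <- merge(data.frame(i = hitIdx,
                                 motifId = mcols(hits)$motifId),
                      tfMap, by = "motifId")
    hitIdx <- expanded$i
    tf <- expanded$tf
  }
  skipped <- sum(is.na(tf)) +
    (length(hits) - length(unique(hitIdx[!is.na(tf)])))
  keep <- !is.na(tf) & mcols(hits)$matchP[hitIdx] < pThreshold
  hitIdx <- hitIdx[keep]; tf <- tf[keep]
  tfs <- sort(unique(tf))
  pres <- matrix(FALSE, length(master), length(tfs),
                 dimnames = list(names(master), tfs))
  if (length(hitIdx)) {
    ov <- findOverlaps(hits[hitIdx], master, ignore.strand = TRUE)
    pres[cbind(subjectHits(ov),
               match(tf[queryHits(ov)], tfs))] <- TRUE
  }
  if (skipped > 0)
    warning(skipped, " motif hit(s) without a TF link skipped")
  attr(pres, "skippedHits") <- skipped
  pres
}

#' Cumulative hypergeometric enrichment of TF motifs in a DHS set
#'
#' For each TF, tests whether the DHSs of a cluster (or any focal set)
#' contain its motif more often than expected from the motif's overall
#' prevalence in the background DHS universe:
#' p = P(X >= k), X ~ Hypergeometric(N, K, n), upper tail inclusive of k.
#'
#' @param clusterIds DHS ids of the focal set (subset of
#'   `backgroundIds`).
#' @param presence logical DHS x TF matrix from [dhsMotifPresence()].
#' @param backgroundIds DHS ids of the background universe (default: all
#'   rows of `presence`).
#' @param cluster label recorded in the output.
#' @return data.frame with one row per TF: `tf`, `cluster`, `k`, `n`,
#'   `K`, `N`, `p`, `degenerate` (TRUE when K = 0, p set to 1).
#' @export
hypergeomEnrichment <- function(clusterIds, presence,
                                backgroundIds = rownames(presence),
                                cluster = "cluster") {
  stopifnot(all(clusterIds %in% backgroundIds))
  bg <- presence[backgroundIds, , drop = FALSE]
  fg <- presence[clusterIds, , drop = FALSE]
  N <- length(backgroundIds)
  n <- length(clusterIds)
  K <- colSums(bg)
  k <- colSums(fg)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  degenerate <- K == 0
  p[degenerate] <- 1
  data.frame(tf = colnames(presence), cluster = cluster,
             k = as.integer(k), n = n, K = as.integer(K), N = N,
             p = as.numeric(p), degenerate = degenerate,
             row.names = NULL)
}

#' Bonferroni correction of enrichment records
#'
#' @param records data.frame with a `p` column.
#' @param m number of tests in the family (default: number of records).
#' @param alpha family-wise significance level applied to the corrected
#'   p-values (default 0.01).
#' @return `records` with columns `pBonf = min(1, p * m)` and
#'   `significant`.
#' @export
bonferroniCorrect <- function(records, m = nrow(records), alpha = 0.01) {
  stopifnot(m >= nrow(records) || m >= 1)
  records$pBonf <- pmin(1, records$p * m)
  records$significant <- records$pBonf < alpha
  records
}

#' Enrichment records over every cluster of a model
#'
#' Runs [hypergeomEnrichment()] of all TFs against the full master-list
#' background for each cluster and applies one Bonferroni family over
#' all TF x cluster tests.
#'
#' @param model a [ClusterModel].
#' @param presence logical DHS x TF matrix.
#' @param alpha family-wise significance level.
#' @return data.frame of corrected records for the full TF x cluster
#'   grid.
#' @export
clusterEnrichment <- function(model, presence, alpha = 0.01) {
  asg <- assignments(model)
  stopifnot(all(names(asg) %in% rownames(presence)))
  recs <- lapply(seq_len(model@k), function(cl) {
    ids <- names(asg)[asg == cl]
    hypergeomEnrichment(ids, presence, backgroundIds = names(asg),
                        cluster = as.character(cl))
  })
  recs <- do.call(rbind, recs)
  bonferroniCorrect(recs, m = nrow(recs), alpha = alpha)
}

#' TF x cluster matrix of -log10 enrichment p-values
#'
#' Degenerate cells (K = 0) and p = 1 export as 0.
#'
#' @param records enrichment records covering the TF x cluster grid.
#' @param corrected use `pBonf` instead of raw `p` when available.
#' @return numeric TF x cluster matrix, values >= 0.
#' @export
enrichmentMatrix <- function(records, corrected = FALSE) {
  pcol <- if (corrected && "pBonf" %in% names(records)) "pBonf" else "p"
  tfs <- sort(unique(records$tf))
  cls <- unique(records$cluster)
  m <- matrix(0, length(tfs), length(cls),
              dimnames = list(tfs, as.character(cls)))
  p <- records[[pcol]]
  p[records$degenerate] <- 1
  m[cbind(match(records$tf, tfs),
          match(as.character(records$cluster), as.character(cls)))] <-
    -log10(pmax(p, 1e-300))
  m[m < 0] <- 0
  m
}
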