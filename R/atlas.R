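## Master-list construction and interval classification: genomic
## partition, promoter assignment, ChIP occupancy, region-specific
## subtraction and pairwise-overlap clustering of DHS sets.

#' Build a non-redundant master list of DHSs across samples
#'
#' Transitively overlapping (or abutting) peaks across all input sets are
#' merged into maximal union intervals; the result is sorted, pairwise
#' non-overlapping, and records which samples contributed to each master
#' DHS. The construction is idempotent.
#'
#' @param peakSets named list of GRanges (one peak set per sample/stage).
#' @return GRanges of master DHSs, named `DHS_<i>`, with metadata column
#'   `sourceSamples` (CharacterList of contributing set names).
#' @export
buildMasterList <- function(peakSets) {
  if (is.null(names(peakSets)))
    names(peakSets) <- paste0("set", seq_along(peakSets))
  all <- unlist(GRangesList(lapply(peakSets, function(g) {
    mcols(g) <- NULL
    names(g) <- NULL
    g
  })), use.names = FALSE)
  master <- GenomicRanges::reduce(sort(all), ignore.strand = TRUE)
  src <- vector("list", length(master))
  for (nm in names(peakSets)) {
    hit <- unique(subjectHits(findOverlaps(peakSets[[nm]], master,
                                           ignore.strand = TRUE)))
    for (h in hit) src[[h]] <- c(src[[h]], nm)
  }
  mcols(master)$sourceSamples <- CharacterList(src)
  names(master) <- sprintf("DHS_%06d", seq_along(master))
  master
}

#' Maximum normalized density per master DHS per sample
#'
#' For each master DHS and sample, the maximum tags-per-million window
#' density over all windows intersecting the DHS; 0 when no window
#' intersects.
#'
#' @param master GRanges of master DHSs (named).
#' @param tracks named list of [CutTrack] objects, one per sample.
#' @return numeric matrix (DHS x sample).
#' @export
maxDensityPerSample <- function(master, tracks) {
  m <- matrix(0, length(master), length(tracks),
              dimnames = list(names(master), names(tracks)))
  for (j in seq_along(tracks)) {
    w <- cutWindows(tracks[[j]])
    ov <- findOverlaps(w, master, ignore.strand = TRUE)
    if (!length(ov)) next
    mx <- tapply(mcols(w)$density[queryHits(ov)], subjectHits(ov), max)
    m[as.integer(names(mx)), j] <- as.numeric(mx)
  }
  m
}

#' Classify DHSs as promoter-proximal
#'
#' A DHS is a promoter DHS when it intersects the 1-kb region upstream of
#' any annotated TSS. Upstream is strand-aware: for a plus-strand TSS the
#' window covers the `upstream` bases before the TSS; for a minus-strand
#' TSS the bases after it.
#'
#' @param dhs GRanges of DHSs.
#' @param tss stranded width-1 GRanges of TSSs.
#' @param upstream window size in bp (default 1000).
#' @return logical vector along `dhs`.
#' @export
classifyPromoter <- function(dhs, tss, upstream = 1000) {
  prom <- GenomicRanges::promoters(tss, upstream = upstream,
                                   downstream = 0)
  prom <- GenomicRanges::trim(prom)
  IRanges::overlapsAny(dhs, prom, ignore.strand = TRUE)
}

#' Partition DHSs by genomic feature
#'
#' Assigns every DHS exactly one category with precedence
#' promoter > exon > intron > intergenic; intergenic DHSs are split at
#' `proximalDist` bp from the nearest TSS into proximal vs distal.
#'
#' @param master GRanges of master DHSs.
#' @param annotation list with elements `tss` (stranded GRanges),
#'   `exons` and `introns` (GRanges). Missing elements are skipped with a
#'   warning.
#' @param upstream promoter window in bp.
#' @param proximalDist proximal/distal intergenic boundary in bp from the
#'   nearest TSS.
#' @return factor along `master` with levels promoter, exon, intron,
#'   proximal_intergenic, distal_intergenic.
#' @export
genomicPartition <- function(master, annotation, upstream = 1000,
                             proximalDist = 2500) {
  lv <- c("promoter", "exon", "intron", "proximal_intergenic",
          "distal_intergenic")
  lab <- rep("distal_intergenic", length(master))
  if (!is.null(annotation$tss)) {
    d <- GenomicRanges::distanceToNearest(master, annotation$tss,
                                          ignore.strand = TRUE)
    dist <- rep(Inf, length(master))
    dist[queryHits(d)] <- mcols(d)$distance
    lab[dist <= proximalDist] <- "proximal_intergenic"
  } else {
    warning("no TSS annotation: intergenic DHSs all labelled distal")
  }
  for (cls in c("intron", "exon")) {
    key <- paste0(cls, "s")
    if (is.null(annotation[[key]])) {
      warning("no ", cls, " annotation: category unused")
      next
    }
    hit <- IRanges::overlapsAny(master, annotation[[key]],
                                ignore.strand = TRUE)
    lab[hit] <- cls
  }
  if (!is.null(annotation$tss))
    lab[classifyPromoter(master, annotation$tss, upstream)] <- "promoter"
  factor(lab, levels = lv)
}

#' ChIP-seq occupancy of master DHSs
#'
#' A ChIP peak overlapping exactly one DHS by at least `minOverlap` bp
#' marks that DHS occupied. Peaks overlapping more than one DHS by at
#' least `minOverlap` bp each are excluded from occupancy and tallied;
#' peaks reaching no DHS at that overlap are tallied as non-overlapping.
#'
#' @param master GRanges of master DHSs (named).
#' @param chipPeaks GRanges of ChIP-seq peak calls for one factor.
#' @param factor label of the ChIP'd factor.
#' @param minOverlap minimum overlap in bp (default 75).
#' @return list with `calls` (DataFrame dhsId/factor/status/overlapBp,
#'   one row per master DHS), `counts` (named integer: occupiedPeaks,
#'   multiDhsExcluded, nonOverlapping) and `totalPeaks`.
#' @export
occupancy <- function(master, chipPeaks, factor = "TF", minOverlap = 75) {
  ov <- findOverlaps(chipPeaks, master, minoverlap = minOverlap,
                     ignore.strand = TRUE)
  nHits <- tabulate(queryHits(ov), nbins = length(chipPeaks))
  single <- which(nHits == 1L)
  multi <- sum(nHits > 1L)
  none <- sum(nHits == 0L)
  keep <- queryHits(ov) %in% single
  dhsHit <- subjectHits(ov)[keep]
  pkHit <- queryHits(ov)[keep]
  ovBp <- width(pintersect(chipPeaks[pkHit], master[dhsHit],
                           ignore.strand = TRUE))
  status <- rep("unoccupied", length(master))
  overlapBp <- integer(length(master))
  status[dhsHit] <- "occupied"
  best <- tapply(ovBp, dhsHit, max)
  overlapBp[as.integer(names(best))] <- as.integer(best)
  calls <- DataFrame(dhsId = names(master), factor = factor,
                     status = factor(status,
                                     levels = c("occupied", "unoccupied")),
                     overlapBp = overlapBp)
  list(calls = calls,
       counts = c(occupiedPeaks = length(single),
                  multiDhsExcluded = multi, nonOverlapping = none),
       totalPeaks = length(chipPeaks))
}

#' Region- or cell-type-specific DHSs by subtraction
#'
#' Retains the target DHSs whose overlap with every single DHS of every
#' comparison set stays below `minOverlap` bp.
#'
#' @param target GRanges of the target DHS set.
#' @param others list of GRanges to subtract.
#' @param minOverlap overlap (bp) at or above which a target DHS is
#'   removed (default 25).
#' @return GRanges subset of `target`.
#' @export
subtractSpecific <- function(target, others, minOverlap = 25) {
  if (!length(others)) {
    warning("no comparison sets: target returned unchanged")
    return(target)
  }
  drop <- rep(FALSE, length(target))
  for (o in others)
    drop <- drop | IRanges::overlapsAny(target, o, minoverlap = minOverlap,
                                        ignore.strand = TRUE)
  target[!drop]
}

#' Pairwise-overlap matrix and hierarchical clustering of DHS sets
#'
#' Entry (A, B) is the fraction of A's peaks overlapping any peak of B by
#' at least 1 bp (asymmetric). Sets are clustered by average linkage on
#' the distance 1 minus the symmetrized (arithmetic-mean) overlap.
#'
#' @param sets named list of at least two GRanges.
#' @return list with `overlap` (asymmetric matrix, diagonal 1),
#'   `dist` (symmetrized distance) and `hclust` (the average-linkage
#'   tree; empty sets are excluded with a warning).
#' @export
pairwiseOverlapMatrix <- function(sets) {
  stopifnot(length(sets) >= 2)
  n <- length(sets)
  nm <- names(sets)
  m <- matrix(0, n, n, dimnames = list(nm, nm))
  sizes <- lengths(sets)
  for (a in seq_len(n)) {
    if (sizes[a] == 0L) next
    for (b in seq_len(n)) {
      m[a, b] <- mean(IRanges::overlapsAny(sets[[a]], sets[[b]],
                                           ignore.strand = TRUE))
    }
  }
  diag(m) <- 1
  keep <- sizes > 0L
  if (!all(keep))
    warning("empty set(s) excluded from clustering: ",
            paste(nm[!keep], collapse = ", "))
  sym <- (m[keep, keep, drop = FALSE] +
            t(m[keep, keep, drop = FALSE])) / 2
  d <- as.dist(1 - sym)
  hc <- if (sum(keep) >= 2) hclust(d, method = "average") else NULL
  list(overlap = m, dist = d, hclust = hc)
}

#' Fraction of externally validated enhancer candidates with a DHS
#'
#' Utility for summarising validation against an external enhancer
#' catalogue: the percentage (0-100, rounded to integer) of candidate
#' elements that carry a DHS.
#'
#' @param nWithDhs candidates overlapping a DHS.
#' @param nTotal total candidates.
#' @return rounded percentage.
#' @export
enhancerValidationRate <- function(nWithDhs, nTotal) {
  stopifnot(nTotal > 0, nWithDhs >= 0, nWithDhs <= nTotal)
  round(100 * nWithDhs / nTotal)
}
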