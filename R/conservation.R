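## Cross-species DHS conservation: shared / diverged / unalignable
## categorization through an orthology interval map, category
## distributions per region and pairwise chi-squared comparison.

## orthology map data.frame -> GRanges pair (source keyed, target in mcols)
.orthoGRanges <- function(map) {
  src <- GRanges(map$srcChrom, IRanges(map$srcStart, map$srcEnd))
  mcols(src)$tgtChrom <- map$tgtChrom
  mcols(src)$tgtStart <- map$tgtStart
  mcols(src)$tgtEnd <- map$tgtEnd
  src
}

#' Categorize DHSs by cross-species conservation
#'
#' A DHS with no orthology record is `unalignable`; a mapped DHS whose
#' target interval overlaps a partner-species DHS by at least
#' `minOverlap` bp is `shared`; any other mapped DHS is `diverged`
#' (orthologous sequence present but not a DHS in the partner species).
#' When several orthology records overlap a DHS, the one with the
#' largest source overlap is used (split mappings collapse to the
#' largest block).
#'
#' @param dhs GRanges of DHSs (named).
#' @param orthoMap data.frame with columns srcChrom/srcStart/srcEnd/
#'   tgtChrom/tgtStart/tgtEnd (1-based closed; see
#'   [readOrthologyMap()]).
#' @param partnerDhs GRanges of partner-species DHSs (target
#'   coordinates).
#' @param minOverlap minimum target overlap in bp (default 25).
#' @return factor along `dhs` with levels shared, diverged, unalignable,
#'   named by DHS id.
#' @export
categorizeConservation <- function(dhs, orthoMap, partnerDhs,
                                   minOverlap = 25) {
  cat3 <- rep("unalignable", length(dhs))
  if (nrow(orthoMap)) {
    src <- .orthoGRanges(orthoMap)
    ov <- findOverlaps(dhs, src, ignore.strand = TRUE)
    if (length(ov)) {
      ovBp <- width(pintersect(dhs[queryHits(ov)], src[subjectHits(ov)],
                               ignore.strand = TRUE))
      ## keep the largest-overlap record per DHS
      ord <- order(queryHits(ov), -ovBp)
      first <- !duplicated(queryHits(ov)[ord])
      qi <- queryHits(ov)[ord][first]
      si <- subjectHits(ov)[ord][first]
      tgt <- GRanges(mcols(src)$tgtChrom[si],
                     IRanges(mcols(src)$tgtStart[si],
                             mcols(src)$tgtEnd[si]))
      shared <- IRanges::overlapsAny(tgt, partnerDhs,
                                     minoverlap = minOverlap,
                                     ignore.strand = TRUE)
      cat3[qi] <- ifelse(shared, "shared", "diverged")
    }
  }
  out <- factor(cat3, levels = c("shared", "diverged", "unalignable"))
  names(out) <- names(dhs)
  out
}

#' Conservation category distribution per region
#'
#' @param recordsPerRegion named list of category factors (one per
#'   region, as returned by [categorizeConservation()]). Empty regions
#'   are dropped with a warning.
#' @return list with `counts` (region x category integer matrix) and
#'   `proportions` (rows summing to 1).
#' @export
categoryDistribution <- function(recordsPerRegion) {
  stopifnot(length(recordsPerRegion) >= 1)
  keep <- vapply(recordsPerRegion, length, integer(1)) > 0
  if (!all(keep))
    warning("empty region(s) dropped: ",
            paste(names(recordsPerRegion)[!keep], collapse = ", "))
  recordsPerRegion <- recordsPerRegion[keep]
  lv <- c("shared", "diverged", "unalignable")
  counts <- t(vapply(recordsPerRegion,
                     function(r) table(factor(r, levels = lv)),
                     numeric(3)))
  colnames(counts) <- lv
  props <- counts / rowSums(counts)
  list(counts = counts, proportions = props)
}

#' Pairwise chi-squared comparison of category distributions
#'
#' Pearson chi-squared (no continuity correction) on the 2 x 3
#' contingency table of each pair of regions; df = 2 per pair. Low
#' expected counts trigger the usual approximation warning but are
#' computed anyway.
#'
#' @param counts region x category count matrix.
#' @return symmetric matrix of p-values with unit diagonal.
#' @export
pairwiseChisq <- function(counts) {
  n <- nrow(counts)
  nm <- rownames(counts)
  p <- matrix(1, n, n, dimnames = list(nm, nm))
  if (n < 2) return(p)
  for (a in seq_len(n - 1)) {
    for (b in seq((a + 1), n)) {
      tab <- counts[c(a, b), , drop = FALSE]
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      pv <- if (ncol(tab) < 2 || all(tab[1, ] == tab[2, ])) {
        1  # identical (or single-category) rows: statistic 0
      } else {
        chisq.test(tab, correct = FALSE)$p.value
      }
      p[a, b] <- p[b, a] <- pv
    }
  }
  p
}
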