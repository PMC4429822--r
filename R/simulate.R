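## Synthetic DNase-seq study generator: planted DHSs with temporal
## archetypes, cleavage tags, ChIP peak sets, motif hit tables and
## orthology maps, all with known ground truth.

#' Construct a synthetic-study configuration
#'
#' @param nChroms number of chromosomes.
#' @param chromLength chromosome length in bp.
#' @param nTrueDhs number of planted DHSs.
#' @param dhsWidth DHS width in bp.
#' @param archetypeMix named proportions over the temporal archetypes
#'   early/mid/late/constitutive; must sum to 1.
#' @param enrichmentFold in-DHS over background per-bp cleavage rate at
#'   archetype weight 1. Must be >= 1.
#' @param depth tags per sample.
#' @param stages ordered stage labels.
#' @param nTss number of synthetic transcription start sites.
#' @param seed integer seed fixing the planted truth.
#' @return a [SimConfig].
#' @examples
#' cfg <- SimConfig(nChroms = 1, chromLength = 2e5, nTrueDhs = 40,
#'                  depth = 5e4, seed = 7)
#' @export
SimConfig <- function(nChroms = 2, chromLength = 5e6, nTrueDhs = 2000,
                      dhsWidth = 300,
                      archetypeMix = c(early = 0.25, mid = 0.25,
                                       late = 0.25, constitutive = 0.25),
                      enrichmentFold = 10, depth = 1e6,
                      stages = c("P0", "P7", "Adult"), nTss = 300,
                      seed = 1) {
  new("SimConfig", nChroms = as.integer(nChroms),
      chromLength = as.integer(chromLength),
      nTrueDhs = as.integer(nTrueDhs), dhsWidth = as.integer(dhsWidth),
      archetypeMix = archetypeMix, enrichmentFold = enrichmentFold,
      depth = as.numeric(depth), stages = stages,
      nTss = as.integer(nTss), seed = as.integer(seed))
}

#' Per-stage cleavage weight of each temporal archetype
#'
#' Relative cleavage-rate multipliers of the four archetypes (rows
#' early, mid, late, constitutive) across the ordered stages (columns).
#'
#' @param stages ordered stage labels used as column names.
#' @return a 4 x length(stages) numeric matrix.
#' @export
archetypeWeights <- function(stages = c("P0", "P7", "Adult")) {
  w <- .ARCHETYPE_WEIGHTS
  colnames(w) <- stages
  w
}

## Place n non-overlapping intervals of width w on a chromosome of length
## L, separated by at least `gap` bp. Deterministic given the RNG state.
.placeIntervals <- function(n, w, L, gap = 1000L) {
  free <- L - n * (w + gap)
  if (free < 0)
    stop("intervals do not fit: reduce count or width")
  offs <- sort(sample.int(free + 1L, n, replace = TRUE)) - 1L
  starts <- offs + (seq_len(n) - 1L) * (w + gap) + gap %/% 2L + 1L
  IRanges(start = starts, width = w)
}

#' Draw the planted ground truth of a synthetic study
#'
#' Places pairwise non-overlapping DHS intervals on the synthetic genome,
#' assigns each a temporal archetype drawn from the configured mix, and
#' scatters stranded TSS records. The truth is a deterministic function
#' of the configuration (including its seed).
#'
#' @param config a [SimConfig].
#' @return a [SimTruth].
#' @export
simulateTruth <- function(config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(config@seed)
  chroms <- paste0("chr", seq_len(config@nChroms))
  ## spread DHSs across chromosomes as evenly as possible
  per <- rep(config@nTrueDhs %/% config@nChroms, config@nChroms)
  extra <- config@nTrueDhs %% config@nChroms
  if (extra) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  irl <- lapply(per, .placeIntervals, w = config@dhsWidth,
                L = config@chromLength)
  dhs <- GRanges(rep(chroms, per), do.call(c, irl),
                 seqlengths = setNames(rep(config@chromLength,
                                           config@nChroms), chroms))
  arch <- sample(names(config@archetypeMix), length(dhs), replace = TRUE,
                 prob = config@archetypeMix)
  w <- archetypeWeights(config@stages)
  inten <- w[arch, , drop = FALSE]
  mcols(dhs)$archetype <- arch
  for (s in config@stages) mcols(dhs)[[paste0("w_", s)]] <- inten[, s]
  names(dhs) <- sprintf("trueDHS_%05d", seq_along(dhs))

  tssPos <- sample.int(config@chromLength, config@nTss, replace = TRUE)
  tssChr <- sample(chroms, config@nTss, replace = TRUE)
  tss <- GRanges(tssChr, IRanges(tssPos, width = 1L),
                 strand = sample(c("+", "-"), config@nTss, replace = TRUE))
  seqlengths(tss) <- seqlengths(dhs)[seqlevels(tss)]
  mcols(tss)$gene <- sprintf("gene_%04d", seq_along(tss))
  tss <- sort(tss, ignore.strand = TRUE)
  new("SimTruth", config = config, dhs = dhs, tss = tss)
}

## Map uniform draws over the concatenated complement of `dhs` back onto
## genomic coordinates. gapStarts/gapWidths describe the complement.
.complementGaps <- function(dhs, config) {
  chroms <- paste0("chr", seq_len(config@nChroms))
  genome <- GRanges(chroms, IRanges(1L, config@chromLength))
  seqlengths(genome) <- setNames(rep(config@chromLength, config@nChroms),
                                 chroms)
  GenomicRanges::setdiff(genome, dhs, ignore.strand = TRUE)
}

#' Simulate a cleavage TagSet for one stage
#'
#' Emits exactly `depth` width-1 cleavage tags. Background tags are
#' uniform over the genome outside planted DHSs; within a DHS the per-bp
#' rate is the background rate times `enrichmentFold` times the DHS
#' archetype's weight at the requested stage. Identical
#' (config, stage, seed) reproduce identical output.
#'
#' @param config a [SimConfig].
#' @param stage one of `config`'s stage labels.
#' @param truth optional precomputed [SimTruth] (recomputed from `config`
#'   when missing).
#' @param seed tag-level seed; defaults to `config@seed` offset by the
#'   stage index so stages are independent.
#' @return a [TagSet] with `sampleId` `"<stage>"`.
#' @export
simulateTags <- function(config, stage, truth = NULL, seed = NULL) {
  stopifnot(is(config, "SimConfig"))
  if (!stage %in% config@stages) stop("unknown stage: ", stage)
  if (is.null(truth)) truth <- simulateTruth(config)
  if (is.null(seed))
    seed <- config@seed + 1000L * match(stage, config@stages)
  set.seed(as.integer(seed))

  dhs <- truth@dhs
  wStage <- mcols(dhs)[[paste0("w_", stage)]]
  dhsWeight <- as.numeric(width(dhs)) * config@enrichmentFold * wStage
  gaps <- .complementGaps(dhs, config)
  bgLen <- sum(as.numeric(width(gaps)))
  probs <- c(dhsWeight, bgLen)
  expIn <- config@depth * dhsWeight / sum(probs)
  if (mean(expIn) < 1)
    warning("expected in-DHS tag count < 1 per DHS at this depth")

  counts <- as.vector(stats::rmultinom(1, size = config@depth,
                                       prob = probs))
  nDhs <- length(dhs)
  nBg <- counts[nDhs + 1L]
  cnt <- counts[seq_len(nDhs)]

  ## in-DHS tags: uniform within each planted interval
  idx <- rep.int(seq_len(nDhs), cnt)
  inPos <- start(dhs)[idx] +
    (sample.int(config@dhsWidth, sum(cnt), replace = TRUE) - 1L)
  inChr <- as.character(seqnames(dhs))[idx]

  ## background tags: uniform over the concatenated complement
  gw <- as.numeric(width(gaps))
  cum <- cumsum(gw)
  u <- ceiling(runif(nBg) * bgLen)
  u[u < 1] <- 1
  gi <- findInterval(u - 1, cum) + 1L
  off <- u - c(0, cum)[gi] - 1
  bgPos <- start(gaps)[gi] + as.integer(off)
  bgChr <- as.character(seqnames(gaps))[gi]

  pos <- c(inPos, bgPos)
  chr <- c(inChr, bgChr)
  strand <- sample(c("+", "-"), length(pos), replace = TRUE)
  gr <- GRanges(chr, IRanges(pos, width = 1L), strand = strand)
  seqlengths(gr) <- seqlengths(dhs)[seqlevels(gr)]
  gr <- sort(gr, ignore.strand = TRUE)
  new("TagSet", sampleId = stage, tags = gr)
}

#' Simulate a ChIP-seq peak set with controlled DHS overlap
#'
#' A fraction of peaks (round-half-to-even of `overlapFraction * nPeaks`)
#' is placed so each intersects one planted DHS by at least
#' `minOverlap` bp; the remainder is placed entirely outside all planted
#' DHSs.
#'
#' @param truth a [SimTruth].
#' @param overlapFraction proportion of peaks that must hit a DHS.
#' @param nPeaks total peaks to emit.
#' @param peakWidth peak width in bp.
#' @param minOverlap guaranteed overlap of the hitting peaks, in bp.
#' @param seed RNG seed.
#' @return GRanges of peaks with logical metadata column `overlapsTruth`.
#' @export
simulateChipPeaks <- function(truth, overlapFraction, nPeaks,
                              peakWidth = 200, minOverlap = 75, seed = 1) {
  stopifnot(is(truth, "SimTruth"),
            overlapFraction >= 0, overlapFraction <= 1)
  cfg <- truth@config
  if (min(peakWidth, cfg@dhsWidth) < minOverlap)
    stop("peak or DHS width too small to guarantee ", minOverlap,
         " bp overlap")
  nOv <- round(overlapFraction * nPeaks)   # round-half-to-even
  if (nOv > length(truth@dhs))
    stop("more overlapping peaks requested than planted DHSs")
  set.seed(as.integer(seed))

  hit <- sample.int(length(truth@dhs), nOv)
  d <- truth@dhs[hit]
  ## centre peaks on their DHS: guarantees min(peakWidth, dhsWidth) overlap
  centre <- start(d) + width(d) %/% 2L
  ovPeaks <- GRanges(seqnames(d),
                     IRanges(centre - peakWidth %/% 2L, width = peakWidth))

  nBg <- nPeaks - nOv
  if (nBg > 0) {
    gaps <- .complementGaps(truth@dhs, cfg)
    gaps <- gaps[width(gaps) >= peakWidth + 2L]
    avail <- width(gaps) - peakWidth - 1L   # keep >= 1 bp clear of DHSs
    cum <- cumsum(as.numeric(avail))
    u <- sample(cum[length(cum)], nBg)
    gi <- findInterval(u - 1, cum) + 1L
    off <- as.integer(u - c(0, cum)[gi])
    bgPeaks <- GRanges(seqnames(gaps)[gi],
                       IRanges(start(gaps)[gi] + off, width = peakWidth))
  } else {
    bgPeaks <- GRanges()
  }
  peaks <- c(ovPeaks, bgPeaks)
  mcols(peaks)$overlapsTruth <- rep(c(TRUE, FALSE), c(nOv, nBg))
  names(peaks) <- sprintf("peak_%05d", seq_along(peaks))
  seqlengths(peaks) <- seqlengths(truth@dhs)[seqlevels(peaks)]
  sort(peaks, ignore.strand = TRUE)
}

#' Simulate a motif hit table with controlled per-archetype enrichment
#'
#' For each transcription factor, a planted DHS carries a motif hit with
#' probability `backgroundRate` outside the factor's target archetype and
#' `min(1, backgroundRate * odds)` inside it. Each hit is an interval
#' inside its DHS with a match p-value below the scan threshold.
#'
#' @param truth a [SimTruth].
#' @param tfTargets data.frame with columns `tf`, `archetype`, `odds`
#'   (odds >= 1; archetype NA means no target, pure background).
#' @param backgroundRate per-DHS background presence probability.
#' @param pThreshold motif-scan match p-value threshold; emitted hits lie
#'   strictly below it.
#' @param motifWidth hit width in bp.
#' @param seed RNG seed.
#' @return list with `hits` (GRanges with `tf`, `motifId`, `matchP`),
#'   `presence` (DHS x TF logical matrix, the ground truth) and
#'   `pThreshold`.
#' @export
simulateMotifHits <- function(truth, tfTargets, backgroundRate = 0.05,
                              pThreshold = 1e-4, motifWidth = 12,
                              seed = 1) {
  stopifnot(is(truth, "SimTruth"), all(tfTargets$odds >= 1))
  set.seed(as.integer(seed))
  dhs <- truth@dhs
  arch <- mcols(dhs)$archetype
  nD <- length(dhs)
  presence <- matrix(FALSE, nD, nrow(tfTargets),
                     dimnames = list(names(dhs), tfTargets$tf))
  for (i in seq_len(nrow(tfTargets))) {
    pIn <- backgroundRate * tfTargets$odds[i]
    if (pIn > 1) {
      warning("backgroundRate * odds > 1 for ", tfTargets$tf[i],
              "; clamped to 1")
      pIn <- 1
    }
    p <- rep(backgroundRate, nD)
    if (!is.na(tfTargets$archetype[i]))
      p[arch == tfTargets$archetype[i]] <- pIn
    presence[, i] <- rbinom(nD, 1L, p) == 1L
  }
  ij <- which(presence, arr.ind = TRUE)
  if (nrow(ij)) {
    d <- dhs[ij[, 1L]]
    maxOff <- width(d) - motifWidth
    off <- floor(runif(nrow(ij)) * (maxOff + 1))
    hits <- GRanges(seqnames(d),
                    IRanges(start(d) + as.integer(off), width = motifWidth))
    mcols(hits)$tf <- tfTargets$tf[ij[, 2L]]
    mcols(hits)$motifId <- paste0(tfTargets$tf[ij[, 2L]], "_M1")
    mcols(hits)$matchP <- runif(nrow(ij)) * pThreshold
    seqlengths(hits) <- seqlengths(dhs)[seqlevels(hits)]
    hits <- sort(hits, ignore.strand = TRUE)
  } else {
    hits <- GRanges(tf = character(), motifId = character(),
                    matchP = numeric())
  }
  list(hits = hits, presence = presence, pThreshold = pThreshold)
}

## split n into integer counts proportional to `props` (largest-remainder
## apportionment; exact when n * props are integers)
.apportion <- function(n, props) {
  raw <- n * props / sum(props)
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  setNames(as.integer(cnt), names(props))
}

#' Simulate a cross-species orthology map with controlled conservation
#'
#' Partitions the planted DHSs into shared / diverged / unalignable in the
#' exact proportions given (largest-remainder rounding). Shared and
#' diverged DHSs receive a mapped partner-genome interval; shared ones
#' additionally receive a partner-species DHS inside the mapped interval.
#'
#' @param truth a [SimTruth].
#' @param proportions named proportions over shared/diverged/unalignable;
#'   must sum to 1.
#' @param seed RNG seed.
#' @return list with `map` (data.frame srcChrom/srcStart/srcEnd/
#'   tgtChrom/tgtStart/tgtEnd, 1-based closed), `partnerDhs` (GRanges on
#'   the partner genome) and `categories` (factor named by DHS id — the
#'   ground truth).
#' @export
simulateOrthology <- function(truth,
                              proportions = c(shared = 0.6, diverged = 0.3,
                                              unalignable = 0.1),
                              seed = 1) {
  stopifnot(is(truth, "SimTruth"))
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must sum to 1")
  set.seed(as.integer(seed))
  dhs <- truth@dhs
  n <- length(dhs)
  cnt <- .apportion(n, proportions[c("shared", "diverged", "unalignable")])
  cat3 <- sample(rep(names(cnt), cnt))
  categories <- factor(cat3, levels = c("shared", "diverged", "unalignable"))
  names(categories) <- names(dhs)

  mapped <- which(categories != "unalignable")
  if (length(mapped)) {
    w <- width(dhs)[mapped]
    tgtStart <- cumsum(c(1L, utils::head(w + 1000L, -1L)))
    map <- data.frame(
      srcChrom = as.character(seqnames(dhs))[mapped],
      srcStart = start(dhs)[mapped], srcEnd = end(dhs)[mapped],
      tgtChrom = "pchr1", tgtStart = tgtStart,
      tgtEnd = tgtStart + w - 1L,
      stringsAsFactors = FALSE)
  } else {
    map <- data.frame(srcChrom = character(), srcStart = integer(),
                      srcEnd = integer(), tgtChrom = character(),
                      tgtStart = integer(), tgtEnd = integer())
  }
  sharedInMap <- categories[mapped] == "shared"
  partnerDhs <- GRanges(map$tgtChrom[sharedInMap],
                        IRanges(map$tgtStart[sharedInMap],
                                map$tgtEnd[sharedInMap]))
  list(map = map, partnerDhs = sort(partnerDhs), categories = categories)
}

#' Simulate a transformed accessibility matrix with planted archetypes
#'
#' Draws DHS temporal profiles directly on the transformed 0-10 scale:
#' each row is its archetype's weight vector scaled to a maximum of 10
#' plus Gaussian noise (truncated at 0). Used to study the clustering
#' stage in isolation from the tag-level pipeline.
#'
#' @param nDhs rows to draw.
#' @param archetypeMix named archetype proportions.
#' @param noiseSd Gaussian noise standard deviation on the 0-10 scale.
#' @param stages ordered stage labels (columns).
#' @param seed RNG seed.
#' @return list with `mat` (nDhs x stages matrix) and `archetype`
#'   (character ground-truth labels).
#' @export
simulateDensityMatrix <- function(nDhs = 5000,
                                  archetypeMix = c(early = 0.25, mid = 0.25,
                                                   late = 0.25,
                                                   constitutive = 0.25),
                                  noiseSd = 0.5,
                                  stages = c("P0", "P7", "Adult"),
                                  seed = 1) {
  set.seed(as.integer(seed))
  w <- archetypeWeights(stages) * 10
  arch <- sample(names(archetypeMix), nDhs, replace = TRUE,
                 prob = archetypeMix)
  mat <- w[arch, , drop = FALSE] +
    matrix(rnorm(nDhs * length(stages), sd = noiseSd), nDhs)
  mat[mat < 0] <- 0
  rownames(mat) <- sprintf("DHS_%05d", seq_len(nDhs))
  list(mat = mat, archetype = arch)
}
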