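## Hotspot detection: windowed cut counting, binomial local-background
## p-values, significant-window merging, 150-bp peak calling, simulated
## random-read FDR calibration and the SPOT quality score.

#' Construct a TagSet
#'
#' @param gr GRanges of width-1 cleavage positions.
#' @param sampleId sample label.
#' @return a [TagSet].
#' @export
TagSet <- function(gr, sampleId = "sample") {
  new("TagSet", sampleId = sampleId, tags = gr)
}

#' Down-sample a TagSet without replacement
#'
#' Random sampling without replacement to a fixed target depth, so that
#' samples sequenced to different depths are compared at equal depth
#' before hotspot calling. The conventional full-scale target is 25
#' million tags.
#'
#' @param x a [TagSet].
#' @param targetDepth tags to retain; must not exceed `depth(x)`.
#' @param seed RNG seed.
#' @return a [TagSet] of exactly `targetDepth` tags.
#' @export
downsampleTags <- function(x, targetDepth = 25e6, seed = 1) {
  stopifnot(is(x, "TagSet"))
  d <- depth(x)
  if (targetDepth > d)
    stop("targetDepth (", targetDepth, ") exceeds sample depth (", d, ")")
  set.seed(as.integer(seed))
  idx <- sample.int(d, targetDepth)
  new("TagSet", sampleId = x@sampleId, tags = sort(x@tags[idx]))
}

#' Count cleavage tags in sliding windows
#'
#' Tags are summed within `windowLen`-bp windows placed every `step` bp
#' along each chromosome (a tag falls in a window when its 5' cut
#' position lies within the window span; strand is ignored). The
#' tags-per-million normalized density is stored alongside the raw count.
#'
#' @param x a [TagSet].
#' @param windowLen window length in bp (default 150).
#' @param step window step in bp (default 20).
#' @return a [CutTrack].
#' @export
countCuts <- function(x, windowLen = 150, step = 20) {
  stopifnot(is(x, "TagSet"))
  windowLen <- as.integer(windowLen); step <- as.integer(step)
  gr <- x@tags
  total <- length(gr)
  sl <- seqlengths(gr)
  chroms <- seqlevels(gr)[seqlevels(gr) %in% unique(as.character(seqnames(gr)))]
  if (total == 0L)
    return(new("CutTrack", sampleId = x@sampleId, windows = GRanges(),
               cuts = list(), totalTags = 0, windowLen = windowLen,
               step = step))
  cuts <- list()
  chrV <- character(); startV <- integer(); cntV <- integer()
  for (chr in chroms) {
    pos <- sort(start(gr)[as.character(seqnames(gr)) == chr])
    cuts[[chr]] <- pos
    L <- sl[chr]
    if (is.na(L)) L <- max(pos) + windowLen
    starts <- seq.int(1L, max(1L, L - windowLen + 1L), by = step)
    cnt <- findInterval(starts + windowLen - 1L, pos) -
      findInterval(starts - 1L, pos)
    chrV <- c(chrV, rep(chr, length(starts)))
    startV <- c(startV, starts)
    cntV <- c(cntV, cnt)
  }
  windows <- GRanges(chrV, IRanges(startV, width = windowLen))
  mcols(windows)$count <- cntV
  mcols(windows)$density <- cntV * 1e6 / total
  seqlengths(windows) <- sl[seqlevels(windows)]
  new("CutTrack", sampleId = x@sampleId, windows = windows, cuts = cuts,
      totalTags = total, windowLen = windowLen, step = step)
}

#' Upper-tail binomial window p-value against a local background
#'
#' Probability of observing at least `windowCount` tags in a window of
#' `windowLen` bp when the `localTotal` tags of the surrounding
#' `backgroundLen`-bp background fall uniformly:
#' P(X >= windowCount), X ~ Binomial(localTotal, windowLen/backgroundLen).
#'
#' @param windowCount tags in the window.
#' @param localTotal tags in the local background (includes the window).
#' @param windowLen window length in bp.
#' @param backgroundLen local background length in bp; must exceed
#'   `windowLen`.
#' @return the upper-tail p-value (vectorized over the first two
#'   arguments).
#' @export
binomialWindowPvalue <- function(windowCount, localTotal,
                                 windowLen = 150, backgroundLen = 50000) {
  if (any(backgroundLen <= windowLen))
    stop("backgroundLen must exceed windowLen")
  if (any(localTotal < windowCount))
    stop("localTotal must be >= windowCount")
  pbinom(windowCount - 1, localTotal, windowLen / backgroundLen,
         lower.tail = FALSE)
}

## Per-window binomial p-values of a track against the local background:
## localTotal = tags within backgroundLen centred on each window (clipped
## at chromosome ends; the success probability uses the clipped length).
.windowPvalues <- function(track, backgroundLen = 50000) {
  w <- track@windows
  p <- numeric(length(w))
  half <- backgroundLen %/% 2L
  chrAll <- as.character(seqnames(w))
  for (chr in names(track@cuts)) {
    sel <- chrAll == chr
    if (!any(sel)) next
    pos <- track@cuts[[chr]]
    st <- start(w)[sel]; en <- end(w)[sel]
    centre <- st + track@windowLen %/% 2L
    L <- seqlengths(w)[chr]
    if (is.na(L)) L <- max(en)
    lo <- pmax(1L, pmin(centre - half, st))
    hi <- pmax(en, pmin(L, centre + half - 1L))
    localTotal <- findInterval(hi, pos) - findInterval(lo - 1L, pos)
    effLen <- hi - lo + 1L
    cnt <- mcols(w)$count[sel]
    p[sel] <- pbinom(cnt - 1, localTotal, track@windowLen / effLen,
                     lower.tail = FALSE)
  }
  p
}

## merge significant windows (gap <= step) into hotspot intervals
.mergeSignificant <- function(windows, p, threshold, step) {
  sig <- which(p <= threshold)
  if (!length(sig)) return(GRanges())
  GenomicRanges::reduce(windows[sig], min.gapwidth = step + 1L)
}

#' Call hotspots from a windowed cut track
#'
#' Windows whose binomial local-background p-value is at or below
#' `threshold` are merged (when overlapping or separated by at most one
#' step) into maximal hotspot intervals. Each hotspot carries its tag
#' count and the minimum window p-value inside it.
#'
#' @param track a [CutTrack].
#' @param threshold p-value cutoff (typically set by
#'   [calibrateThreshold()]).
#' @param backgroundLen local background length in bp.
#' @return GRanges of hotspots with metadata columns `tagCount`,
#'   `pValue` and `score` (-log10 p capped at 1000).
#' @export
callHotspots <- function(track, threshold = 1e-4, backgroundLen = 50000) {
  stopifnot(is(track, "CutTrack"))
  if (length(track@windows) == 0L) return(GRanges())
  p <- .windowPvalues(track, backgroundLen)
  hs <- .mergeSignificant(track@windows, p, threshold, track@step)
  if (!length(hs)) return(hs)
  sig <- which(p <= threshold)
  ov <- findOverlaps(track@windows[sig], hs)
  minP <- tapply(p[sig][queryHits(ov)], subjectHits(ov), min)
  mcols(hs)$pValue <- as.numeric(minP[as.character(seq_along(hs))])
  chrAll <- as.character(seqnames(hs))
  cnt <- integer(length(hs))
  for (chr in unique(chrAll)) {
    sel <- chrAll == chr
    pos <- track@cuts[[chr]]
    cnt[sel] <- findInterval(end(hs)[sel], pos) -
      findInterval(start(hs)[sel] - 1L, pos)
  }
  mcols(hs)$tagCount <- cnt
  mcols(hs)$score <- pmin(1000, round(-log10(pmax(mcols(hs)$pValue,
                                                  1e-300))))
  names(hs) <- sprintf("hotspot_%05d", seq_along(hs))
  hs
}

## indices of run-maxima of a numeric vector (centre of each plateau run)
.localMaxima <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(r$values)
  left <- c(-Inf, r$values[-n])
  right <- c(r$values[-1L], -Inf)
  isMax <- r$values > left & r$values > right
  mid <- starts + (r$lengths - 1L) %/% 2L
  mid[isMax]
}

#' Call fixed-width peaks inside hotspots
#'
#' Each hotspot is scanned for local maxima of the window cut counts;
#' `windowLen`-bp peaks centred on the maxima are emitted greedily in
#' decreasing count order, skipping any maximum whose peak would overlap
#' an already-emitted peak. Every hotspot yields at least one peak.
#' Peaks are clipped (shifted) to chromosome bounds when a summit lies
#' near an end.
#'
#' @param hotspots GRanges from [callHotspots()].
#' @param track the [CutTrack] the hotspots were called on.
#' @return GRanges of peaks with metadata columns `summit`, `density`
#'   and `parentHotspot`.
#' @export
callPeaks <- function(hotspots, track) {
  stopifnot(is(track, "CutTrack"))
  if (!length(hotspots)) return(GRanges())
  w <- track@windows
  wl <- track@windowLen
  halfLo <- wl %/% 2L
  halfHi <- wl - halfLo - 1L
  ov <- findOverlaps(w, hotspots, type = "within")
  sl <- seqlengths(w)
  out <- vector("list", length(hotspots))
  for (h in seq_along(hotspots)) {
    wi <- queryHits(ov)[subjectHits(ov) == h]
    if (!length(wi)) { # degenerate: fall back to windows overlapping at all
      wi <- queryHits(findOverlaps(w, hotspots[h]))
    }
    wi <- wi[order(start(w)[wi])]
    cnt <- mcols(w)$count[wi]
    mx <- .localMaxima(cnt)
    if (!length(mx)) mx <- which.max(cnt)
    mx <- mx[order(cnt[mx], decreasing = TRUE)]
    chr <- as.character(seqnames(hotspots))[h]
    L <- sl[chr]
    taken <- IRanges()
    for (m in mx) {
      summit <- start(w)[wi[m]] + halfLo
      st <- summit - halfLo
      if (!is.na(L) && st + wl - 1L > L) st <- L - wl + 1L
      if (st < 1L) st <- 1L
      pk <- IRanges(st, width = wl)
      if (length(taken) && any(IRanges::overlapsAny(pk, taken))) next
      taken <- c(taken, pk)
      out[[h]] <- rbind(out[[h]],
                        data.frame(chr = chr, start = st, summit = summit,
                                   density = mcols(w)$density[wi[m]],
                                   parent = h))
    }
  }
  df <- do.call(rbind, out)
  pk <- GRanges(df$chr, IRanges(df$start, width = wl))
  mcols(pk)$summit <- df$summit
  mcols(pk)$density <- df$density
  mcols(pk)$parentHotspot <- names(hotspots)[df$parent]
  seqlengths(pk) <- sl[seqlevels(pk)]
  sort(pk, ignore.strand = TRUE)
}

## uniform random TagSet over mappable regions at a given depth
.nullTags <- function(nTags, mappable, sampleId = "null") {
  gw <- as.numeric(width(mappable))
  cum <- cumsum(gw)
  u <- ceiling(runif(nTags) * cum[length(cum)])
  u[u < 1] <- 1
  gi <- findInterval(u - 1, cum) + 1L
  off <- as.integer(u - c(0, cum)[gi] - 1)
  gr <- GRanges(seqnames(mappable)[gi],
                IRanges(start(mappable)[gi] + off, width = 1L),
                strand = sample(c("+", "-"), nTags, replace = TRUE))
  seqlengths(gr) <- seqlengths(mappable)[seqlevels(gr)]
  new("TagSet", sampleId = sampleId, tags = sort(gr, ignore.strand = TRUE))
}

#' Estimate the FDR of hotspot calls by simulated random reads
#'
#' Generates `nReplicates` simulated tag sets of uniform random reads at
#' equal sequencing depth over the mappable genome, scans each with the
#' identical count / p-value / merge chain, and reports
#' `fdrEstimate = mean simulated hotspot count / observed hotspot count`.
#'
#' @param x a [TagSet].
#' @param mappable GRanges of mappable regions the null reads are placed
#'   on.
#' @param threshold p-value cutoff applied to both observed and null
#'   scans.
#' @param seed RNG seed for the null tag sets.
#' @param nReplicates number of simulated null datasets.
#' @param windowLen,step,backgroundLen scan parameters, as in
#'   [countCuts()] and [callHotspots()].
#' @return an [FdrCalibration].
#' @export
estimateFdr <- function(x, mappable, threshold = 1e-4, seed = 1,
                        nReplicates = 1, windowLen = 150, step = 20,
                        backgroundLen = 50000) {
  stopifnot(is(x, "TagSet"), length(mappable) > 0)
  track <- countCuts(x, windowLen, step)
  obsHs <- callHotspots(track, threshold, backgroundLen)
  nObs <- length(obsHs)
  set.seed(as.integer(seed))
  nullCounts <- vapply(seq_len(nReplicates), function(i) {
    nt <- .nullTags(depth(x), mappable)
    ntr <- countCuts(nt, windowLen, step)
    length(.mergeSignificant(ntr@windows,
                             .windowPvalues(ntr, backgroundLen),
                             threshold, ntr@step))
  }, numeric(1))
  if (nObs == 0L) {
    warning("no observed hotspots; FDR estimate undefined, reported as 1")
    fdr <- 1.0
  } else {
    fdr <- mean(nullCounts) / nObs
  }
  new("FdrCalibration", threshold = threshold,
      observedHotspots = nObs, simulatedHotspots = mean(nullCounts),
      fdrEstimate = fdr,
      spotObserved = if (nObs) spotScore(x, obsHs) else 0,
      nullCounts = nullCounts,
      nReplicates = as.integer(nReplicates), seed = as.integer(seed))
}

#' Calibrate the detection threshold to a target FDR
#'
#' Bisection search over -log10 p in [2, 12] (25 iterations) for the
#' most permissive threshold whose simulated-null FDR estimate is below
#' `targetFdr`. Observed and null window p-values are computed once and
#' reused across iterations, so the search cost is dominated by the
#' `nReplicates` null scans.
#'
#' @param x a [TagSet].
#' @param mappable GRanges of mappable regions.
#' @param targetFdr target false discovery rate (default 0.01, i.e. 1%).
#' @param seed RNG seed for the null tag sets.
#' @param nReplicates number of simulated null datasets.
#' @param windowLen,step,backgroundLen scan parameters.
#' @param logRange search range of -log10 p.
#' @param iterations bisection iterations.
#' @return an [FdrCalibration] at the calibrated threshold.
#' @export
calibrateThreshold <- function(x, mappable, targetFdr = 0.01, seed = 1,
                               nReplicates = 1, windowLen = 150,
                               step = 20, backgroundLen = 50000,
                               logRange = c(2, 12), iterations = 25) {
  stopifnot(is(x, "TagSet"), length(mappable) > 0)
  track <- countCuts(x, windowLen, step)
  pObs <- .windowPvalues(track, backgroundLen)
  set.seed(as.integer(seed))
  nullScans <- lapply(seq_len(nReplicates), function(i) {
    nt <- .nullTags(depth(x), mappable)
    ntr <- countCuts(nt, windowLen, step)
    list(windows = ntr@windows, p = .windowPvalues(ntr, backgroundLen))
  })
  fdrAt <- function(thr) {
    nObs <- length(.mergeSignificant(track@windows, pObs, thr, track@step))
    nNull <- vapply(nullScans, function(s)
      length(.mergeSignificant(s$windows, s$p, thr, track@step)),
      numeric(1))
    mean(nNull) / max(nObs, 1L)
  }
  lo <- logRange[1]; hi <- logRange[2]
  for (i in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    if (fdrAt(10^(-mid)) < targetFdr) hi <- mid else lo <- mid
  }
  thr <- 10^(-hi)
  obsHs <- callHotspots(track, thr, backgroundLen)
  nNull <- vapply(nullScans, function(s)
    length(.mergeSignificant(s$windows, s$p, thr, track@step)), numeric(1))
  nObs <- length(obsHs)
  new("FdrCalibration", threshold = thr, observedHotspots = nObs,
      simulatedHotspots = mean(nNull),
      fdrEstimate = mean(nNull) / max(nObs, 1L),
      spotObserved = if (nObs) spotScore(x, obsHs) else 0,
      nullCounts = nNull,
      nReplicates = as.integer(nReplicates), seed = as.integer(seed))
}

#' SPOT score: signal portion of tags
#'
#' Fraction of a sample's tags that fall inside its hotspot intervals; a
#' library-quality metric in [0, 1].
#'
#' @param x the [TagSet] the hotspots were called on.
#' @param hotspots GRanges of hotspots.
#' @return proportion of tags inside hotspots.
#' @export
spotScore <- function(x, hotspots) {
  stopifnot(is(x, "TagSet"))
  d <- depth(x)
  if (d == 0L) stop("SPOT score undefined at depth 0")
  sum(IRanges::overlapsAny(x@tags, hotspots, ignore.strand = TRUE)) / d
}
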