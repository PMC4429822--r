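test_that("downsampling returns exact depth without replacement", {
  cfg <- tinyConfig()
  ts <- simulateTags(cfg, "P0")
  sub <- downsampleTags(ts, 40000, seed = 1)
  expect_equal(depth(sub), 40000)
  ## multiset inclusion: every downsampled position count <= original
  orig <- table(paste(seqnames(tags(ts)), start(tags(ts))))
  kept <- table(paste(seqnames(tags(sub)), start(tags(sub))))
  expect_true(all(kept <= orig[names(kept)]))
  ## identity at equal depth
  same <- downsampleTags(ts, depth(ts), seed = 2)
  expect_identical(sort(start(tags(same))), sort(start(tags(ts))))
  ## different seeds: same depth, different subsets
  s1 <- downsampleTags(ts, 40000, seed = 3)
  s2 <- downsampleTags(ts, 40000, seed = 4)
  expect_equal(depth(s1), depth(s2))
  expect_false(identical(start(tags(s1)), start(tags(s2))))
  expect_error(downsampleTags(ts, depth(ts) + 1), "exceeds")
})

test_that("window counting matches brute-force enumeration", {
  L <- 10000L
  ## single interior tags at several grid phases
  for (p in c(500L, 507L, 510L, 519L, 520L)) {
    ts <- tagSetAt(p, chromLength = L)
    track <- countCuts(ts)
    w <- cutWindows(track)
    containing <- bruteWindowStarts(p, L)
    expect_equal(start(w)[mcols(w)$count > 0], containing)
    expect_true(all(mcols(w)$count[mcols(w)$count > 0] == 1L))
    ## total over windows equals the brute-force sum
    expect_equal(sum(mcols(w)$count), length(containing))
  }
  ## stacked tags: every window containing the position sees all of them
  ts3 <- tagSetAt(rep(100L, 3), chromLength = L)
  w3 <- cutWindows(countCuts(ts3))
  hit <- start(w3) %in% bruteWindowStarts(100L, L)
  expect_true(all(mcols(w3)$count[hit] == 3L))
  expect_true(all(mcols(w3)$count[!hit] == 0L))
  ## normalized density is tags-per-million
  expect_equal(mcols(w3)$density, mcols(w3)$count * 1e6 / 3)
})

test_that("binomial window p-value matches the exact tail sum", {
  ## frozen arbitrary-precision value for the worked case
  ## P(X >= 5), X ~ Bin(200, 150/50000)
  expect_equal(binomialWindowPvalue(5, 200, 150, 50000),
               0.000379519995893668, tolerance = 1e-12)
  expect_equal(binomialWindowPvalue(0, 200, 150, 50000), 1)
  ## non-increasing in the window count
  p <- binomialWindowPvalue(0:30, 200, 150, 50000)
  expect_true(all(diff(p) <= 0))
  ## relative error vs explicit log-space tail summation on a grid
  grid <- expand.grid(cnt = c(1, 2, 5, 10, 25, 50),
                      tot = c(60, 500, 5000, 10000))
  for (i in seq_len(nrow(grid))) {
    cnt <- grid$cnt[i]; tot <- grid$tot[i]
    pr <- 150 / 50000
    exact <- sum(exp(lchoose(tot, cnt:tot) + (cnt:tot) * log(pr) +
                       (tot - cnt:tot) * log1p(-pr)))
    expect_lt(abs(binomialWindowPvalue(cnt, tot) - exact) / exact, 1e-3)
  }
  expect_error(binomialWindowPvalue(5, 200, 150, 100), "exceed")
  expect_error(binomialWindowPvalue(5, 4), ">=")
})

test_that("hotspot calling merges significant windows into maximal runs", {
  L <- 50000L
  ## a dense cluster of cuts: the hotspot is the union span of the
  ## brute-force containing windows
  spike <- rep(20001L, 60)
  bg <- seq.int(1L, L, by = 500L)  # faint uniform background
  ts <- tagSetAt(c(spike, bg), chromLength = L)
  track <- countCuts(ts)
  hs <- callHotspots(track, threshold = 1e-6)
  expect_length(hs, 1)
  containing <- bruteWindowStarts(20001L, L)
  expect_equal(start(hs), min(containing))
  expect_equal(end(hs), max(containing) + 149L)
  ## two clusters far apart give two hotspots
  ts2 <- tagSetAt(c(rep(10001L, 60), rep(40001L, 60), bg),
                  chromLength = L)
  hs2 <- callHotspots(countCuts(ts2), threshold = 1e-6)
  expect_length(hs2, 2)
  ## hotspots are pairwise non-overlapping
  expect_equal(length(GenomicRanges::reduce(hs2)), 2)
  ## uniform track: nothing passes a strict threshold
  hs0 <- callHotspots(countCuts(tagSetAt(bg, chromLength = L)),
                      threshold = 1e-10)
  expect_length(hs0, 0)
})

test_that("peak calling finds non-overlapping 150-bp peaks at local maxima", {
  L <- 60000L
  base <- unlist(lapply(seq(20001L, 20600L, by = 10L), rep, 4L))
  unimodal <- c(base, rep(20301L, 40))
  ts <- tagSetAt(unimodal, chromLength = L)
  track <- countCuts(ts)
  hs <- callHotspots(track, threshold = 1e-6)
  pk <- callPeaks(hs, track)
  expect_length(pk, 1)
  expect_equal(width(pk), 150)
  ## summit window contains the spike
  expect_true(start(pk) <= 20301 && 20301 <= end(pk))
  ## bimodal, modes 300 bp apart: two non-overlapping peaks
  bimodal <- c(base, rep(20201L, 40), rep(20501L, 40))
  ts2 <- tagSetAt(bimodal, chromLength = L)
  track2 <- countCuts(ts2)
  hs2 <- callHotspots(track2, threshold = 1e-6)
  pk2 <- callPeaks(hs2, track2)
  expect_length(pk2, 2)
  expect_equal(length(GenomicRanges::reduce(pk2)), 2)
  ## modes 100 bp apart: the second peak would overlap, one peak only
  close <- c(base, rep(20201L, 40), rep(20301L, 36))
  ts3 <- tagSetAt(close, chromLength = L)
  track3 <- countCuts(ts3)
  hs3 <- callHotspots(track3, threshold = 1e-6)
  pk3 <- callPeaks(hs3, track3)
  expect_length(pk3, 1)
  ## every peak lies within its parent hotspot
  expect_true(all(IRanges::overlapsAny(pk2, hs2, type = "within")))
})

test_that("peak calling is invariant to coordinate translation", {
  L <- 100000L
  pos <- c(rep(20001L, 50), rep(20501L, 50),
           seq(19001L, 22001L, by = 25L))
  shift <- 4000L  # a multiple of the window step keeps the grid aligned
  t1 <- countCuts(tagSetAt(pos, chromLength = L))
  t2 <- countCuts(tagSetAt(pos + shift, chromLength = L))
  h1 <- callHotspots(t1, 1e-6); h2 <- callHotspots(t2, 1e-6)
  p1 <- callPeaks(h1, t1); p2 <- callPeaks(h2, t2)
  expect_equal(start(h2), start(h1) + shift)
  expect_equal(start(p2), start(p1) + shift)
  expect_equal(mcols(p2)$summit, mcols(p1)$summit + shift)
})

test_that("SPOT score equals the brute-force in-hotspot tag fraction", {
  cfg <- tinyConfig(seed = 71)
  ts <- simulateTags(cfg, "P7")
  track <- countCuts(ts)
  hs <- callHotspots(track, threshold = 1e-5)
  s <- spotScore(ts, hs)
  inHs <- vapply(seq_len(depth(ts)), function(i) {
    p <- start(tags(ts))[i]
    any(start(hs) <= p & p <= end(hs))
  }, logical(1))
  expect_equal(s, mean(inHs))
  ## hotspots covering everything give 1
  expect_equal(spotScore(ts, genomeOf(cfg)), 1)
  expect_error(spotScore(TagSet(GRanges()), hs), "depth 0")
})

test_that("uniform random tags yield an FDR estimate near 1", {
  cfg <- SimConfig(nChroms = 1, chromLength = 5e5, nTrueDhs = 2,
                   depth = 5e4, seed = 81)
  mappable <- genomeOf(cfg)
  set.seed(81)
  nullTags <- TagSet(GRanges("chr1",
                             IRanges(sample.int(5e5, 5e4, replace = TRUE),
                                     width = 1),
                             strand = "+",
                             seqlengths = c(chr1 = 5e5)),
                     sampleId = "null")
  ## a permissive threshold keeps the hotspot counts large enough that
  ## the observed/null ratio is not dominated by Poisson noise
  cal <- estimateFdr(nullTags, mappable, threshold = 1e-2, seed = 9,
                     nReplicates = 20)
  expect_gt(fdrEstimate(cal), 0.5)
  expect_lt(fdrEstimate(cal), 2.0)
})

test_that("threshold calibration reaches the target FDR on planted truth", {
  cfg <- SimConfig(nChroms = 1, chromLength = 1e6, nTrueDhs = 200,
                   depth = 2e5, seed = 91)
  tr <- simulateTruth(cfg)
  ts <- simulateTags(cfg, "P7", truth = tr)
  cal <- calibrateThreshold(ts, genomeOf(cfg), targetFdr = 0.01,
                            seed = 10, nReplicates = 5)
  expect_lt(fdrEstimate(cal), 0.01)
  hs <- callHotspots(countCuts(ts), fdrThreshold(cal))
  empFdr <- mean(!IRanges::overlapsAny(hs, trueDhs(tr)))
  nc <- nullHotspotCounts(cal)
  se <- stats::sd(nc) / sqrt(length(nc)) / max(length(hs), 1)
  expect_lt(empFdr, 0.01 + 3 * max(se, sqrt(0.01 * 0.99 / length(hs))))
})
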