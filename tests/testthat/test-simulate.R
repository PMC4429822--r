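test_that("simulateTags emits exactly depth tags, in bounds, reproducibly", {
  cfg <- tinyConfig()
  tr <- simulateTruth(cfg)
  ts1 <- simulateTags(cfg, "P0", truth = tr)
  ts2 <- simulateTags(cfg, "P0", truth = tr)
  expect_equal(depth(ts1), 1e5)
  expect_identical(tags(ts1), tags(ts2))          # same seed, same tags
  expect_true(all(start(tags(ts1)) >= 1))
  expect_true(all(end(tags(ts1)) <= cfg@chromLength))
  ts3 <- simulateTags(cfg, "P0", truth = tr, seed = 999)
  expect_false(identical(tags(ts1), tags(ts3)))
})

test_that("planted truth is deterministic, non-overlapping and labelled", {
  cfg <- tinyConfig()
  tr1 <- simulateTruth(cfg)
  tr2 <- simulateTruth(cfg)
  expect_identical(trueDhs(tr1), trueDhs(tr2))
  d <- trueDhs(tr1)
  expect_length(d, cfg@nTrueDhs)
  expect_true(all(width(d) == cfg@dhsWidth))
  expect_equal(length(GenomicRanges::reduce(d)), length(d))  # no overlaps
  expect_true(all(mcols(d)$archetype %in%
                    c("early", "mid", "late", "constitutive")))
})

test_that("stage archetype weights scale in-DHS tag counts as expected", {
  ## early-archetype DHSs at the late stage should receive weight-0.15
  ## times the P0-weighted expectation; checked against the analytic
  ## multinomial mean within 3 binomial SDs over 50 replicates
  cfg <- tinyConfig(seed = 21)
  tr <- simulateTruth(cfg)
  d <- trueDhs(tr)
  early <- d[mcols(d)$archetype == "early"]
  w <- archetypeWeights(cfg@stages)
  countIn <- function(stage, seed) {
    ts <- simulateTags(cfg, stage, truth = tr, seed = seed)
    sum(IRanges::overlapsAny(tags(ts), early))
  }
  nRep <- 50
  cnt <- vapply(seq_len(nRep), function(r) countIn("Adult", 5000 + r),
                numeric(1))
  ## analytic expectation under the generator's multinomial model
  wStage <- mcols(d)[["w_Adult"]]
  dhsW <- width(d) * cfg@enrichmentFold * wStage
  bgW <- cfg@chromLength - sum(width(d))
  pEarly <- sum(dhsW[mcols(d)$archetype == "early"]) / (sum(dhsW) + bgW)
  expMean <- cfg@depth * pEarly
  se <- sqrt(cfg@depth * pEarly * (1 - pEarly) / nRep)
  expect_lt(abs(mean(cnt) - expMean), 3 * se)
  ## and the early:late weight ratio at Adult is 0.15 : 1
  expect_equal(unname(w["early", "Adult"] / w["late", "Adult"]), 0.15)
})

test_that("ChIP peak simulation honours the overlap contract", {
  cfg <- tinyConfig(seed = 31)
  tr <- simulateTruth(cfg)
  d <- trueDhs(tr)
  full <- simulateChipPeaks(tr, 1.0, 50, seed = 1)
  ovBp <- width(pintersect(full, d[subjectHits(findOverlaps(full, d))]))
  expect_length(full, 50)
  expect_true(all(ovBp >= 75))
  none <- simulateChipPeaks(tr, 0.0, 50, seed = 1)
  expect_false(any(IRanges::overlapsAny(none, d)))
  some <- simulateChipPeaks(tr, 0.8, 40, seed = 2)
  expect_equal(sum(mcols(some)$overlapsTruth), round(0.8 * 40))
  expect_error(simulateChipPeaks(tr, 1.0, 1000), "more overlapping")
})

test_that("motif hit simulation respects background rate and threshold", {
  cfg <- tinyConfig(seed = 41)
  tr <- simulateTruth(cfg)
  tfT <- data.frame(tf = "TF_X", archetype = "early", odds = 20)
  sim <- simulateMotifHits(tr, tfT, backgroundRate = 0, seed = 3)
  arch <- mcols(trueDhs(tr))$archetype
  ## background rate 0: no presence outside the target archetype
  expect_true(all(!sim$presence[arch != "early", "TF_X"]))
  simBg <- simulateMotifHits(tr, data.frame(tf = "TF_Y", archetype = NA,
                                            odds = 1),
                             backgroundRate = 0.3, seed = 4)
  expect_true(all(mcols(simBg$hits)$matchP < simBg$pThreshold))
  expect_true(all(IRanges::overlapsAny(simBg$hits, trueDhs(tr))))
  expect_warning(
    simulateMotifHits(tr, data.frame(tf = "TF_Z", archetype = "mid",
                                     odds = 100),
                      backgroundRate = 0.5, seed = 5),
    "clamped")
})

test_that("orthology simulation partitions DHSs in exact proportions", {
  cfg <- SimConfig(nChroms = 1, chromLength = 3e6, nTrueDhs = 1000,
                   depth = 1e5, seed = 51)
  tr <- simulateTruth(cfg)
  orth <- simulateOrthology(tr, c(shared = 0.6, diverged = 0.3,
                                  unalignable = 0.1), seed = 6)
  expect_equal(as.integer(table(orth$categories)), c(600, 300, 100))
  allShared <- simulateOrthology(tr, c(shared = 1, diverged = 0,
                                       unalignable = 0), seed = 7)
  expect_true(all(allShared$categories == "shared"))
  noneMapped <- simulateOrthology(tr, c(shared = 0, diverged = 0,
                                        unalignable = 1), seed = 8)
  expect_equal(nrow(noneMapped$map), 0)
  expect_length(noneMapped$partnerDhs, 0)
})

test_that("aggregate in-DHS tag fraction converges to the analytic value", {
  cfg <- SimConfig(nChroms = 1, chromLength = 1e6, nTrueDhs = 100,
                   archetypeMix = c(early = 0, mid = 0, late = 0,
                                    constitutive = 1),
                   depth = 1e6, seed = 61)
  tr <- simulateTruth(cfg)
  ts <- simulateTags(cfg, "P0", truth = tr)
  d <- trueDhs(tr)
  footprint <- sum(width(d))
  pIn <- footprint * cfg@enrichmentFold /
    (footprint * cfg@enrichmentFold + (cfg@chromLength - footprint))
  obs <- sum(IRanges::overlapsAny(tags(ts), d))
  se <- sqrt(cfg@depth * pIn * (1 - pIn))
  expect_lt(abs(obs - cfg@depth * pIn), 3 * se)
})
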