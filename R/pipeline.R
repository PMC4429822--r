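## End-to-end orchestration of the synthetic study: tags -> hotspots and
## peaks (FDR-calibrated) -> master list -> normalized matrix -> temporal
## clusters -> annotation / occupancy -> motif enrichment -> conservation,
## plus validation of every stage against the planted truth.

#' Assemble a pipeline run configuration
#'
#' Collects the synthetic-study configuration and all analysis constants
#' (window 150 bp / step 20 bp, FDR target 1%, occupancy overlap 75 bp,
#' cross-set mapping overlap 25 bp, promoter window 1 kb, motif match
#' threshold 1e-4, k = 12, alpha = 0.01) under a single seed.
#'
#' @param simConfig a [SimConfig] describing the synthetic study.
#' @param fdrTarget target FDR of hotspot calling.
#' @param nullReplicates simulated-null datasets per calibration.
#' @param k number of temporal clusters.
#' @param windowLen,step,backgroundLen scan parameters.
#' @param occupancyOverlap,mappingOverlap,promoterUpstream,motifP,alpha
#'   classification and testing constants (see module functions).
#' @param chipOverlapFraction,chipPeaks ChIP simulation settings.
#' @param seed master seed; all stage seeds derive from it.
#' @param outDir optional output directory; when set, every intermediate
#'   artifact is written.
#' @return a named list of class `dhsRunConfig`.
#' @export
runConfig <- function(simConfig = SimConfig(), fdrTarget = 0.01,
                      nullReplicates = 2, k = 12, windowLen = 150,
                      step = 20, backgroundLen = 50000,
                      occupancyOverlap = 75, mappingOverlap = 25,
                      promoterUpstream = 1000, motifP = 1e-4,
                      alpha = 0.01, chipOverlapFraction = 0.9,
                      chipPeaks = 200, seed = 1, outDir = NULL) {
  cfg <- list(simConfig = simConfig, fdrTarget = fdrTarget,
              nullReplicates = nullReplicates, k = k,
              windowLen = windowLen, step = step,
              backgroundLen = backgroundLen,
              occupancyOverlap = occupancyOverlap,
              mappingOverlap = mappingOverlap,
              promoterUpstream = promoterUpstream, motifP = motifP,
              alpha = alpha, chipOverlapFraction = chipOverlapFraction,
              chipPeaks = chipPeaks, seed = as.integer(seed),
              outDir = outDir)
  class(cfg) <- "dhsRunConfig"
  cfg
}

.configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  cfg <- config
  cfg$outDir <- NULL
  saveRDS(cfg, f, version = 2)
  unname(tools::md5sum(f))
}

.genomeRanges <- function(simConfig) {
  chroms <- paste0("chr", seq_len(simConfig@nChroms))
  gr <- GRanges(chroms, IRanges(1L, simConfig@chromLength))
  seqlengths(gr) <- setNames(rep(simConfig@chromLength,
                                 simConfig@nChroms), chroms)
  gr
}

.writeTsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# configHash: ", hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-study pipeline
#'
#' Executes every stage in order on data generated from the configured
#' synthetic study and returns all intermediate objects together with a
#' machine-readable report. Identical configuration and seed reproduce
#' an identical report.
#'
#' @param config a list from [runConfig()].
#' @return a list of class `dhsRun` with elements `truth`, `samples`
#'   (per-stage tags/track/calibration/hotspots/peaks), `master`,
#'   `raw`, `transformed`, `model`, `promoter`, `occupancy`, `motifs`,
#'   `enrichment`, `orthology`, `conservation` and `report`.
#' @export
runAll <- function(config) {
  stopifnot(inherits(config, "dhsRunConfig"))
  sc <- config$simConfig
  hash <- .configHash(config)
  truth <- simulateTruth(sc)
  mappable <- .genomeRanges(sc)
  samples <- list()
  for (i in seq_along(sc@stages)) {
    stage <- sc@stages[i]
    ts <- simulateTags(sc, stage, truth = truth,
                       seed = config$seed + 1000L * i)
    cal <- calibrateThreshold(ts, mappable,
                              targetFdr = config$fdrTarget,
                              seed = config$seed + 100L * i,
                              nReplicates = config$nullReplicates,
                              windowLen = config$windowLen,
                              step = config$step,
                              backgroundLen = config$backgroundLen)
    track <- countCuts(ts, config$windowLen, config$step)
    hs <- callHotspots(track, fdrThreshold(cal), config$backgroundLen)
    pk <- callPeaks(hs, track)
    samples[[stage]] <- list(tags = ts, track = track, calibration = cal,
                             hotspots = hs, peaks = pk)
  }
  peakSets <- lapply(samples, `[[`, "peaks")
  master <- buildMasterList(peakSets)
  tracks <- lapply(samples, `[[`, "track")
  raw <- maxDensityPerSample(master, tracks)
  spots <- vapply(samples, function(s) s$calibration@spotObserved,
                  numeric(1))
  transformed <- normalizeDensity(raw, spots)
  kUse <- min(config$k, nrow(transformed))
  model <- kmeansCluster(transformed, k = kUse, seed = config$seed)
  promoter <- classifyPromoter(master, tssSites(truth),
                               config$promoterUpstream)
  names(promoter) <- names(master)

  chip <- list(
    TF_A = simulateChipPeaks(truth, config$chipOverlapFraction,
                             config$chipPeaks,
                             minOverlap = config$occupancyOverlap,
                             seed = config$seed + 11L),
    TF_B = simulateChipPeaks(truth, config$chipOverlapFraction,
                             config$chipPeaks,
                             minOverlap = config$occupancyOverlap,
                             seed = config$seed + 12L))
  occ <- lapply(names(chip), function(f)
    occupancy(master, chip[[f]], factor = f,
              minOverlap = config$occupancyOverlap))
  names(occ) <- names(chip)

  tfTargets <- data.frame(
    tf = c("TF_early", "TF_mid", "TF_late", paste0("TF_bg", 1:3)),
    archetype = c("early", "mid", "late", NA, NA, NA),
    odds = c(10, 10, 10, 1, 1, 1))
  motifs <- simulateMotifHits(truth, tfTargets,
                              pThreshold = config$motifP,
                              seed = config$seed + 21L)
  presence <- dhsMotifPresence(master, motifs$hits,
                               pThreshold = config$motifP)
  enrichment <- clusterEnrichment(model, presence, alpha = config$alpha)

  orth <- simulateOrthology(truth, seed = config$seed + 31L)
  conservation <- categorizeConservation(trueDhs(truth), orth$map,
                                         orth$partnerDhs,
                                         minOverlap = config$mappingOverlap)

  top <- enrichment[enrichment$significant, , drop = FALSE]
  top <- top[order(top$pBonf), , drop = FALSE]
  report <- list(
    configHash = hash, seed = config$seed,
    spot = spots,
    hotspotCounts = vapply(samples, function(s) length(s$hotspots),
                           integer(1)),
    peakCounts = vapply(samples, function(s) length(s$peaks),
                        integer(1)),
    fdrEstimates = vapply(samples, function(s) fdrEstimate(s$calibration),
                          numeric(1)),
    masterSize = length(master),
    clusterSizes = as.integer(table(factor(assignments(model),
                                           levels = seq_len(kUse)))),
    clusterLabels = clusterLabels(model),
    topEnrichments = utils::head(top, 10),
    conservationCounts = as.integer(table(conservation)))

  run <- list(config = config, truth = truth, samples = samples,
              master = master, raw = raw, transformed = transformed,
              model = model, promoter = promoter, occupancy = occ,
              chip = chip, motifs = motifs, presence = presence,
              enrichment = enrichment, orthology = orth,
              conservation = conservation, report = report)
  class(run) <- "dhsRun"
  if (!is.null(config$outDir)) .writeRunArtifacts(run, config$outDir, hash)
  run
}

.writeRunArtifacts <- function(run, outDir, hash) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (stage in names(run$samples)) {
    s <- run$samples[[stage]]
    writeBed5(s$hotspots, file.path(outDir,
                                    paste0(stage, "_hotspots.bed")))
    writeBed5(s$peaks, file.path(outDir, paste0(stage, "_peaks.bed")))
  }
  writeBed5(run$master, file.path(outDir, "master_list.bed"))
  .writeTsv(data.frame(dhsId = rownames(run$transformed),
                       run$transformed, check.names = FALSE),
            file.path(outDir, "density_matrix.tsv"), hash)
  .writeTsv(data.frame(dhsId = names(assignments(run$model)),
                       cluster = assignments(run$model),
                       label = clusterLabels(run$model)[
                         assignments(run$model)]),
            file.path(outDir, "clusters.tsv"), hash)
  .writeTsv(run$enrichment, file.path(outDir, "enrichment.tsv"), hash)
  .writeTsv(data.frame(dhsId = names(run$conservation),
                       category = run$conservation),
            file.path(outDir, "conservation.tsv"), hash)
  rep <- run$report
  .writeTsv(data.frame(key = c("masterSize", "seed",
                               paste0("spot_", names(rep$spot)),
                               paste0("hotspots_", names(rep$hotspotCounts))),
                       value = c(rep$masterSize, rep$seed, rep$spot,
                                 rep$hotspotCounts)),
            file.path(outDir, "report.tsv"), hash)
  invisible(outDir)
}

#' Benchmark FDR calibration on the demonstration genome
#'
#' Runs the simulated-random-reads calibration at its target FDR on the
#' default synthetic study (2 chromosomes x 5 Mb, 2,000 planted DHSs at
#' 10-fold enrichment, 1 million tags), calls hotspots at the calibrated
#' threshold and measures the empirical false discovery rate against the
#' planted truth: the fraction of called hotspots that do not overlap
#' any planted DHS.
#'
#' @param seed master seed of the benchmark.
#' @param nReplicates simulated null datasets used by the calibration.
#' @param targetFdr calibration target (default 0.01).
#' @param stage stage whose tag sample is scanned.
#' @param simConfig optional [SimConfig] override of the study.
#' @return list with `empiricalFdr` (proportion), `mcSe` (Monte-Carlo
#'   standard error of the estimate), `nHotspots`, `sensitivity` and the
#'   [FdrCalibration].
#' @export
demoFdrBenchmark <- function(seed = 1, nReplicates = 20,
                             targetFdr = 0.01, stage = "P0",
                             simConfig = NULL) {
  sc <- if (is.null(simConfig)) SimConfig(seed = as.integer(seed))
        else simConfig
  truth <- simulateTruth(sc)
  ts <- simulateTags(sc, stage, truth = truth,
                     seed = as.integer(seed) + 1000L)
  mappable <- .genomeRanges(sc)
  cal <- calibrateThreshold(ts, mappable, targetFdr = targetFdr,
                            seed = as.integer(seed) + 7L,
                            nReplicates = nReplicates)
  hs <- callHotspots(countCuts(ts), fdrThreshold(cal))
  planted <- trueDhs(truth)
  falseHs <- !IRanges::overlapsAny(hs, planted, ignore.strand = TRUE)
  empFdr <- if (length(hs)) mean(falseHs) else NA_real_
  nc <- nullHotspotCounts(cal)
  ## MC uncertainty: variability of the null hotspot count across
  ## replicates, plus the binomial error of the observed false fraction
  seNull <- stats::sd(nc) / sqrt(length(nc)) / max(length(hs), 1L)
  seBin <- sqrt(max(empFdr, targetFdr) *
                  (1 - max(empFdr, targetFdr)) / max(length(hs), 1L))
  list(empiricalFdr = empFdr, mcSe = max(seNull, seBin),
       nHotspots = length(hs),
       sensitivity = mean(IRanges::overlapsAny(planted, hs,
                                               ignore.strand = TRUE)),
       calibration = cal)
}

#' Validate a pipeline run against the planted truth
#'
#' @param run a `dhsRun` from [runAll()].
#' @param truth the [SimTruth] of the run (defaults to the run's own).
#' @return list of metrics: per-stage hotspot `sensitivity` (fraction of
#'   planted DHSs recovered) and `empiricalFdr` (fraction of called
#'   hotspots not overlapping any planted DHS), `clusterPurity` of the
#'   temporal clustering against archetypes, `enrichmentRecovery`
#'   (fraction of planted enriched TFs reaching Bonferroni significance),
#'   and `conservationMatchRate` against the generator's categories.
#' @export
validateAgainstTruth <- function(run, truth = run$truth) {
  planted <- trueDhs(truth)
  sens <- vapply(run$samples, function(s)
    mean(IRanges::overlapsAny(planted, s$hotspots, ignore.strand = TRUE)),
    numeric(1))
  efdr <- vapply(run$samples, function(s) {
    if (!length(s$hotspots)) return(NA_real_)
    mean(!IRanges::overlapsAny(s$hotspots, planted, ignore.strand = TRUE))
  }, numeric(1))

  ## archetype truth of master DHSs overlapping exactly one planted DHS
  ov <- findOverlaps(run$master, planted, ignore.strand = TRUE)
  nHit <- tabulate(queryHits(ov), nbins = length(run$master))
  uniq <- which(nHit == 1L)
  archOf <- rep(NA_character_, length(run$master))
  archOf[queryHits(ov)] <- mcols(planted)$archetype[subjectHits(ov)]
  asg <- assignments(run$model)
  sel <- names(run$master)[uniq]
  purity <- if (length(sel) >= 2)
    clusterPurity(asg[sel], archOf[uniq]) else NA_real_

  plantedTf <- c("TF_early", "TF_mid", "TF_late")
  rec <- vapply(plantedTf, function(tf) {
    any(run$enrichment$significant[run$enrichment$tf == tf])
  }, logical(1))

  consMatch <- mean(run$conservation ==
                      run$orthology$categories[names(run$conservation)])
  list(sensitivity = sens, empiricalFdr = efdr,
       clusterPurity = purity,
       enrichmentRecovery = mean(rec),
       conservationMatchRate = consMatch)
}
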