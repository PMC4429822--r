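#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom GenomeInfoDb seqnames seqlevels seqlengths seqlengths<- Seqinfo
#' @importFrom stats pbinom phyper kmeans hclust as.dist chisq.test rbinom rnorm runif setNames
#' @importFrom utils read.delim write.table
NULL

## Stage weights of the four temporal accessibility archetypes across an
## ordered three-stage design (early / mid / late / constitutive).  Values
## are relative cleavage-rate multipliers within a DHS.
.ARCHETYPE_WEIGHTS <- rbind(
  early        = c(1.00, 0.40, 0.15),
  mid          = c(0.30, 1.00, 0.30),
  late         = c(0.15, 0.40, 1.00),
  constitutive = c(1.00, 1.00, 1.00)
)

#' SimConfig: parameters of the synthetic DNase-seq study
#'
#' Describes a synthetic genome with planted DNase I hypersensitive sites
#' (DHSs) whose accessibility follows one of four temporal archetypes
#' across an ordered set of developmental stages. The defaults define the
#' demonstration study: 2 chromosomes of 5 Mb, 2,000 planted 300-bp DHSs
#' at 10-fold cleavage enrichment, 1 million tags per sample, stages
#' P0/P7/Adult.
#'
#' @slot nChroms number of chromosomes.
#' @slot chromLength length of each chromosome in bp.
#' @slot nTrueDhs number of planted DHSs (pairwise non-overlapping).
#' @slot dhsWidth width of each planted DHS in bp.
#' @slot archetypeMix named proportions over the four archetypes
#'   (early, mid, late, constitutive); must sum to 1.
#' @slot enrichmentFold ratio of in-DHS to background per-bp cleavage rate
#'   at an archetype weight of 1.
#' @slot depth tags per sample.
#' @slot stages ordered stage labels.
#' @slot nTss number of synthetic transcription start sites.
#' @slot seed integer RNG seed; fixes the planted truth.
#' @export
setClass("SimConfig", slots = c(
  nChroms = "integer", chromLength = "integer", nTrueDhs = "integer",
  dhsWidth = "integer", archetypeMix = "numeric", enrichmentFold = "numeric",
  depth = "numeric", stages = "character", nTss = "integer", seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nChroms < 1L || object@chromLength < 1L)
    msg <- c(msg, "chromosome count and length must be positive")
  if (object@dhsWidth < 1L) msg <- c(msg, "dhsWidth must be positive")
  if (object@depth <= 0) msg <- c(msg, "depth must be positive")
  if (object@enrichmentFold < 1) msg <- c(msg, "enrichmentFold must be >= 1")
  if (abs(sum(object@archetypeMix) - 1) > 1e-8)
    msg <- c(msg, "archetypeMix must sum to 1")
  if (!all(names(object@archetypeMix) %in% rownames(.ARCHETYPE_WEIGHTS)))
    msg <- c(msg, "archetypeMix names must be early/mid/late/constitutive")
  if (length(object@stages) != ncol(.ARCHETYPE_WEIGHTS))
    msg <- c(msg, sprintf("exactly %d ordered stages are supported",
                          ncol(.ARCHETYPE_WEIGHTS)))
  ## all planted DHSs (plus separating gaps) must fit on the genome
  need <- as.numeric(object@nTrueDhs) * (object@dhsWidth + 1000)
  if (need > as.numeric(object@nChroms) * object@chromLength)
    msg <- c(msg, "planted DHSs do not fit in the genome")
  if (length(msg)) msg else TRUE
})

#' SimTruth: ground truth of a synthetic study
#'
#' @slot config the [SimConfig] the truth was drawn from.
#' @slot dhs GRanges of planted DHSs with metadata columns `archetype` and
#'   one per-stage intensity weight column per stage.
#' @slot tss GRanges (width 1, stranded) of synthetic transcription start
#'   sites with a `gene` column.
#' @export
setClass("SimTruth", slots = c(
  config = "SimConfig", dhs = "GRanges", tss = "GRanges"
))

#' TagSet: aligned DNase I cleavage tag positions for one sample
#'
#' Each tag is the 5' cleavage position of one sequenced fragment; the
#' sequencing depth of the sample is the number of tags.
#'
#' @slot sampleId sample label.
#' @slot tags GRanges of width-1 positions with strand.
#' @export
setClass("TagSet", slots = c(sampleId = "character", tags = "GRanges"))

setValidity("TagSet", function(object) {
  if (length(object@tags) && !all(GenomicRanges::width(object@tags) == 1L))
    return("all tags must have width 1 (5' cut positions)")
  TRUE
})

#' CutTrack: windowed cleavage counts for one sample
#'
#' Tags summed within fixed-length windows placed at a fixed step along
#' each chromosome, with a tags-per-million normalized density alongside
#' the raw count. The sorted per-chromosome cut positions are retained so
#' that local background totals can be computed exactly at hotspot-calling
#' time.
#'
#' @slot sampleId sample label.
#' @slot windows GRanges of windows with metadata columns `count`
#'   (raw tags in window) and `density` (count x 1e6 / totalTags).
#' @slot cuts per-chromosome sorted integer positions of all tags.
#' @slot totalTags total tags in the sample.
#' @slot windowLen window length in bp.
#' @slot step window step in bp.
#' @export
setClass("CutTrack", slots = c(
  sampleId = "character", windows = "GRanges", cuts = "list",
  totalTags = "numeric", windowLen = "integer", step = "integer"
))

#' FdrCalibration: simulated-null false discovery rate estimate
#'
#' Result of scanning uniform random tag sets at equal depth with the
#' identical hotspot-detection chain and comparing simulated to observed
#' hotspot counts.
#'
#' @slot threshold binomial p-value cutoff in force.
#' @slot observedHotspots hotspots called on the observed sample.
#' @slot simulatedHotspots mean hotspots called across null replicates.
#' @slot fdrEstimate simulatedHotspots / max(observedHotspots, 1).
#' @slot spotObserved SPOT score of the observed sample at this threshold.
#' @slot nullCounts hotspot count of each null replicate.
#' @slot nReplicates number of null replicates.
#' @slot seed RNG seed of the null tag sets.
#' @export
setClass("FdrCalibration", slots = c(
  threshold = "numeric", observedHotspots = "integer",
  simulatedHotspots = "numeric", fdrEstimate = "numeric",
  spotObserved = "numeric", nullCounts = "numeric",
  nReplicates = "integer", seed = "integer"
))

setValidity("FdrCalibration", function(object) {
  if (object@fdrEstimate < 0) return("fdrEstimate must be non-negative")
  TRUE
})

#' ClusterModel: k-means partition of master DHSs into temporal groups
#'
#' @slot k number of clusters.
#' @slot assignments integer cluster index per DHS, named by DHS id.
#' @slot centroids k x nStages matrix of cluster centres on the
#'   transformed 0-10 accessibility scale.
#' @slot labels temporal label per cluster: E (early), M (mid), L (late),
#'   O (other/valley), C (constitutive).
#' @slot seed RNG seed of the initialization.
#' @slot totWithinss total within-cluster sum of squares.
#' @export
setClass("ClusterModel", slots = c(
  k = "integer", assignments = "integer", centroids = "matrix",
  labels = "character", seed = "integer", totWithinss = "numeric"
))

setValidity("ClusterModel", function(object) {
  msg <- character()
  if (nrow(object@centroids) != object@k)
    msg <- c(msg, "centroids must have k rows")
  if (length(object@labels) != object@k)
    msg <- c(msg, "labels must cover all k clusters")
  if (any(object@assignments < 1L | object@assignments > object@k))
    msg <- c(msg, "assignments out of range")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nChroms, "chrom x",
      object@chromLength, "bp;", object@nTrueDhs, "DHS x",
      object@dhsWidth, "bp; fold", object@enrichmentFold,
      "; depth", format(object@depth, big.mark = ","),
      "; stages", paste(object@stages, collapse = "/"),
      "; seed", object@seed, "\n")
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(object@dhs), "planted DHSs,",
      length(object@tss), "TSSs\n")
  print(table(archetype = mcols(object@dhs)$archetype))
})

setMethod("show", "TagSet", function(object) {
  cat("TagSet '", object@sampleId, "': ", length(object@tags),
      " tags on ", length(unique(as.character(seqnames(object@tags)))),
      " chromosome(s)\n", sep = "")
})

setMethod("show", "CutTrack", function(object) {
  cat("CutTrack '", object@sampleId, "': ", length(object@windows),
      " windows (", object@windowLen, " bp / step ", object@step,
      "), ", format(object@totalTags, big.mark = ","), " tags\n", sep = "")
})

setMethod("show", "FdrCalibration", function(object) {
  cat("FdrCalibration: threshold p <=",
      format(object@threshold, digits = 4),
      "\n  observed hotspots:  ", object@observedHotspots,
      "\n  simulated hotspots: ", format(object@simulatedHotspots, digits = 4),
      " (mean of ", object@nReplicates, " null replicate(s))",
      "\n  FDR estimate:       ", format(object@fdrEstimate, digits = 4),
      "\n  SPOT score:         ", format(object@spotObserved, digits = 4),
      "\n", sep = "")
})

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel: k =", object@k, "on",
      length(object@assignments), "DHSs\n")
  tab <- table(factor(object@assignments, levels = seq_len(object@k)))
  cat("  sizes: ", paste(as.integer(tab), collapse = ", "), "\n", sep = "")
  cat("  labels:", paste(object@labels, collapse = ", "), "\n")
})
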