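library(GenomicRanges)
library(IRanges)

## tiny synthetic-study configuration for fast unit tests
tinyConfig <- function(seed = 11, ...) {
  SimConfig(nChroms = 1, chromLength = 5e5, nTrueDhs = 100,
            dhsWidth = 300, depth = 1e5, nTss = 50, seed = seed, ...)
}

## whole-genome mappable ranges of a SimConfig
genomeOf <- function(config) {
  chroms <- paste0("chr", seq_len(config@nChroms))
  gr <- GRanges(chroms, IRanges(1, config@chromLength))
  seqlengths(gr) <- setNames(rep(config@chromLength, config@nChroms),
                             chroms)
  gr
}

## TagSet from bare 1-based positions on one chromosome
tagSetAt <- function(pos, chromLength = max(pos) + 200L, chrom = "chr1",
                     sampleId = "toy") {
  gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L),
                strand = "+")
  seqlengths(gr) <- setNames(chromLength, chrom)
  TagSet(gr, sampleId = sampleId)
}

## brute-force window starts (1-based, step, length) containing position p
bruteWindowStarts <- function(p, chromLength, windowLen = 150, step = 20) {
  starts <- seq.int(1L, max(1L, chromLength - windowLen + 1L), by = step)
  starts[starts <= p & p <= starts + windowLen - 1L]
}

## independent exact hypergeometric upper tail via the choose() identity
hyperTailOracle <- function(k, N, K, n) {
  jmax <- min(n, K)
  if (k > jmax) return(0)
  js <- seq.int(k, jmax)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
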