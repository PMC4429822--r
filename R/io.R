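## Readers and writers for the BED-family and TSV interchange formats.
## Internal coordinates are 1-based closed (GRanges); files on disk use
## the conventions of their formats (BED 0-based half-open, FIMO 1-based
## inclusive).

#' Read / write interval sets as BED
#'
#' Thin wrappers over `rtracklayer` handling the 0-based half-open to
#' 1-based closed conversion. Gzipped paths are supported.
#'
#' @param path file path (`.bed` or `.bed.gz`).
#' @param gr GRanges to write.
#' @return `readBed` returns a GRanges.
#' @export
readBed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' @rdname readBed
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a TagSet as 6-column BED
#'
#' One line per tag (name ".", score 0, strand kept).
#'
#' @param x a [TagSet].
#' @param path output path; `.gz` suffix compresses.
#' @return the path, invisibly.
#' @export
writeTagsBed <- function(x, path) {
  gr <- tags(x)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = ".", score = 0L,
                   strand = as.character(strand(gr)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 6-column BED of tag positions into a TagSet
#'
#' @param path BED6 path (positions are width-1 cut sites).
#' @param sampleId sample label.
#' @return a [TagSet].
#' @export
readTagsBed <- function(path, sampleId = basename(path)) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]),
                strand = if (ncol(df) >= 6) df[[6]] else "*")
  TagSet(gr, sampleId = sampleId)
}

#' Read / write a six-column orthology interval map
#'
#' TSV with header srcChrom/srcStart/srcEnd/tgtChrom/tgtStart/tgtEnd in
#' 0-based half-open coordinates on disk; converted to the internal
#' 1-based closed convention on read.
#'
#' @param path file path.
#' @param map data.frame in the internal convention (as produced by
#'   [simulateOrthology()]).
#' @return `readOrthologyMap` returns the internal-convention
#'   data.frame.
#' @export
readOrthologyMap <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$srcStart <- df$srcStart + 1L
  df$tgtStart <- df$tgtStart + 1L
  df
}

#' @rdname readOrthologyMap
#' @export
writeOrthologyMap <- function(map, path) {
  out <- map
  out$srcStart <- out$srcStart - 1L
  out$tgtStart <- out$tgtStart - 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FIMO-style motif hit table
#'
#' Tab-separated scanner output with columns motif_id, sequence_name,
#' start, stop, strand, score, p.value (1-based inclusive coordinates,
#' as FIMO prints them; sequence_name is taken as the chromosome).
#'
#' @param path file path.
#' @return GRanges with metadata columns `motifId`, `matchP` and
#'   `score`.
#' @export
readFimo <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  cn <- tolower(gsub("[^a-z.]", ".", tolower(names(df))))
  names(df) <- cn
  pcol <- grep("^p\\.value$|^pvalue$", cn, value = TRUE)[1]
  gr <- GRanges(df$sequence.name, IRanges(df$start, df$stop),
                strand = if ("strand" %in% cn) df$strand else "*")
  mcols(gr)$motifId <- df$motif.id
  mcols(gr)$matchP <- df[[pcol]]
  if ("score" %in% cn) mcols(gr)$score <- df$score
  gr
}

#' Write hotspots or peaks as BED5
#'
#' Score column is -log10 p (or the stored score) clipped to 0-1000.
#'
#' @param gr GRanges with a `score` metadata column.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeBed5 <- function(gr, path) {
  sc <- mcols(gr)$score
  if (is.null(sc)) sc <- 0L
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = if (is.null(names(gr)))
                     paste0("region_", seq_along(gr)) else names(gr),
                   score = pmin(1000L, pmax(0L, as.integer(sc))))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
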