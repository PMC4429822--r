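test_that("master-list construction merges transitively and is idempotent", {
  A <- GRanges("chr1", IRanges(c(100, 1000), width = 150))
  m <- buildMasterList(list(a = A, b = A))
  expect_equal(unname(granges(m)), granges(A))
  ## two partially overlapping peaks merge into one master interval
  two <- buildMasterList(list(x = GRanges("chr1", IRanges(101, 250)),
                              y = GRanges("chr1", IRanges(201, 350))))
  expect_length(two, 1)
  expect_equal(start(two), 101)
  expect_equal(end(two), 350)
  ## a chain of 150-bp peaks at starts 1,101,201,301,401 -> one master
  chain <- GRanges("chr1", IRanges(c(1, 101, 201, 301, 401), width = 150))
  m2 <- buildMasterList(list(s = chain))
  expect_length(m2, 1)
  expect_equal(width(m2), 550)
  ## idempotence and provenance
  m3 <- buildMasterList(list(m2 = m2))
  expect_equal(unname(granges(m3)), unname(granges(m2)))
  multi <- buildMasterList(list(setA = A, setB = shift(A, 50)))
  expect_true(all(lengths(mcols(multi)$sourceSamples) == 2))
})

test_that("max density per sample matches a linear-scan oracle", {
  ts <- tagSetAt(c(rep(1000L, 3), rep(1100L, 7), rep(1200L, 5)),
                 chromLength = 5000L)
  track <- countCuts(ts)
  master <- GRanges("chr1", IRanges(c(950, 3000), width = 300))
  names(master) <- c("DHS_1", "DHS_2")
  m <- maxDensityPerSample(master, list(s1 = track))
  w <- cutWindows(track)
  ov <- IRanges::overlapsAny(w, master[1])
  expect_equal(m["DHS_1", "s1"], max(mcols(w)$density[ov]))
  expect_equal(m["DHS_2", "s1"], 0)  # no tags there
})

test_that("promoter classification is strand-aware 1-kb upstream", {
  tss <- GRanges("chr1", IRanges(c(50000, 80000), width = 1),
                 strand = c("+", "-"))
  ## upstream of the + TSS
  expect_true(classifyPromoter(GRanges("chr1", IRanges(49500, 49650)),
                               tss))
  ## downstream of the + TSS is not promoter
  expect_false(classifyPromoter(GRanges("chr1", IRanges(50011, 50160)),
                                tss))
  ## boundary: exactly 1000 bp upstream still counts
  expect_true(classifyPromoter(GRanges("chr1", IRanges(49000, 49000)),
                               tss))
  expect_false(classifyPromoter(GRanges("chr1", IRanges(48999, 48999)),
                                tss))
  ## minus strand: upstream lies to the right
  expect_true(classifyPromoter(GRanges("chr1", IRanges(80500, 80600)),
                               tss))
  expect_false(classifyPromoter(GRanges("chr1", IRanges(79500, 79900)),
                                tss))
})

test_that("genomic partition applies the precedence rules", {
  tss <- GRanges("chr1", IRanges(10000, width = 1), strand = "+")
  ann <- list(tss = tss,
              exons = GRanges("chr1", IRanges(c(10000, 30000),
                                              width = 500)),
              introns = GRanges("chr1", IRanges(30500, 40000)))
  dhs <- GRanges("chr1", IRanges(c(9500,   # promoter (and exon-adjacent)
                                   30100,  # exon
                                   35000,  # intron
                                   11500,  # proximal intergenic (1.5 kb)
                                   60000), # distal intergenic
                                 width = 100))
  lab <- genomicPartition(dhs, ann)
  expect_equal(as.character(lab),
               c("promoter", "exon", "intron", "proximal_intergenic",
                 "distal_intergenic"))
  ## promoter wins over exon when both apply
  both <- GRanges("chr1", IRanges(9950, 10050))
  expect_equal(as.character(genomicPartition(both, ann)), "promoter")
  w <- testthat::capture_warnings(genomicPartition(dhs, list(tss = tss)))
  expect_true(any(grepl("unused", w)))
})

test_that("genomic partition recovers a planted composition", {
  set.seed(5)
  tss <- GRanges("chr1", IRanges(seq(5000, 95000, by = 10000), width = 1),
                 strand = "+")
  ann <- list(tss = tss,
              exons = GRanges("chr1", IRanges(seq(200000, by = 10000,
                                                  length.out = 10),
                                              width = 2000)),
              introns = GRanges("chr1", IRanges(seq(400000, by = 10000,
                                                    length.out = 10),
                                                width = 4000)))
  dhs <- c(
    GRanges("chr1", IRanges(start(tss)[1:10] - 500, width = 100)),
    GRanges("chr1", IRanges(seq(200500, by = 10000, length.out = 10),
                            width = 50)),
    GRanges("chr1", IRanges(seq(401000, by = 10000, length.out = 10),
                            width = 50)),
    GRanges("chr1", IRanges(seq(700000, by = 10000, length.out = 10),
                            width = 50)))
  ## planted: 10 promoter, 10 exon, 10 intron, 10 distal
  lab <- genomicPartition(dhs, ann)
  expect_equal(sum(lab == "promoter"), 10)
  expect_equal(sum(lab == "exon"), 10)
  expect_equal(sum(lab == "intron"), 10)
  expect_equal(sum(lab == "distal_intergenic"), 10)
})

test_that("occupancy enforces the 75-bp rule and multi-overlap exclusion", {
  master <- GRanges("chr1", IRanges(c(1000, 1300), width = 150))
  names(master) <- c("DHS_1", "DHS_2")
  ## overlap 70 bp: below threshold
  o1 <- occupancy(master, GRanges("chr1", IRanges(1080, 1300)), "F")
  expect_true(all(o1$calls$status == "unoccupied"))
  expect_equal(unname(o1$counts["nonOverlapping"]), 1L)
  ## overlap 100 bp: occupied
  o2 <- occupancy(master, GRanges("chr1", IRanges(1000, 1099)), "F")
  expect_equal(as.character(o2$calls$status), c("occupied", "unoccupied"))
  expect_equal(o2$calls$overlapBp[1], 100L)
  ## a peak straddling both DHSs by >= 75 bp each is excluded
  o3 <- occupancy(master, GRanges("chr1", IRanges(1060, 1420)), "F")
  expect_true(all(o3$calls$status == "unoccupied"))
  expect_equal(unname(o3$counts["multiDhsExcluded"]), 1L)
})

test_that("occupancy matches a brute-force all-pairs oracle", {
  set.seed(17)
  master <- GenomicRanges::reduce(
    GRanges("chr1", IRanges(sample.int(2e6, 800), width = 200)))
  names(master) <- paste0("DHS_", seq_along(master))
  peaks <- GRanges("chr1", IRanges(sample.int(2e6, 600), width = 250))
  occ <- occupancy(master, peaks, "F", minOverlap = 75)
  ## brute force over every (peak, DHS) pair
  ovBp <- matrix(0L, length(peaks), length(master))
  for (i in seq_along(peaks)) {
    s <- pmax(start(peaks)[i], start(master))
    e <- pmin(end(peaks)[i], end(master))
    ovBp[i, ] <- pmax(0L, e - s + 1L)
  }
  nHits <- rowSums(ovBp >= 75)
  occupiedDhs <- sort(unique(unlist(
    lapply(which(nHits == 1L), function(i) which(ovBp[i, ] >= 75)))))
  expect_equal(which(occ$calls$status == "occupied"), occupiedDhs)
  expect_equal(unname(occ$counts["multiDhsExcluded"]), sum(nHits > 1))
  expect_equal(unname(occ$counts["nonOverlapping"]), sum(nHits == 0))
})

test_that("specificity subtraction applies the 25-bp threshold exactly", {
  target <- GRanges("chr1", IRanges(c(1000, 2000, 3000), width = 100))
  ## overlaps of 24, 25 and 0 bp with the comparison set
  other <- GRanges("chr1", IRanges(c(1076, 2075), width = 100))
  spec <- subtractSpecific(target, list(other), minOverlap = 25)
  expect_equal(start(spec), c(1000, 3000))
  expect_warning(subtractSpecific(target, list()), "unchanged")
  ## planted 600 shared / 400 unique
  set.seed(23)
  shared <- GRanges("chr1", IRanges(seq(1, by = 1000,
                                        length.out = 600), width = 200))
  unique_ <- GRanges("chr2", IRanges(seq(1, by = 1000,
                                         length.out = 400), width = 200))
  out <- subtractSpecific(suppressWarnings(c(shared, unique_)),
                          list(shared))
  expect_length(out, 400)
})

test_that("pairwise overlap matrix and linkage order behave as constructed", {
  A <- GRanges("chr1", IRanges(seq(1, by = 1000, length.out = 100),
                               width = 200))
  B <- A[1:80]
  C <- A[1:10]
  res <- pairwiseOverlapMatrix(list(A = A, B = B, C = C))
  expect_equal(res$overlap["A", "B"], 0.80)
  expect_equal(res$overlap["B", "A"], 1.0)
  expect_equal(unname(diag(res$overlap)), c(1, 1, 1))
  ## identical sets have off-diagonal 1
  res2 <- pairwiseOverlapMatrix(list(X = A, Y = A))
  expect_equal(res2$overlap["X", "Y"], 1.0)
  ## the two similar sets join before the dissimilar third
  sim <- pairwiseOverlapMatrix(list(A = A, B = A[1:90], C = A[1:10]))
  merged1 <- sim$hclust$merge[1, ]
  expect_setequal(abs(merged1), c(1, 2))  # A and B first
  expect_warning(pairwiseOverlapMatrix(list(A = A, E = GRanges())),
                 "empty")
})
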