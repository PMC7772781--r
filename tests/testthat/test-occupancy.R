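gr1 <- function(chrom, start1, end1) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1))
}

test_that("interval intersection is half-open-exact at 1 bp", {
  # BED [100,200) vs [199,300): exactly 1 shared base
  a <- readBed(tmpFile("chr1\t100\t200"))
  expect_true(intervalsOverlap(a, readBed(tmpFile("chr1\t199\t300"))))
  # adjacent half-open intervals do not intersect
  expect_false(intervalsOverlap(a, readBed(tmpFile("chr1\t200\t300"))))
  # chromosome mismatch
  expect_false(intervalsOverlap(a, readBed(tmpFile("chr2\t100\t200"))))
})

test_that("callOccupancy equals the all-pairs oracle on random instances", {
  withr::local_seed(401)
  for (rep in 1:30) {
    regions <- randomRegions(sample(5:60, 1))
    peaks <- list(A = randomPeaks(sample(0:50, 1), "A"),
                  B = randomPeaks(sample(1:50, 1), "B"))
    got <- occupancyCalls(callOccupancy(regions, peaks))
    expect_identical(got, bruteOccupancy(regions, peaks))
  }
})

test_that("occupancy edge cases and provenance behave", {
  regions <- randomRegions(10)
  empty <- callOccupancy(regions, list(A = randomPeaks(0, "A")))
  expect_false(any(occupancyCalls(empty)))
  # one peak spanning a whole chromosome binds every region there
  big <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1, 10000))
  big$name <- "span"; big$summit <- 5000L
  m <- callOccupancy(regions, list(A = big))
  onA <- as.character(GenomicRanges::seqnames(regions)) == "chrA"
  expect_identical(unname(occupancyCalls(m)[, "A"]), onA)
  expect_identical(occupancyProvenance(m, regions$enh_id[which(onA)[1]], "A"),
                   "span")
  # duplicate ids rejected
  dup <- regions; dup$enh_id <- rep("same", 10)
  expect_error(callOccupancy(dup, list(A = big)), "duplicate region ids")
})

test_that("adding peaks never unbinds and removing regions is local", {
  withr::local_seed(402)
  regions <- randomRegions(30)
  peaks <- list(A = randomPeaks(20, "A"))
  before <- occupancyCalls(callOccupancy(regions, peaks))
  more <- list(A = c(peaks$A, randomPeaks(10, "A")))
  after <- occupancyCalls(callOccupancy(regions, more))
  expect_true(all(after[before[, "A"], "A"]))
  sub <- callOccupancy(regions[-5], peaks)
  expect_identical(occupancyCalls(sub),
                   before[rownames(occupancyCalls(sub)), , drop = FALSE])
})

test_that("peak annotation follows summit precedence TSS > TES > body", {
  genes <- readGeneTable(tmpFile(
    c("gene_id\tchrom\tstrand\ttss\ttes",
      "g1\tchr1\t+\t10000\t20000")))
  mk <- function(summit, halfw = 50L) {
    p <- gr1("chr1", summit - halfw, summit + halfw)
    p$summit <- as.integer(summit)
    p$name <- "p"
    p
  }
  expect_identical(annotatePeaks(mk(10000), genes)$subcontext, "TSS")
  expect_identical(annotatePeaks(mk(15000), genes)$subcontext, "gene_body")
  expect_identical(annotatePeaks(mk(19800), genes)$subcontext, "TES")
  far <- annotatePeaks(mk(50000), genes)
  expect_identical(far$context, "intergenic")
  # within the genic flank but outside all summit windows
  near <- annotatePeaks(mk(8500), genes)
  expect_identical(near$context, "genic")
  expect_identical(near$subcontext, "intergenic")
})

test_that("genic/intergenic fractions on planted data match the plant map", {
  ds <- paperDatasetLight()
  ann <- annotatePeaks(datasetPeaks(ds)$Ctr9, datasetGenes(ds))
  pm <- plantMap(ds)
  # planted truth: gene-promoter peaks are genic, enhancer peaks intergenic
  isGenePeak <- grepl("^Ctr9_gene_", ann$name)
  expect_identical(ann$context == "genic", isGenePeak)
})

test_that("state classification partitions regions and matches the rules", {
  ds <- minimalDataset()
  m <- callOccupancy(datasetEnhancers(ds), datasetPeaks(ds))
  st <- classifyStates(m)
  calls <- occupancyCalls(m)
  expect_identical(st$state == "active", unname(calls[, "H3K27ac"]))
  expect_identical(st$state == "poised",
                   unname(calls[, "H3K4me1"] & !calls[, "H3K27ac"]))
  expect_true(all(st$state %in% c("active", "poised", "unmarked")))
  expect_error(classifyStates(callOccupancy(datasetEnhancers(ds),
                                            datasetPeaks(ds)["Ctr9"])),
               "H3K27ac")
})

test_that("venn subset counts enumerate all subsets and sum to n", {
  withr::local_seed(403)
  regions <- randomRegions(40)
  peaks <- list(X = randomPeaks(25, "X"), Y = randomPeaks(25, "Y"),
                Z = randomPeaks(25, "Z"))
  m <- callOccupancy(regions, peaks)
  v <- vennCounts(m, c("X", "Y", "Z"))
  expect_length(v, 8L)
  expect_identical(sum(v), 40L)
  # spot-check one subset against direct enumeration
  calls <- occupancyCalls(m)
  expect_identical(unname(v[["X+Y-Z-"]]),
                   sum(calls[, "X"] & !calls[, "Y"] & !calls[, "Z"]))
})

test_that("active-enhancer prediction follows the co-occupancy rule", {
  genes <- readGeneTable(tmpFile(
    c("gene_id\tchrom\tstrand\ttss\ttes", "g1\tchr1\t+\t1000\t5000")))
  k27 <- c(gr1("chr1", 800, 1200),    # co-bound but overlaps the promoter
           gr1("chr1", 20000, 21000), # co-bound, intergenic -> predicted
           gr1("chr1", 40000, 41000)) # no Ctr9 -> dropped
  ctr9 <- c(gr1("chr1", 900, 1100), gr1("chr1", 20500, 20600))
  pred <- predictActiveEnhancers(k27, ctr9, genes)
  expect_length(pred, 1L)
  expect_identical(GenomicRanges::start(pred), 20000L)
  expect_length(predictActiveEnhancers(k27, ctr9[0], genes), 0L)
  # overlapping survivors merge
  k27b <- c(gr1("chr1", 20000, 21000), gr1("chr1", 20800, 22000))
  expect_length(predictActiveEnhancers(k27b, ctr9, genes), 1L)
})
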