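mkPeak <- function(chrom, summit, score = 1, factor = "NELFA") {
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(summit - 100L, summit + 100L))
  gr$summit <- as.integer(summit)
  gr$score <- score
  gr$factor <- factor
  gr$name <- sprintf("%s_%d", factor, summit)
  gr
}

test_that("summit-to-TSS offsets are strand-corrected", {
  expect_equal(summitTssOffset(1184, 1000, "+"), 184)
  expect_equal(summitTssOffset(1979, 2000, "-"), 21)
  expect_equal(summitTssOffset(1000, 1000, "+"), 0)
  expect_error(summitTssOffset(10, 10, "+", "chr1", "chr2"),
               "different chromosomes")
})

test_that("offset summary assigns to nearest TSS with deterministic ties", {
  genes <- readGeneTable(tmpFile(
    c("gene_id\tchrom\tstrand\ttss\ttes",
      "gLeft\tchr1\t+\t1000\t4000",
      "gRight\tchr1\t-\t9000\t6000")))
  one <- factorOffsetSummary(mkPeak("chr1", 1039), genes)
  expect_equal(one$mean, 39)
  expect_equal(one$n, 1L)
  # equidistant between TSS 1000 and 9000: goes to the smaller TSS,
  # 4000 bp away, outside the default window -> dropped
  mid <- factorOffsetSummary(mkPeak("chr1", 5000), genes)
  expect_equal(mid$n, 0L)
  expect_true(is.na(mid$mean))
  # with a wide window the tie resolves to gLeft (+ strand: offset +4000)
  midWide <- factorOffsetSummary(mkPeak("chr1", 5000), genes,
                                 assignmentWindow = 5000L)
  expect_equal(midWide$offsets, 4000)
})

test_that("reversing every gene strand negates every offset", {
  ds <- minimalDataset()
  genes <- datasetGenes(ds)
  pk <- datasetPeaks(ds)$NELFA
  s1 <- factorOffsetSummary(pk, genes)
  flipped <- genes
  GenomicRanges::strand(flipped) <-
    ifelse(as.character(GenomicRanges::strand(genes)) == "+", "-", "+")
  s2 <- factorOffsetSummary(pk, flipped)
  expect_equal(sort(s2$offsets), sort(-s1$offsets))
})

test_that("offset recovery on planted data equals the plant map exactly", {
  ds <- paperDatasetLight()
  pm <- plantMap(ds)$genes
  for (f in c("NELFA", "Ser5p", "Ctr9")) {
    s <- factorOffsetSummary(datasetPeaks(ds)[[f]], datasetGenes(ds))
    planted <- pm[[paste0("off_", f)]]
    planted <- planted[!is.na(planted)]
    expect_equal(s$n, length(planted))
    expect_equal(s$mean, mean(planted))
  }
})

test_that("NELFA-Ctr9 pairing: arithmetic, laterality, tie-breaks", {
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000))
  region$enh_id <- "r1"
  nelfa <- mkPeak("chr1", 5000, score = 10)
  uni <- pairNelfaCtr9(region, nelfa, mkPeak("chr1", 5465, factor = "Ctr9"))
  expect_equal(uni$distance, 465)
  expect_identical(uni$laterality, "unilateral")
  bi <- pairNelfaCtr9(region, nelfa,
                      c(mkPeak("chr1", 4800, factor = "Ctr9"),
                        mkPeak("chr1", 5200, factor = "Ctr9")))
  expect_equal(bi$distance, 200)
  expect_identical(bi$laterality, "bilateral")
  none <- suppressWarnings(
    pairNelfaCtr9(region, nelfa, mkPeak("chr2", 5000, factor = "Ctr9")))
  expect_identical(none$laterality, "none")
  expect_true(is.na(none$distance))
  # equidistant Ctr9 summits: the smaller coordinate wins
  tie <- pairNelfaCtr9(region, nelfa,
                       c(mkPeak("chr1", 4900, factor = "Ctr9"),
                         mkPeak("chr1", 5100, factor = "Ctr9")))
  expect_equal(tie$ctr9_summit, 4900)
  # the strongest NELFA peak anchors
  two <- pairNelfaCtr9(region, c(mkPeak("chr1", 3000, score = 99),
                                 mkPeak("chr1", 5000, score = 1)),
                       mkPeak("chr1", 3100, factor = "Ctr9"))
  expect_equal(two$nelfa_summit, 3000)
})

test_that("pairing equals the brute-force nearest-summit scan", {
  withr::local_seed(404)
  for (rep in 1:20) {
    regions <- randomRegions(20, maxPos = 1000L, maxWidth = 200L)
    nelfa <- randomPeaks(15, "NELFA", maxPos = 1200L)
    ctr9 <- randomPeaks(15, "Ctr9", maxPos = 1200L)
    got <- pairNelfaCtr9(regions, nelfa, ctr9)
    want <- brutePairs(regions, nelfa, ctr9)
    expect_identical(got$region_id, want$region_id)
    expect_equal(got$distance, want$distance)
    expect_identical(got$laterality, want$laterality)
  }
})

test_that("planted pair distances are recovered exactly", {
  ds <- paperDatasetLight()
  pairs <- pairNelfaCtr9(datasetEnhancers(ds), datasetPeaks(ds)$NELFA,
                         datasetPeaks(ds)$Ctr9)
  pm <- plantMap(ds)$enhancers
  merged <- merge(pairs, pm[, c("enh_id", "pair_distance", "laterality")],
                  by.x = "region_id", by.y = "enh_id")
  planted <- !is.na(merged$pair_distance)
  expect_equal(merged$distance[planted], merged$pair_distance[planted])
  expect_identical(merged$laterality.x[planted],
                   merged$laterality.y[planted])
})
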