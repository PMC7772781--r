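test_that("narrowPeak parsing computes summits and preserves order", {
  f <- tmpFile(c("chr1\t100\t200\tp1\t0\t.\t5\t3\t2\t50",
                 "chr1\t100\t201\tp2\t0\t.\t5\t3\t2\t-1",
                 "chr2\t10\t20\tp3\t0\t+\t1\t1\t1\t0"),
               ".narrowPeak")
  pk <- readNarrowPeak(f, "Ctr9")
  expect_length(pk, 3L)
  expect_identical(pk$name, c("p1", "p2", "p3"))
  # summit = start + offset (0-based), stored 1-based
  expect_identical(pk$summit[1L] - 1L, 100L + 50L)
  # offset -1 falls back to the floored midpoint
  expect_identical(pk$summit[2L] - 1L, 150L)
  expect_identical(pk$factor, rep("Ctr9", 3L))
  expect_identical(GenomicRanges::start(pk), c(101L, 101L, 11L))
})

test_that("narrowPeak parse/validation errors name the offending line", {
  bad <- tmpFile("chr1\t100\t200\tp1\t0\t.\t5\t3", ".narrowPeak")
  expect_error(readNarrowPeak(bad, "x"), "line 1.*10 columns")
  bad2 <- tmpFile(c("chr1\t0\t10\ta\t0\t.\t1\t1\t1\t0",
                    "chr1\t100\t200\tp1\t0\t.\t5\t3\t2\t100"),
                  ".narrowPeak")
  expect_error(readNarrowPeak(bad2, "x"), "line 2.*summit offset")
  bad3 <- tmpFile("chr1\t200\t100\tp1\t0\t.\t5\t3\t2\t0", ".narrowPeak")
  expect_error(readNarrowPeak(bad3, "x"), "end <= start")
})

test_that("BED and enhancer BED parse with validation", {
  gr <- readBed(tmpFile("chr2\t0\t500", ".bed"))
  expect_identical(GenomicRanges::start(gr), 1L)
  expect_identical(GenomicRanges::end(gr), 500L)
  expect_error(readBed(tmpFile("chr2\t500\t500", ".bed")), "end <= start")

  e <- readEnhancerBed(tmpFile(c("chr1\t1000\t9000\tSE\tse1\tgeneA,geneB",
                                 "chr1\t20000\t21000\tTE\tte1\t."),
                               ".bed"))
  expect_identical(e$enh_class, c("SE", "TE"))
  expect_identical(as.list(e$target_genes)[[1L]], c("geneA", "geneB"))
  expect_length(as.list(e$target_genes)[[2L]], 0L)
  expect_error(
    readEnhancerBed(tmpFile("chr1\t0\t10\tXX\tid", ".bed")),
    "unknown class 'XX'")
})

test_that("gene tables honor the strand/TSS orientation invariant", {
  g <- readGeneTable(tmpFile(
    c("gene_id\tchrom\tstrand\ttss\ttes",
      "gMinus\tchr1\t-\t5000\t2000",
      "gPlus\tchr1\t+\t100\t900")))
  expect_length(g, 2L)
  expect_identical(g$tss[g$gene_id == "gMinus"], 5000L)
  expect_error(readGeneTable(tmpFile(
    c("gene_id\tchrom\tstrand\ttss\ttes", "bad\tchr1\t+\t900\t100"))),
    "orientation invariant")
})

test_that("expression reader collapses transcripts to best-expressed gene", {
  df <- readExpressionTable(tmpFile(
    c("gene_id\ttpm_control\ttpm_knockdown",
      "g1\t4\t2", "g1\t9\t3", "g2\t1\t1")))
  expect_identical(nrow(df), 2L)
  expect_equal(df$tpm_control[df$gene_id == "g1"], 9)
})

test_that("write-then-parse round trips are byte-identical", {
  ds <- minimalDataset()
  # narrowPeak
  f1 <- tempfile(); f2 <- tempfile()
  writeNarrowPeak(datasetPeaks(ds)$Ctr9, f1)
  writeNarrowPeak(readNarrowPeak(f1, "Ctr9"), f2)
  expect_identical(readLines(f1), readLines(f2))
  # enhancer BED
  writeEnhancerBed(datasetEnhancers(ds), f1)
  writeEnhancerBed(readEnhancerBed(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
  # gene table
  writeGeneTable(datasetGenes(ds), f1)
  writeGeneTable(readGeneTable(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
  # expression
  writeExpressionTable(datasetExpression(ds), f1)
  writeExpressionTable(readExpressionTable(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
  # bedGraph
  tr <- datasetTracks(ds)$Ctr9
  writeBedGraph(tr, f1)
  writeBedGraph(readBedGraph(f1, binWidth(tr), genomeSizes(ds)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("bedGraph binning and rpm normalization conserve mass", {
  f <- tmpFile("chr1\t0\t100\t2", ".bedGraph")
  tr <- readBedGraph(f, 10L)
  expect_equal(totalMass(tr), 200)
  # with a declared library mass of 200, rpm value is 2e6/200 per bp
  rpm <- toRPM(tr)
  expect_equal(unique(trackValues(rpm)$chr1), 10000)
  expect_equal(sum(trackValues(rpm)$chr1) * binWidth(rpm), 1e6)
  # relative bin ratios survive normalization
  tr2 <- SignalTrack(list(chr1 = c(4, 1, 0, 2)), 10L)
  rpm2 <- toRPM(tr2)
  v <- trackValues(tr2)$chr1
  w <- trackValues(rpm2)$chr1
  expect_equal(w[1] / w[2], v[1] / v[2])
  expect_equal(w[4] / w[2], v[4] / v[2])
})

test_that("unaligned bedGraph intervals are length-weighted into bins", {
  f <- tmpFile(c("chr1\t5\t15\t3", "chr1\t15\t20\t1"), ".bedGraph")
  tr <- readBedGraph(f, 10L)
  # bin 1 gets 5 bp of value 3; bin 2 gets 5 bp of 3 and 5 bp of 1
  expect_equal(trackValues(tr)$chr1, c(1.5, 2.0))
  expect_equal(totalMass(tr), 3 * 10 + 1 * 5)
})

test_that("empty track parses but cannot be rpm-normalized", {
  f <- tmpFile(character(), ".bedGraph")
  tr <- readBedGraph(f, 10L, genomeSizes = c(chr1 = 100))
  expect_equal(totalMass(tr), 0)
  expect_error(toRPM(tr), "zero total mass")
})
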