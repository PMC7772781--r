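flatTrack <- function(v = 2, nbins = 4000L, bw = 10L) {
  SignalTrack(list(chr1 = rep(v, nbins)), bw)
}

geneSet <- function(starts, len = 6000L, strand = "+") {
  tss <- ifelse(strand == "+", starts, starts + len - 1L)
  readGeneTable(tmpFile(c(
    "gene_id\tchrom\tstrand\ttss\ttes",
    sprintf("g%d\tchr1\t%s\t%d\t%d", seq_along(starts), strand, tss,
            ifelse(strand == "+", starts + len - 1L, starts)))))
}

test_that("expression strata split by rank with silent genes set aside", {
  expr <- data.frame(gene_id = sprintf("g%02d", 1:10),
                     tpm_control = c(0.2, 0.5, 1, 2, 3, 4, 5, 6, 7, 8))
  st <- expressionStrata(expr)
  expect_length(st$silent, 2L)
  expect_length(st$high, 2L)
  expect_length(st$medium, 4L)
  expect_length(st$low, 2L)
  # disjoint cover of all genes
  all <- c(st$high, st$medium, st$low, st$silent)
  expect_identical(sort(all), sort(expr$gene_id))
  expect_identical(st$high, c("g10", "g09"))
  # all-zero expression: everything silent
  z <- expressionStrata(data.frame(gene_id = c("a", "b"),
                                   tpm_control = c(0, 0)))
  expect_identical(sort(z$silent), c("a", "b"))
  expect_error(expressionStrata(expr[0, ]), "empty")
})

test_that("strata partition holds on random tables", {
  withr::local_seed(405)
  for (rep in 1:10) {
    n <- sample(5:80, 1)
    expr <- data.frame(gene_id = sprintf("g%03d", seq_len(n)),
                       tpm_control = round(stats::rlnorm(n, 0, 2), 3))
    st <- expressionStrata(expr)
    all <- c(st$high, st$medium, st$low, st$silent)
    expect_identical(sort(all), sort(expr$gene_id))
    expect_identical(anyDuplicated(all), 0L)
  }
})

test_that("a uniform track yields a flat scaled profile", {
  tr <- flatTrack(v = 2)
  genes <- geneSet(c(5001, 15001, 25001))
  prof <- scaledGeneProfile(tr, genes)
  scale <- 1e7 / totalMass(tr)
  expect_equal(prof$values, rep(2 * scale, 100), tolerance = 1e-12)
  expect_equal(prof$n_genes, 3L)
})

test_that("an impulse at the TSS lands in the first body bin", {
  v <- numeric(4000)
  v[501] <- 7                       # bin [5000, 5010): the TSS base
  tr <- SignalTrack(list(chr1 = v), 10L)
  genes <- geneSet(5001)            # TSS at 5001, gene start0 = 5000
  prof <- scaledGeneProfile(tr, genes)
  nz <- which(prof$values > 0)
  expect_identical(nz, 21L)         # first gene-body bin
})

test_that("scaled profiles conserve mass per gene", {
  withr::local_seed(406)
  tr <- SignalTrack(list(chr1 = stats::rpois(4000, 3) / 10), 10L)
  genes <- geneSet(c(5001, 13001, 21001), len = 5500L)
  prof <- scaledGeneProfile(tr, genes)
  scale <- 1e7 / totalMass(tr)
  windows <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(GenomicRanges::start(genes) - 2000L,
                             GenomicRanges::end(genes) + 2000L))
  oracle <- binnedMass(tr, windows) * scale
  expect_equal(prof$perGeneMass, oracle, tolerance = 1e-9)
  # equal-length genes: profile bins x bin widths x n = total mass
  widths <- c(rep(100, 20), rep(5500 / 60, 60), rep(100, 20))
  expect_lt(abs(sum(prof$values * widths) * prof$n_genes - sum(oracle)) /
              sum(oracle), 1e-6)
  # too-short genes are skipped with a warning
  tiny <- geneSet(9001, len = 30L)
  expect_warning(p2 <- scaledGeneProfile(tr, tiny), "skipped")
  expect_equal(p2$n_genes, 0L)
})

test_that("TSS window profiles are strand-corrected and zero on silence", {
  z <- tssWindowProfile(flatTrack(0), geneSet(10001))
  expect_equal(unname(z), rep(0, 400))
  # mirror property: flipping the strand reverses the profile
  withr::local_seed(407)
  tr <- SignalTrack(list(chr1 = stats::runif(4000)), 10L)
  plus <- geneSet(10001, strand = "+")
  minusTss <- readGeneTable(tmpFile(c(
    "gene_id\tchrom\tstrand\ttss\ttes", "g1\tchr1\t-\t10001\t4002")))
  pPlus <- tssWindowProfile(tr, plus)
  pMinus <- tssWindowProfile(tr, minusTss)
  expect_equal(unname(pMinus), rev(unname(pPlus)))
})

test_that("planted factor order appears in TSS window profiles", {
  ds <- paperDataset()
  genes <- datasetGenes(ds)
  expressed <- genes[!is.na(plantMap(ds)$genes$off_NELFA)]
  pn <- tssWindowProfile(datasetTracks(ds)$NELFA, expressed)
  pc <- tssWindowProfile(datasetTracks(ds)$Ctr9, expressed)
  offN <- as.numeric(names(pn)[which.max(pn)])
  offC <- as.numeric(names(pc)[which.max(pc)])
  expect_lt(offN, offC)            # NELFA peaks upstream of Ctr9
  expect_lt(abs(offN - 21), 30)
  expect_lt(abs(offC - 184), 30)
})

test_that("anchored heatmaps orient Ctr9 to the right and pad bounds", {
  ds <- minimalDataset()
  pairs <- pairNelfaCtr9(datasetEnhancers(ds), datasetPeaks(ds)$NELFA,
                         datasetPeaks(ds)$Ctr9)
  hm <- anchoredHeatmap(datasetTracks(ds)[c("NELFA", "Ctr9")], pairs,
                        windowBp = 2000L)
  expect_identical(dim(hm$matrices$NELFA), c(nrow(pairs), 200L))
  uni <- which(pairs$laterality == "unilateral")
  for (i in uni) {
    off <- pairs$ctr9_summit[i] - pairs$nelfa_summit[i]
    if (hm$meta$flipped[i]) off <- -off
    col <- floor((off + 1000) / 10) + 1L
    expect_gte(col, 100L)          # Ctr9 summit at or right of center
  }
})

test_that("quantile normalization is idempotent-safe and rank-preserving", {
  withr::local_seed(408)
  m1 <- matrix(stats::rlnorm(200), nrow = 10)
  same <- quantileNormalizeMatrices(list(a = m1, b = m1))
  expect_equal(same$a, m1)
  const <- matrix(3, nrow = 10, ncol = 20)
  cn <- quantileNormalizeMatrices(list(a = const, b = const + 1))
  expect_true(all(cn$a == cn$a[1, 1]))
  # within-row rank order preserved
  m2 <- matrix(stats::rlnorm(200, 1, 2), nrow = 10)
  qn <- quantileNormalizeMatrices(list(a = m1, b = m2))
  for (i in 1:10) {
    expect_identical(order(qn$a[i, ]), order(m1[i, ]))
    expect_identical(order(qn$b[i, ]), order(m2[i, ]))
  }
  expect_error(quantileNormalizeMatrices(list(m1, matrix(0, 2, 2))),
               "same dimensions")
})
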