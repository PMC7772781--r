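test_that("region density matches constant tracks and the per-bp oracle", {
  tr <- SignalTrack(list(chr1 = rep(1.5, 1000)), 10L)
  reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 103), c(200, 777)))
  reg$enh_id <- c("a", "b")
  d <- regionDensity(tr, reg)
  expect_equal(d$density, c(1.5, 1.5))
  z <- regionDensity(SignalTrack(list(chr1 = numeric(1000)), 10L), reg)
  expect_equal(z$density, c(0, 0))
  # unknown chromosome: density 0 with warning
  reg2 <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 10))
  expect_warning(d2 <- regionDensity(tr, reg2), "absent from track")
  expect_equal(d2$density, 0)
})

test_that("edge-partial bins equal per-bp brute force on random tracks", {
  withr::local_seed(409)
  for (rep in 1:25) {
    bw <- sample(c(3L, 5L, 10L), 1)
    tr <- SignalTrack(list(chrA = stats::runif(400), chrB = stats::runif(300)),
                      bw)
    reg <- randomRegions(15, maxPos = 800L, maxWidth = 90L)
    got <- regionDensity(tr, reg)$density
    expect_equal(got, bruteDensity(tr, reg), tolerance = 1e-12)
  }
})

test_that("density is invariant to bin-width refinement", {
  withr::local_seed(410)
  v <- stats::runif(100)
  coarse <- SignalTrack(list(chr1 = v), 10L)
  fine <- SignalTrack(list(chr1 = rep(v, each = 2)), 5L)
  reg0 <- randomRegions(20, maxPos = 900L, maxWidth = 80L)
  reg <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(GenomicRanges::start(reg0),
                             GenomicRanges::end(reg0)))
  expect_equal(regionDensity(coarse, reg)$density,
               regionDensity(fine, reg)$density, tolerance = 1e-9)
})

test_that("class contrasts: fold of means and rank-sum p", {
  mk <- function(a, b) {
    data.frame(enh_class = rep(c("SE", "TE"), c(length(a), length(b))),
               density = c(a, b))
  }
  # identical distributions: fold 1, exact p 1
  same <- compareClasses(mk(c(1, 2), c(1, 2)))
  expect_equal(same$fold, 1)
  expect_equal(same$p, 1)
  # a = {3,4,5}, b = {1,2}: exact p = 2 * 1/C(5,3) = 0.2
  sep <- compareClasses(mk(c(3, 4, 5), c(1, 2)))
  expect_equal(sep$p, 0.2)
  expect_equal(sep$fold, 4 / 1.5)
  # zero denominator: fold is an NA sentinel, p still computed
  degen <- compareClasses(mk(c(1, 2), c(0, 0)))
  expect_true(is.na(degen$fold))
  expect_false(is.na(degen$p))
  expect_error(compareClasses(mk(numeric(), c(1))), "empty")
})

test_that("rank-sum p matches full enumeration for small samples", {
  withr::local_seed(411)
  for (rep in 1:40) {
    nA <- sample(2:6, 1)
    nB <- sample(2:6, 1)
    # integer draws so ties occur regularly
    a <- sample(1:6, nA, replace = TRUE)
    b <- sample(1:6, nB, replace = TRUE)
    expect_equal(rankSumP(a, b), enumRankSumP(a, b),
                 info = paste(c(a, "vs", b), collapse = " "))
  }
})

test_that("shuffled intervals preserve count and length multiset", {
  ds <- minimalDataset()
  enh <- datasetEnhancers(ds)
  sh <- shuffleIntervals(enh, genomeSizes(ds), seed = 5)
  expect_length(sh, length(enh))
  expect_identical(sort(GenomicRanges::width(sh)),
                   sort(GenomicRanges::width(enh)))
  expect_true(all(GenomicRanges::start(sh) >= 1))
  expect_true(all(GenomicRanges::end(sh) <=
                    genomeSizes(ds)[as.character(GenomicRanges::seqnames(sh))]))
  sh2 <- shuffleIntervals(enh, genomeSizes(ds), seed = 5)
  expect_identical(sh, sh2)
  expect_false(identical(sh, shuffleIntervals(enh, genomeSizes(ds), 6)))
  # a region longer than every chromosome is rejected by name
  long <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10))
  long$enh_id <- "giant"
  expect_error(shuffleIntervals(long, c(chr1 = 5), seed = 1), "giant")
})

test_that("shuffled placement is uniform within a chromosome", {
  reg <- GenomicRanges::GRanges(
    rep("chr1", 10000), IRanges::IRanges(start = 1, width = 10))
  sh <- shuffleIntervals(reg, c(chrA = 50000, chrB = 50000), seed = 9)
  # chromosome choice ~ Bernoulli(1/2)
  nA <- sum(as.character(GenomicRanges::seqnames(sh)) == "chrA")
  expect_gt(stats::binom.test(nA, 10000, 0.5)$p.value, 1e-4)
  # start positions uniform: chi-square over 10 position bins
  starts <- GenomicRanges::start(sh)
  counts <- table(cut(starts, breaks = seq(0, 50000, length.out = 11)))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 1e-4)
})

test_that("knockdown fold change recovers constructed divisors", {
  v <- rep(6, 1000)
  ctrl <- SignalTrack(list(chr1 = v), 10L, norm = "rpm", totalMass = 1)
  vkd <- v
  vkd[101:200] <- v[101:200] / 1.5      # the SE region bins
  kd <- SignalTrack(list(chr1 = vkd), 10L, norm = "rpm", totalMass = 1)
  reg <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(1001, 3001), c(2000, 4000)))
  reg$enh_class <- c("SE", "TE")
  fc <- occupancyFoldChange(ctrl, kd, reg)
  expect_equal(fc$fold[fc$class == "SE"], 1.5)
  expect_equal(fc$fold[fc$class == "TE"], 1)
  same <- occupancyFoldChange(ctrl, ctrl, reg)
  expect_equal(same$fold, c(1, 1))
  # zero knockdown median: NA sentinel
  zero <- SignalTrack(list(chr1 = numeric(1000)), 10L, norm = "rpm",
                      totalMass = 1)
  expect_true(all(is.na(occupancyFoldChange(ctrl, zero, reg)$fold)))
})
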