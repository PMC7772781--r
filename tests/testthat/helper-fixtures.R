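# Shared fixtures and independent brute-force oracles.
# Expensive datasets are built lazily once per test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

minimalDataset <- function(seed = 7) {
  memo(paste0("minimal", seed), function() {
    simulateDataset(defaultProfile("minimal"), seed = seed)
  })
}

paperDataset <- function() {
  memo("paper42", function() {
    simulateDataset(defaultProfile("paper2020"), seed = 42)
  })
}

paperDatasetLight <- function() {
  memo("paper42light", function() {
    simulateDataset(defaultProfile("paper2020"), seed = 42,
                    withTracks = FALSE)
  })
}

# sweep of light simulations used by the positional recovery checks:
# per seed, the recovered mean TSS offsets per factor and the mean
# NELFA-Ctr9 pair distance per enhancer class
seedSweep <- function(nSeeds = 100L) {
  memo(paste0("sweep", nSeeds), function() {
    profile <- defaultProfile("paper2020")
    res <- lapply(seq_len(nSeeds), function(s) {
      ds <- simulateDataset(profile, seed = s, withTracks = FALSE)
      genes <- datasetGenes(ds)
      pk <- datasetPeaks(ds)
      means <- vapply(c("NELFA", "Ser5p", "Ctr9"), function(f) {
        factorOffsetSummary(pk[[f]], genes)$mean
      }, numeric(1L))
      pairs <- pairNelfaCtr9(datasetEnhancers(ds), pk$NELFA, pk$Ctr9)
      ok <- !is.na(pairs$distance)
      c(means,
        pairSE = mean(pairs$distance[ok & pairs$enh_class == "SE"]),
        pairTE = mean(pairs$distance[ok & pairs$enh_class == "TE"]))
    })
    do.call(rbind, res)
  })
}

# --- small random instances -------------------------------------------------

randomRegions <- function(n, maxPos = 2000L, maxWidth = 60L) {
  chrom <- sample(c("chrA", "chrB"), n, replace = TRUE)
  start <- sample.int(maxPos, n, replace = TRUE)
  width <- sample.int(maxWidth, n, replace = TRUE)
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = start, width = width))
  gr$enh_id <- sprintf("r%03d", seq_len(n))
  gr
}

randomPeaks <- function(n, factor, maxPos = 2000L, maxWidth = 60L) {
  chrom <- sample(c("chrA", "chrB"), n, replace = TRUE)
  start <- sample.int(maxPos, n, replace = TRUE)
  width <- sample.int(maxWidth, n, replace = TRUE)
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = start, width = width))
  gr$name <- sprintf("%s_p%03d", factor, seq_len(n))
  gr$score <- round(stats::runif(n, 1, 100))
  gr$summit <- as.integer(start + floor(stats::runif(n) * width))
  gr$factor <- rep(factor, n)
  gr
}

# --- independent quadratic oracles ------------------------------------------

# all-pairs occupancy scan on plain vectors (1-based closed intervals)
bruteOccupancy <- function(regions, peaksByFactor) {
  ids <- regions$enh_id
  rc <- as.character(GenomicRanges::seqnames(regions))
  rs <- GenomicRanges::start(regions)
  re <- GenomicRanges::end(regions)
  out <- sapply(names(peaksByFactor), function(f) {
    pk <- peaksByFactor[[f]]
    pc <- as.character(GenomicRanges::seqnames(pk))
    ps <- GenomicRanges::start(pk)
    pe <- GenomicRanges::end(pk)
    vapply(seq_along(regions), function(i) {
      any(pc == rc[i] & ps <= re[i] & pe >= rs[i])
    }, logical(1L))
  })
  out <- matrix(out, nrow = length(regions),
                dimnames = list(ids, names(peaksByFactor)))
  out
}

# nearest-summit scan for NELFA-Ctr9 pairing
brutePairs <- function(regions, nelfa, ctr9) {
  ids <- regions$enh_id
  rc <- as.character(GenomicRanges::seqnames(regions))
  rs <- GenomicRanges::start(regions)
  re <- GenomicRanges::end(regions)
  nc <- as.character(GenomicRanges::seqnames(nelfa))
  cc <- as.character(GenomicRanges::seqnames(ctr9))
  rows <- list()
  for (i in seq_along(regions)) {
    np <- which(nc == rc[i] & nelfa$summit >= rs[i] & nelfa$summit <= re[i])
    if (length(np) == 0L) next
    np <- np[order(-nelfa$score[np], nelfa$summit[np])]
    anchor <- nelfa$summit[np[1L]]
    cs <- sort(ctr9$summit[cc == rc[i] & ctr9$summit >= rs[i] &
                             ctr9$summit <= re[i]])
    if (length(cs) == 0L) {
      rows[[length(rows) + 1L]] <-
        data.frame(region_id = ids[i], distance = NA_real_,
                   laterality = "none", stringsAsFactors = FALSE)
    } else {
      d <- abs(cs - anchor)
      lat <- if (any(cs < anchor) && any(cs > anchor)) "bilateral"
             else "unilateral"
      rows[[length(rows) + 1L]] <-
        data.frame(region_id = ids[i], distance = min(d), laterality = lat,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(region_id = character(), distance = numeric(),
                      laterality = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# per-bp density scan
bruteDensity <- function(track, regions) {
  bw <- binWidth(track)
  vals <- trackValues(track)
  vapply(seq_along(regions), function(i) {
    ch <- as.character(GenomicRanges::seqnames(regions))[i]
    v <- vals[[ch]]
    if (is.null(v)) return(0)
    pos <- GenomicRanges::start(regions)[i]:GenomicRanges::end(regions)[i]
    bins <- floor((pos - 1L) / bw) + 1L
    keep <- bins <= length(v)
    sum(v[bins[keep]]) / length(pos)
  }, numeric(1L))
}

# exact two-sided rank-sum p by full enumeration (average ranks for ties)
enumRankSumP <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  nA <- length(a)
  wObs <- sum(r[seq_len(nA)])
  ws <- apply(utils::combn(length(pooled), nA), 2L,
              function(ix) sum(r[ix]))
  min(1, 2 * min(mean(ws <= wObs + 1e-9), mean(ws >= wObs - 1e-9)))
}

# U by explicit pair counting
brutePairCountU <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

tmpFile <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
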