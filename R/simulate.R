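#' Simulate a complete synthetic dataset
#'
#' Generates a genome, gene models, SE/TE enhancer annotations, per-factor
#' peak sets, coverage tracks, an expression table and eRNA intervals with
#' the statistical structure the downstream analyses assume, and records a
#' plant map (every sampled offset, distance, occupancy draw and knockdown
#' effect) sufficient to recompute every expected summary without
#' re-simulation.
#'
#' Layout: features occupy disjoint fixed-width slots; chromosome 1 hosts a
#' fraction of the genes and no enhancers (so genes without any enhancer
#' within the association window exist); the remaining genes and all
#' enhancers are shuffled across the other chromosomes. Slot margins
#' guarantee that promoter peaks are always nearest to their own TSS within
#' the 2 kb assignment window and that enhancer peaks never fall within
#' 2 kb of a TSS.
#'
#' Promoter peaks are planted at `TSS + Normal(mean, sd)` on the
#' strand-corrected axis for NELFA, RNAPII Ser5p and Ctr9. On enhancers
#' bound by both NELFA and Ctr9, the Ctr9 summit is planted at the class's
#' NELFA-Ctr9 distance (unilaterally for most regions, as symmetric
#' flanking peaks for the rest). RNAPII Ser2p and eRNA draws are
#' conditional on Ctr9 so the containment constraints hold for every
#' region. Coverage tracks are sums of symmetric triangular kernels at
#' planted summits (uniform domains for the histone marks) plus Poisson
#' noise; the Ctr9 kernel masses on enhancers are calibrated so the
#' expected SE:TE mean density ratio equals the profile's target. The
#' knockdown Ser2p track is the control track with all enhancer-local
#' signal divided by the class divisor.
#'
#' @param profile A [CalibrationProfile-class], e.g.
#'   `defaultProfile("paper2020")`.
#' @param seed Integer seed; identical `(profile, seed)` gives an
#'   identical dataset.
#' @param withTracks Generate coverage tracks (the slowest part); set
#'   `FALSE` when only peaks/annotations are needed.
#' @return A [SyntheticDataset-class].
#' @examples
#' ds <- simulateDataset(defaultProfile("minimal"), seed = 1)
#' ds
#' @export
simulateDataset <- function(profile, seed, withTracks = TRUE) {
  withSeed(seed, .simulateDataset(profile, as.integer(seed), withTracks))
}

.simulateDataset <- function(profile, seed, withTracks) {
  gp <- profile@genome
  cv <- profile@coverage
  nG <- gp$nGenes
  nSE <- as.integer(profile@counts[["SE"]])
  nTE <- as.integer(profile@counts[["TE"]])
  slotW <- c(gene = gp$geneSlot, SE = gp$seSlot, TE = gp$teSlot)
  featW <- c(gene = NA, SE = gp$seWidth, TE = gp$teWidth)

  ## ---- genome layout ----
  nOther <- round(gp$otherFraction * nG)
  restTypes <- c(rep("gene", nG - nOther), rep("SE", nSE), rep("TE", nTE))
  restTypes <- restTypes[sample.int(length(restTypes))]
  nRestChrom <- gp$nChrom - 1L
  cumW <- cumsum(slotW[restTypes])
  chunk <- pmin(nRestChrom,
                findInterval(cumW - slotW[restTypes],
                             sum(slotW[restTypes]) / nRestChrom *
                               seq_len(nRestChrom - 1L)) + 1L)
  feat <- data.frame(
    type = c(rep("gene", nOther), restTypes),
    chrom = c(rep("chr1", nOther), paste0("chr", chunk + 1L)),
    stringsAsFactors = FALSE)
  feat$slotW <- slotW[feat$type]
  feat$slotStart <- stats::ave(feat$slotW, feat$chrom,
                               FUN = function(w) cumsum(w) - w)
  chromNames <- paste0("chr", seq_len(gp$nChrom))
  sizes <- vapply(chromNames, function(ch) {
    sum(feat$slotW[feat$chrom == ch]) + gp$tailMargin
  }, numeric(1L))
  names(sizes) <- chromNames
  if (!is.null(gp$chromLength) && any(sizes > gp$chromLength)) {
    .stopf("genome too small to host the requested features: chromosome %s needs %d bp but chromLength is %d",
           chromNames[which(sizes > gp$chromLength)[1L]],
           max(sizes), gp$chromLength)
  }

  ## ---- genes ----
  gi <- which(feat$type == "gene")
  lens <- sample(seq(gp$geneLenMin, gp$geneLenMax, by = 100L),
                 length(gi), replace = TRUE)
  gStart0 <- feat$slotStart[gi] + gp$geneMargin
  gEnd0 <- gStart0 + lens
  gStrand <- sample(c("+", "-"), length(gi), replace = TRUE)
  tss <- ifelse(gStrand == "+", gStart0 + 1L, gEnd0)
  tes <- ifelse(gStrand == "+", gEnd0, gStart0 + 1L)
  geneIds <- sprintf("gene_%04d", seq_along(gi))
  genes <- GenomicRanges::GRanges(
    seqnames = feat$chrom[gi],
    ranges = IRanges::IRanges(start = gStart0 + 1L, end = gEnd0),
    strand = gStrand, seqlengths = sizes)
  genes$gene_id <- geneIds
  genes$tss <- as.integer(tss)
  genes$tes <- as.integer(tes)

  ## ---- enhancers ----
  ei <- which(feat$type != "gene")
  eClass <- feat$type[ei]
  eW <- featW[eClass]
  eStart0 <- feat$slotStart[ei] + (feat$slotW[ei] - eW) / 2
  eEnd0 <- eStart0 + eW
  enhIds <- sprintf("enh_%05d", seq_along(ei))
  enhancers <- GenomicRanges::GRanges(
    seqnames = feat$chrom[ei],
    ranges = IRanges::IRanges(start = eStart0 + 1L, end = eEnd0),
    seqlengths = sizes)
  enhancers$enh_class <- eClass
  enhancers$enh_id <- enhIds

  ## ---- expression (control) ----
  ex <- profile@expression
  silent <- stats::runif(length(gi)) < ex$silentFraction
  level <- rep(NA_character_, length(gi))
  level[!silent] <- sample(names(ex$levels), sum(!silent), replace = TRUE,
                           prob = ex$levelProb)
  tpmCtrl <- numeric(length(gi))
  tpmCtrl[silent] <- stats::runif(sum(silent), 0, 0.5)
  tpmCtrl[!silent] <- pmax(1, ex$levels[level[!silent]] *
                              exp(stats::rnorm(sum(!silent), 0, ex$sdLog)))
  category <- ifelse(silent, "silent", level)

  ## ---- gene association groups (planted ground truth) ----
  group <- .plantGroups(feat$chrom[gi], tss, feat$chrom[ei], eStart0 + 1L,
                        eEnd0, eClass, maxDistance = 1e5)
  assocEnh <- attr(group, "enh_id")
  group <- as.vector(group)

  ## ---- knockdown expression ----
  kd <- profile@knockdown
  down <- stats::runif(length(gi)) < kd$downFraction[group]
  lfc <- numeric(length(gi))
  lfc[down] <- -pmax(kd$downLog2[["min"]],
                     stats::rnorm(sum(down), kd$downLog2[["mean"]],
                                  kd$downLog2[["sd"]]))
  lfc[!down] <- pmax(kd$upLog2[["min"]],
                     stats::rnorm(sum(!down), kd$upLog2[["mean"]],
                                  kd$upLog2[["sd"]]))
  tpmKd <- tpmCtrl * 2^lfc
  expression <- data.frame(gene_id = geneIds, tpm_control = tpmCtrl,
                           tpm_knockdown = tpmKd, group = group,
                           stringsAsFactors = FALSE)

  ## ---- promoter peaks ----
  expressed <- which(tpmCtrl >= 1)
  sgn <- ifelse(gStrand == "+", 1L, -1L)
  offs <- profile@promoterOffsets
  peakTables <- list()
  geneOffsets <- matrix(NA_real_, nrow = length(gi), ncol = nrow(offs),
                        dimnames = list(NULL, rownames(offs)))
  phw <- cv$promoterPeakHalfWidth
  for (f in rownames(offs)) {
    off <- round(stats::rnorm(length(expressed), offs[f, "mean"],
                              offs[f, "sd"]))
    geneOffsets[expressed, f] <- off
    summit <- tss[expressed] + sgn[expressed] * off
    peakTables[[f]] <- data.frame(
      chrom = feat$chrom[gi][expressed], summit = summit,
      start1 = summit - phw, end1 = summit + phw,
      mass = rep(cv$geneKernelMass[[f]], length(expressed)),
      name = sprintf("%s_gene_%s", f, geneIds[expressed]),
      stringsAsFactors = FALSE)
  }
  # Ser2p accumulates near the transcript end site
  s2sum <- tes[expressed] + round(stats::rnorm(length(expressed), 0, 50))
  peakTables$Ser2p <- data.frame(
    chrom = feat$chrom[gi][expressed], summit = s2sum,
    start1 = s2sum - phw, end1 = s2sum + phw,
    mass = rep(cv$geneKernelMass[["Ser2p"]], length(expressed)),
    name = sprintf("Ser2p_gene_%s", geneIds[expressed]),
    stringsAsFactors = FALSE)
  # H3K27ac marks active promoters (centered on the TSS)
  k27sum <- tss[expressed] + sgn[expressed] *
    round(stats::rnorm(length(expressed), 0, cv$promoterMarkSd))
  peakTables$H3K27ac <- data.frame(
    chrom = feat$chrom[gi][expressed], summit = k27sum,
    start1 = k27sum - 300L, end1 = k27sum + 300L,
    mass = rep(cv$geneKernelMass[["H3K27ac"]], length(expressed)),
    name = sprintf("H3K27ac_gene_%s", geneIds[expressed]),
    stringsAsFactors = FALSE)

  ## ---- enhancer occupancy and peaks ----
  nE <- length(ei)
  occ <- profile@occProb
  drawP <- function(f) stats::runif(nE) < occ[eClass, f]
  bCtr9 <- drawP("Ctr9")
  bNELFA <- drawP("NELFA")
  bSer5p <- drawP("Ser5p")
  bSer2p <- bCtr9 & drawP("Ser2p")              # containment: Ser2p in Ctr9
  bK27 <- drawP("H3K27ac")
  bK4 <- drawP("H3K4me1")
  bErna <- bCtr9 & (stats::runif(nE) < profile@ernaProb[eClass])
  center <- eStart0 + eW / 2
  clamp <- function(x, lim) pmin(pmax(x, -lim), lim)
  nelfaSummit <- center + clamp(round(stats::rnorm(nE, 0, 50)), 300)
  pd <- profile@pairDistance
  d <- pmax(20, round(stats::rnorm(nE, pd[eClass, "mean"],
                                   pd[eClass, "sd"])))
  unilateral <- stats::runif(nE) < profile@unilateralFraction
  dir <- sample(c(-1L, 1L), nE, replace = TRUE)
  ctr9Alt <- center + clamp(round(stats::rnorm(nE, 0, 100)), 300)

  paired <- bNELFA & bCtr9
  ctr9Summit1 <- ifelse(bCtr9,
                        ifelse(paired,
                               ifelse(unilateral, nelfaSummit + dir * d,
                                      nelfaSummit - d),
                               ctr9Alt), NA_real_)
  ctr9Summit2 <- ifelse(paired & !unilateral, nelfaSummit + d, NA_real_)
  pairDistance <- ifelse(paired, d, NA_real_)
  laterality <- ifelse(!bNELFA, NA_character_,
                       ifelse(!bCtr9, "none",
                              ifelse(unilateral, "unilateral", "bilateral")))

  # Ctr9 enhancer kernel mass calibrated to the target SE:TE density ratio
  nu <- cv$noisePerBp
  dSE <- cv$seBoundDensity
  pSE <- occ["SE", "Ctr9"]; pTE <- occ["TE", "Ctr9"]
  dTE <- ((pSE * dSE + nu) / profile@densityRatio - nu) / pTE
  ctr9Mass <- ifelse(eClass == "SE", dSE * gp$seWidth, dTE * gp$teWidth)
  ehw <- cv$enhancerPeakHalfWidth
  clampIn <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  lo <- eStart0 + ehw + 1L
  hi <- eEnd0 - ehw
  enhPeak <- function(f, sel, summit, mass) {
    s <- round(clampIn(summit[sel], lo[sel], hi[sel]))
    data.frame(chrom = feat$chrom[ei][sel], summit = s, start1 = s - ehw,
               end1 = s + ehw, mass = mass[sel],
               name = sprintf("%s_%s", f, enhIds[sel]),
               stringsAsFactors = FALSE)
  }
  otherSummit <- center + clamp(round(stats::rnorm(nE, 0, 100)), 300)
  emass <- function(f) {
    ifelse(eClass == "SE", profile@coverage$enhKernelMass$SE[[f]],
           profile@coverage$enhKernelMass$TE[[f]])
  }
  p1 <- which(bCtr9)
  p2 <- which(!is.na(ctr9Summit2))
  m1 <- ctr9Mass
  m1[p2] <- m1[p2] / 2                         # split mass over the pair
  ctr9Enh <- rbind(
    enhPeak("Ctr9", p1, ctr9Summit1, m1),
    if (length(p2) > 0L) {
      x <- enhPeak("Ctr9", p2, ctr9Summit2, ctr9Mass / 2)
      x$name <- paste0(x$name, "_b")
      x
    })
  peakTables$Ctr9 <- rbind(peakTables$Ctr9, ctr9Enh)
  peakTables$NELFA <- rbind(peakTables$NELFA,
                            enhPeak("NELFA", which(bNELFA), nelfaSummit,
                                    emass("NELFA")))
  peakTables$Ser5p <- rbind(peakTables$Ser5p,
                            enhPeak("Ser5p", which(bSer5p), otherSummit,
                                    emass("Ser5p")))
  peakTables$Ser2p <- rbind(peakTables$Ser2p,
                            enhPeak("Ser2p", which(bSer2p), otherSummit,
                                    emass("Ser2p")))
  histPeak <- function(f, sel) {
    data.frame(chrom = feat$chrom[ei][sel], summit = round(center[sel]),
               start1 = eStart0[sel] + 1L, end1 = eEnd0[sel],
               mass = cv$histoneDensity[[f]] * eW[sel],
               name = sprintf("%s_%s", f, enhIds[sel]),
               stringsAsFactors = FALSE)
  }
  peakTables$H3K27ac <- rbind(peakTables$H3K27ac,
                              histPeak("H3K27ac", which(bK27)))
  peakTables$H3K4me1 <- histPeak("H3K4me1", which(bK4))

  peaks <- lapply(names(peakTables), function(f) {
    tb <- peakTables[[f]]
    gr <- GenomicRanges::GRanges(
      seqnames = tb$chrom,
      ranges = IRanges::IRanges(start = tb$start1, end = tb$end1),
      seqlengths = sizes)
    gr$name <- tb$name
    gr$score <- round(tb$mass / 100)
    gr$signalValue <- tb$mass
    gr$pValue <- rep(-1, nrow(tb))
    gr$qValue <- rep(-1, nrow(tb))
    gr$peak <- as.integer(tb$summit - tb$start1)
    gr$summit <- as.integer(tb$summit)
    gr$factor <- rep(f, nrow(tb))
    gr
  })
  names(peaks) <- names(peakTables)

  ## ---- eRNA intervals ----
  ernaSel <- which(bErna)
  ernas <- GenomicRanges::GRanges(
    seqnames = feat$chrom[ei][ernaSel],
    ranges = IRanges::IRanges(
      start = round(center[ernaSel]) - cv$ernaHalfWidth + 1L,
      end = round(center[ernaSel]) + cv$ernaHalfWidth),
    seqlengths = sizes)
  if (length(ernaSel) > 0L) {
    ernas$name <- sprintf("erna_%s", enhIds[ernaSel])
    ernas$score <- rep(0, length(ernaSel))
  }

  ## ---- enhancer target genes ----
  tgt <- split(geneIds[!is.na(assocEnh)], assocEnh[!is.na(assocEnh)])
  enhancers$target_genes <- IRanges::CharacterList(
    lapply(enhIds, function(id) unname(tgt[[id]] %||% character())))

  ## ---- coverage tracks ----
  tracks <- list()
  if (withTracks) {
    bw <- cv$binWidth
    khw <- cv$kernelHalfWidth
    mkNoise <- function() {
      lapply(sizes, function(s) {
        stats::rpois(as.integer(s / bw), cv$noisePerBp * bw) / bw
      })
    }
    for (f in c("NELFA", "Ser5p", "Ser2p", "Ctr9")) {
      tb <- peakTables[[f]]
      v <- .addTriangularKernels(mkNoise(), tb$chrom, tb$summit, tb$mass,
                                 bw, khw)
      tracks[[f]] <- SignalTrack(v, bw)
    }
    for (f in c("H3K27ac", "H3K4me1")) {
      v <- mkNoise()
      # promoter marks are focal kernels, enhancer domains are uniform
      tb <- peakTables[[f]]
      focal <- tb$end1 - tb$start1 + 1L < 2L * khw * 3L
      v <- .addTriangularKernels(v, tb$chrom[focal], tb$summit[focal],
                                 tb$mass[focal], bw, khw)
      v <- .addUniformDomains(v, tb$chrom[!focal], tb$start1[!focal],
                              tb$end1[!focal], tb$mass[!focal], bw)
      tracks[[f]] <- SignalTrack(v, bw)
    }
    # knockdown Ser2p: enhancer-local signal divided by the class divisor
    vkd <- trackValues(tracks$Ser2p)
    div <- kd$ser2pDivisor[eClass]
    for (i in seq_len(nE)) {
      ch <- feat$chrom[ei][i]
      b0 <- as.integer(eStart0[i] / bw) + 1L
      b1 <- as.integer(eEnd0[i] / bw)
      vkd[[ch]][b0:b1] <- vkd[[ch]][b0:b1] / div[i]
    }
    tracks$Ser2p_kd <- SignalTrack(vkd, bw)
  }

  ## ---- plant map ----
  plant <- list(
    genes = data.frame(gene_id = geneIds, chrom = feat$chrom[gi],
                       strand = gStrand, tss = as.integer(tss),
                       tes = as.integer(tes), category = category,
                       tpm_control = tpmCtrl, tpm_knockdown = tpmKd,
                       lfc = lfc, down = down, group = group,
                       off_NELFA = geneOffsets[, "NELFA"],
                       off_Ser5p = geneOffsets[, "Ser5p"],
                       off_Ctr9 = geneOffsets[, "Ctr9"],
                       stringsAsFactors = FALSE),
    enhancers = data.frame(enh_id = enhIds, chrom = feat$chrom[ei],
                           start = as.integer(eStart0 + 1L),
                           end = as.integer(eEnd0), class = eClass,
                           Ctr9 = bCtr9, NELFA = bNELFA, Ser5p = bSer5p,
                           Ser2p = bSer2p, H3K27ac = bK27, H3K4me1 = bK4,
                           erna = bErna,
                           nelfa_summit = ifelse(bNELFA,
                                                 round(nelfaSummit), NA),
                           ctr9_summit_1 = round(ctr9Summit1),
                           ctr9_summit_2 = round(ctr9Summit2),
                           pair_distance = pairDistance,
                           laterality = laterality,
                           ctr9_mass = ifelse(bCtr9, ctr9Mass, 0),
                           stringsAsFactors = FALSE),
    params = list(profile = profile@name, seed = seed,
                  teBoundDensity = dTE, seBoundDensity = dSE,
                  noisePerBp = nu, ser2pDivisor = kd$ser2pDivisor,
                  downFraction = kd$downFraction))

  methods::new("SyntheticDataset", genomeSizes = sizes, genes = genes,
               enhancers = enhancers, peaks = peaks, tracks = tracks,
               expression = expression, ernas = ernas, plantMap = plant,
               profileName = profile@name, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# nearest-enhancer association used to plant gene groups: distance from the
# TSS to the nearest region edge (0 inside), SE beats TE at equal distance.
.plantGroups <- function(geneChrom, tss, enhChrom, enhStart, enhEnd,
                         enhClass, maxDistance) {
  n <- length(tss)
  bestD <- rep(Inf, n)
  bestClass <- rep(NA_character_, n)
  bestEnh <- rep(NA_integer_, n)
  for (cls in c("TE", "SE")) {       # SE processed last wins ties (<=)
    for (ch in unique(geneChrom)) {
      gsel <- which(geneChrom == ch)
      esel <- which(enhChrom == ch & enhClass == cls)
      if (length(esel) == 0L) next
      o <- esel[order(enhStart[esel])]
      s <- enhStart[o]; e <- enhEnd[o]
      idx <- findInterval(tss[gsel], s)
      dPrev <- ifelse(idx >= 1L,
                      pmax(0, tss[gsel] - e[pmax(idx, 1L)]), Inf)
      dNext <- ifelse(idx < length(s),
                      s[pmin(idx + 1L, length(s))] - tss[gsel], Inf)
      d <- pmin(dPrev, dNext)
      which_ <- ifelse(dPrev <= dNext, pmax(idx, 1L),
                       pmin(idx + 1L, length(s)))
      upd <- d <= bestD[gsel]
      bestD[gsel][upd] <- d[upd]
      bestClass[gsel][upd] <- cls
      bestEnh[gsel][upd] <- o[which_[upd]]
    }
  }
  group <- ifelse(is.infinite(bestD) | bestD > maxDistance, "other",
                  bestClass)
  enhId <- ifelse(group == "other", NA_integer_, bestEnh)
  structure(group,
            enh_id = ifelse(is.na(enhId), NA_character_,
                            sprintf("enh_%05d", enhId)))
}

# add symmetric triangular kernels (total mass exactly `mass` per peak)
# onto per-bp binned values
.addTriangularKernels <- function(values, chrom, summit1, mass, bw, khw) {
  if (length(chrom) == 0L) return(values)
  K <- as.integer(ceiling(khw / bw))
  offs <- -K:K
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    v <- values[[ch]]
    nb <- length(v)
    s0 <- summit1[sel] - 0.5
    sbin <- floor(s0 / bw)
    wts <- vapply(offs, function(k) {
      pmax(0, 1 - abs((sbin + k + 0.5) * bw - s0) / khw)
    }, numeric(length(sel)))
    wts <- matrix(wts, nrow = length(sel))
    wts <- wts / rowSums(wts)
    idx <- rep(sbin + 1L, times = length(offs)) +
      rep(offs, each = length(sel))
    val <- as.vector(wts) * mass[sel] / bw
    ok <- idx >= 1L & idx <= nb & val > 0
    acc <- rowsum(val[ok], idx[ok])
    v[as.integer(rownames(acc))] <- v[as.integer(rownames(acc))] + acc[, 1L]
    values[[ch]] <- v
  }
  values
}

# add uniform signal of total mass `mass` over [start1, end1]
.addUniformDomains <- function(values, chrom, start1, end1, mass, bw) {
  for (i in seq_along(chrom)) {
    ch <- chrom[i]
    b0 <- as.integer((start1[i] - 1L) / bw) + 1L
    b1 <- as.integer(end1[i] / bw)
    values[[ch]][b0:b1] <- values[[ch]][b0:b1] +
      mass[i] / (end1[i] - start1[i] + 1L)
  }
  values
}

#' Simulate a grouped knockdown expression experiment
#'
#' Draws expressed genes in three enhancer-association groups (`SE`, `TE`,
#' `other`) and applies the profile's knockdown effect model: each gene is
#' down-regulated with its group's probability (log2 effect magnitudes
#' drawn from truncated normals), otherwise mildly up-regulated, so the
#' planted fraction of decreased genes per group equals the profile's
#' down-fraction in expectation.
#'
#' @param profile A [CalibrationProfile-class].
#' @param nPerGroup Number of genes per association group.
#' @param seed Integer seed.
#' @return data.frame with `gene_id`, `group`, `tpm_control`,
#'   `tpm_knockdown`, `lfc`, `down`.
#' @export
simulateExpression <- function(profile, nPerGroup = 2000L, seed = 1L) {
  withSeed(seed, {
    ex <- profile@expression
    kd <- profile@knockdown
    groups <- names(kd$downFraction)
    n <- nPerGroup * length(groups)
    group <- rep(groups, each = nPerGroup)
    level <- sample(names(ex$levels), n, replace = TRUE,
                    prob = ex$levelProb)
    tpmCtrl <- pmax(1, ex$levels[level] *
                       exp(stats::rnorm(n, 0, ex$sdLog)))
    down <- stats::runif(n) < kd$downFraction[group]
    lfc <- numeric(n)
    lfc[down] <- -pmax(kd$downLog2[["min"]],
                       stats::rnorm(sum(down), kd$downLog2[["mean"]],
                                    kd$downLog2[["sd"]]))
    lfc[!down] <- pmax(kd$upLog2[["min"]],
                       stats::rnorm(sum(!down), kd$upLog2[["mean"]],
                                    kd$upLog2[["sd"]]))
    data.frame(gene_id = sprintf("gene_%05d", seq_len(n)), group = group,
               tpm_control = unname(tpmCtrl),
               tpm_knockdown = unname(tpmCtrl * 2^lfc),
               lfc = lfc, down = down, stringsAsFactors = FALSE)
  })
}

#' Write a synthetic dataset to disk
#'
#' Serializes every component in the plain-text formats the package reads:
#' chromosome sizes and gene/expression TSVs, enhancer and eRNA BED,
#' per-factor narrowPeak, per-track bedGraph, and the plant map as JSON.
#'
#' @param dataset A [SyntheticDataset-class].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
writeDataset <- function(dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(chrom_sizes = file.path(outdir, "chrom_sizes.tsv"),
             genes = file.path(outdir, "genes.tsv"),
             enhancers = file.path(outdir, "enhancers.bed"),
             expression = file.path(outdir, "expression.tsv"),
             ernas = file.path(outdir, "ernas.bed"),
             plant_map = file.path(outdir, "plant_map.json"))
  utils::write.table(
    data.frame(chrom = names(genomeSizes(dataset)),
               size = unname(genomeSizes(dataset))),
    paths[["chrom_sizes"]], sep = "\t", quote = FALSE, row.names = FALSE)
  writeGeneTable(datasetGenes(dataset), paths[["genes"]])
  writeEnhancerBed(datasetEnhancers(dataset), paths[["enhancers"]])
  writeExpressionTable(datasetExpression(dataset), paths[["expression"]])
  writeBed(datasetErnas(dataset), paths[["ernas"]])
  for (f in names(datasetPeaks(dataset))) {
    p <- file.path(outdir, sprintf("peaks_%s.narrowPeak", f))
    writeNarrowPeak(datasetPeaks(dataset)[[f]], p)
    paths[[paste0("peaks_", f)]] <- p
  }
  for (tn in names(datasetTracks(dataset))) {
    p <- file.path(outdir, sprintf("track_%s.bedGraph", tn))
    writeBedGraph(datasetTracks(dataset)[[tn]], p)
    paths[[paste0("track_", tn)]] <- p
  }
  pm <- plantMap(dataset)
  jsonlite::write_json(pm, paths[["plant_map"]], dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}
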