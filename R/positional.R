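#' Signed summit-to-TSS offset
#'
#' Distance in bp from the TSS to a peak summit on the strand-corrected
#' axis: positive downstream of the TSS. `(summit - tss)` on the plus
#' strand, `(tss - summit)` on the minus strand.
#'
#' @param summit Absolute summit position(s), 1-based.
#' @param tss TSS position(s), 1-based.
#' @param strand `"+"` or `"-"` (vectorized).
#' @param chromPeak,chromGene Optional chromosome names; a mismatch is an
#'   error.
#' @return Signed offset(s) in bp.
#' @examples
#' summitTssOffset(1184, 1000, "+")  # +184
#' summitTssOffset(1979, 2000, "-")  # +21
#' @export
summitTssOffset <- function(summit, tss, strand, chromPeak = NULL,
                            chromGene = NULL) {
  if (!is.null(chromPeak) && !is.null(chromGene) &&
      any(chromPeak != chromGene)) {
    stop("peak and gene are on different chromosomes", call. = FALSE)
  }
  ifelse(strand == "+", summit - tss, tss - summit)
}

#' Summit-to-TSS offset summary for one factor
#'
#' Assigns each peak to the gene whose TSS is nearest to its summit (ties
#' broken toward the smaller TSS coordinate), keeps assignments with
#' absolute offset within `assignmentWindow`, and summarizes the signed
#' strand-corrected offsets.
#'
#' @param peaks `GRanges` with `summit` metadata.
#' @param genes `GRanges` from [readGeneTable()].
#' @param assignmentWindow Maximum absolute offset in bp (default 2000).
#' @return List of class `"OffsetSummary"`: `factor`, `n`, `offsets`
#'   (the retained signed offsets), `mean`, `median`, `q25`, `q75`. When
#'   no peak is assigned, `n = 0` and the statistics are `NA` (an
#'   empty-summary sentinel, not an error).
#' @export
factorOffsetSummary <- function(peaks, genes, assignmentWindow = 2000L) {
  fct <- if (!is.null(peaks$factor) && length(peaks) > 0L)
    peaks$factor[1L] else NA_character_
  offsets <- numeric()
  pChrom <- as.character(GenomicRanges::seqnames(peaks))
  gChrom <- as.character(GenomicRanges::seqnames(genes))
  for (ch in intersect(unique(pChrom), unique(gChrom))) {
    psel <- which(pChrom == ch)
    gsel <- which(gChrom == ch)
    o <- gsel[order(genes$tss[gsel])]
    tssSorted <- genes$tss[o]
    strandSorted <- as.character(GenomicRanges::strand(genes))[o]
    s <- peaks$summit[psel]
    idx <- findInterval(s, tssSorted)
    dPrev <- ifelse(idx >= 1L, s - tssSorted[pmax(idx, 1L)], Inf)
    dNext <- ifelse(idx < length(tssSorted),
                    tssSorted[pmin(idx + 1L, length(tssSorted))] - s, Inf)
    # tie (equidistant TSSs) goes to the smaller TSS coordinate
    pick <- ifelse(dPrev <= dNext, pmax(idx, 1L),
                   pmin(idx + 1L, length(tssSorted)))
    off <- summitTssOffset(s, tssSorted[pick], strandSorted[pick])
    offsets <- c(offsets, off[abs(off) <= assignmentWindow &
                                is.finite(off)])
  }
  structure(list(
    factor = fct, n = length(offsets), offsets = offsets,
    mean = if (length(offsets) > 0L) mean(offsets) else NA_real_,
    median = if (length(offsets) > 0L) stats::median(offsets) else NA_real_,
    q25 = if (length(offsets) > 0L)
      unname(stats::quantile(offsets, 0.25)) else NA_real_,
    q75 = if (length(offsets) > 0L)
      unname(stats::quantile(offsets, 0.75)) else NA_real_),
    class = "OffsetSummary")
}

#' @export
print.OffsetSummary <- function(x, ...) {
  cat(sprintf("OffsetSummary (%s): n=%d", x$factor, x$n))
  if (x$n > 0L) {
    cat(sprintf(", mean=%.2f bp, median=%.1f bp [%.1f, %.1f]",
                x$mean, x$median, x$q25, x$q75))
  }
  cat("\n")
  invisible(x)
}

#' Pair NELFA and Ctr9 summits on enhancers
#'
#' For every region containing at least one NELFA peak, anchors on the
#' summit of the strongest NELFA peak and finds the nearest Ctr9 summit
#' inside the region (ties toward the smaller coordinate). Laterality is
#' `"none"` with no in-region Ctr9 summit, `"bilateral"` when Ctr9
#' summits flank the NELFA summit on both sides, otherwise
#' `"unilateral"`.
#'
#' @param regions `GRanges` with ids (`enh_id` or `name`).
#' @param nelfa,ctr9 `GRanges` of peaks with `summit` and `score`.
#' @return data.frame with `region_id`, `enh_class` (if present on the
#'   regions), `nelfa_summit`, `ctr9_summit`, `distance` (unsigned bp,
#'   `NA` for laterality `"none"`), `laterality`.
#' @export
pairNelfaCtr9 <- function(regions, nelfa, ctr9) {
  ids <- .regionIds(regions)
  nelfaSummit <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(nelfa),
    ranges = IRanges::IRanges(start = nelfa$summit, width = 1L))
  ctr9Summit <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(ctr9),
    ranges = IRanges::IRanges(start = ctr9$summit, width = 1L))
  nh <- GenomicRanges::findOverlaps(regions, nelfaSummit,
                                    ignore.strand = TRUE)
  ch <- GenomicRanges::findOverlaps(regions, ctr9Summit,
                                    ignore.strand = TRUE)
  q1 <- S4Vectors::queryHits(nh)
  s1 <- S4Vectors::subjectHits(nh)
  # anchor: strongest NELFA peak per region; ties toward the smaller summit
  ord1 <- order(q1, -nelfa$score[s1], nelfa$summit[s1])
  keep1 <- !duplicated(q1[ord1])
  ri <- q1[ord1][keep1]
  anchor <- nelfa$summit[s1][ord1][keep1]
  anchorOf <- rep(NA_real_, length(regions))
  anchorOf[ri] <- anchor
  # nearest in-region Ctr9 summit; ties toward the smaller coordinate
  q2 <- S4Vectors::queryHits(ch)
  s2 <- S4Vectors::subjectHits(ch)
  hit <- q2 %in% ri
  q2 <- q2[hit]
  cs <- ctr9$summit[s2[hit]]
  d <- abs(cs - anchorOf[q2])
  ord2 <- order(q2, d, cs)
  keep2 <- !duplicated(q2[ord2])
  bestQ <- q2[ord2][keep2]
  bestSummit <- rep(NA_real_, length(regions))
  bestDist <- rep(NA_real_, length(regions))
  bestSummit[bestQ] <- cs[ord2][keep2]
  bestDist[bestQ] <- d[ord2][keep2]
  sides <- rowsum(cbind(cs < anchorOf[q2], cs > anchorOf[q2]) + 0, q2)
  bilateralOf <- rep(FALSE, length(regions))
  bilateralOf[as.integer(rownames(sides))] <- sides[, 1L] > 0 &
    sides[, 2L] > 0
  lat <- as.character(ifelse(is.na(bestSummit[ri]), "none",
                             ifelse(bilateralOf[ri], "bilateral",
                                    "unilateral")))
  res <- data.frame(
    region_id = ids[ri], nelfa_summit = anchor,
    ctr9_summit = bestSummit[ri], distance = bestDist[ri],
    laterality = lat, stringsAsFactors = FALSE)
  if (!is.null(regions$enh_class)) {
    res$enh_class <- regions$enh_class[match(res$region_id, ids)]
  }
  res$chrom <- as.character(
    GenomicRanges::seqnames(regions))[match(res$region_id, ids)]
  res
}
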