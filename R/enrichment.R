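#' Per-region occupancy density
#'
#' Signal mass of a track over each region (length-weighted at partial
#' edge bins) divided by region length in bp. Regions on chromosomes
#' absent from the track get density 0 with a warning.
#'
#' @param track A [SignalTrack-class] (conventionally rpm-normalized).
#' @param regions `GRanges`; `enh_class` metadata is carried through.
#' @return data.frame with `region_id`, `enh_class` (if present),
#'   `density` (signal per bp) and `count` (total signal mass).
#' @export
regionDensity <- function(track, regions) {
  counts <- binnedMass(track, regions)
  out <- data.frame(region_id = .regionIds(regions),
                    density = counts / GenomicRanges::width(regions),
                    count = counts, stringsAsFactors = FALSE)
  if (!is.null(regions$enh_class)) {
    out <- cbind(out[1L], enh_class = regions$enh_class, out[-1L])
  }
  out
}

#' Compare occupancy densities between two region classes
#'
#' Fold change of class means plus a two-sided Wilcoxon rank-sum p-value.
#' Small samples without ties use the exact rank-sum distribution; small
#' samples with ties use full enumeration over rank assignments; larger
#' samples use the normal approximation with tie correction (switchover
#' at a combined n of 50).
#'
#' @param densities data.frame from [regionDensity()] with an `enh_class`
#'   column, or any data.frame with `enh_class` and a `density` column.
#' @param classA,classB Class labels to contrast (fold = mean A / mean B).
#' @param value Column to compare (default `"density"`).
#' @return List: `fold` (NA sentinel when mean B is 0), `p`, `nA`, `nB`,
#'   `meanA`, `meanB`.
#' @export
compareClasses <- function(densities, classA = "SE", classB = "TE",
                           value = "density") {
  a <- densities[[value]][densities$enh_class == classA]
  b <- densities[[value]][densities$enh_class == classB]
  if (length(a) == 0L || length(b) == 0L) {
    .stopf("class '%s' is empty", if (length(a) == 0L) classA else classB)
  }
  fold <- if (mean(b) == 0) NA_real_ else mean(a) / mean(b)
  list(fold = fold, p = rankSumP(a, b), nA = length(a), nB = length(b),
       meanA = mean(a), meanB = mean(b))
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact distribution (tie-free, combined n <= 50), full enumeration over
#' rank assignments (ties, combined n <= 14), otherwise normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b Numeric samples.
#' @return Two-sided p-value.
#' @export
rankSumP <- function(a, b) {
  n <- length(a) + length(b)
  ties <- anyDuplicated(c(a, b)) > 0L
  if (!ties && n <= 50L) {
    return(stats::wilcox.test(a, b, exact = TRUE)$p.value)
  }
  if (ties && n <= 14L) {
    return(.rankSumEnumerate(a, b))
  }
  suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                      correct = TRUE)$p.value)
}

# exact two-sided p by enumerating all C(n, nA) rank assignments
# (average ranks for ties); p = min(1, 2 * min(P(W <= w), P(W >= w)))
.rankSumEnumerate <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  nA <- length(a)
  wObs <- sum(r[seq_len(nA)])
  combos <- utils::combn(length(pooled), nA)
  ws <- colSums(matrix(r[combos], nrow = nA))
  eps <- 1e-9
  pLow <- mean(ws <= wObs + eps)
  pHigh <- mean(ws >= wObs - eps)
  min(1, 2 * min(pLow, pHigh))
}

#' Length-matched shuffled control intervals
#'
#' Places one random interval per input region: identical length, on a
#' uniformly chosen chromosome among those long enough to host it, at a
#' uniform start position. Deterministic for a fixed seed; the output
#' length multiset equals the input's exactly.
#'
#' @param regions `GRanges`.
#' @param genome Named vector of chromosome lengths in bp.
#' @param seed Integer seed.
#' @return `GRanges` of shuffled intervals (same count as input).
#' @export
shuffleIntervals <- function(regions, genome, seed) {
  lens <- GenomicRanges::width(regions)
  tooLong <- lens > max(genome)
  if (any(tooLong)) {
    .stopf("region %s (length %d) is longer than every chromosome",
           .regionIds(regions)[which(tooLong)[1L]],
           lens[which(tooLong)[1L]])
  }
  withSeed(seed, {
    chromIdx <- vapply(lens, function(l) {
      ok <- which(genome >= l)
      if (length(ok) == 1L) ok else sample(ok, 1L)
    }, integer(1L))
    maxStart <- genome[chromIdx] - lens + 1
    starts <- floor(stats::runif(length(lens)) * maxStart) + 1
    GenomicRanges::GRanges(
      seqnames = names(genome)[chromIdx],
      ranges = IRanges::IRanges(start = as.integer(starts), width = lens))
  })
}

#' Knockdown occupancy fold change per region class
#'
#' Per class: the median of per-region signal counts under each condition
#' and their ratio (control / knockdown), the estimator used for
#' knockdown occupancy contrasts.
#'
#' @param trackControl,trackKnockdown [SignalTrack-class] objects
#'   (conventionally both rpm-normalized).
#' @param regions `GRanges` with an `enh_class` metadata column, or a
#'   named list of `GRanges` per class.
#' @return data.frame with `class`, `n`, `median_control`, `median_kd`,
#'   `fold` (NA sentinel when the knockdown median is 0).
#' @export
occupancyFoldChange <- function(trackControl, trackKnockdown, regions) {
  if (methods::is(regions, "GRanges")) {
    stopifnot(!is.null(regions$enh_class))
    regions <- split(regions, regions$enh_class)
  }
  out <- lapply(names(regions), function(cls) {
    r <- regions[[cls]]
    cc <- binnedMass(trackControl, r)
    ck <- binnedMass(trackKnockdown, r)
    mc <- stats::median(cc)
    mk <- stats::median(ck)
    data.frame(class = cls, n = length(r), median_control = mc,
               median_kd = mk,
               fold = if (mk == 0) NA_real_ else mc / mk,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
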