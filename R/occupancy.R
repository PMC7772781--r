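#' 1-bp interval intersection
#'
#' Two intervals intersect when they share a chromosome and overlap by at
#' least 1 bp — the criterion used throughout for occupancy calls.
#' Vectorized element-wise over two equal-length (or recyclable) `GRanges`.
#'
#' @param a,b `GRanges`.
#' @return Logical vector.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 300))
#' intervalsOverlap(a, b)  # TRUE: exactly 1 bp shared
#' @export
intervalsOverlap <- function(a, b) {
  as.logical(IRanges::poverlaps(a, b, minoverlap = 1L))
}

#' Call factor occupancy over regions
#'
#' A region is bound by a factor when at least one peak of that factor
#' intersects it by >= 1 bp. Uses interval-tree overlap internally; the
#' result equals the all-pairs scan by construction (property-tested).
#'
#' @param regions `GRanges` with unique ids in `enh_id` (or `name`)
#'   metadata; plain unnamed regions get `region_<i>` ids.
#' @param peaksByFactor Named list, factor label -> `GRanges` of peaks.
#' @return An [OccupancyMatrix-class].
#' @export
callOccupancy <- function(regions, peaksByFactor) {
  ids <- .regionIds(regions)
  if (anyDuplicated(ids)) {
    .stopf("duplicate region ids: %s",
           paste(unique(ids[duplicated(ids)])[1:3], collapse = ", "))
  }
  factors <- names(peaksByFactor)
  if (is.null(factors) || any(!nzchar(factors))) {
    stop("'peaksByFactor' must be a named list")
  }
  calls <- matrix(FALSE, nrow = length(regions), ncol = length(factors),
                  dimnames = list(ids, factors))
  provenance <- vector("list", length(factors))
  names(provenance) <- factors
  for (f in factors) {
    pk <- peaksByFactor[[f]]
    if (length(pk) == 0L) {
      provenance[[f]] <- list()
      next
    }
    hits <- GenomicRanges::findOverlaps(regions, pk, minoverlap = 1L,
                                        ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits)
    calls[unique(q), f] <- TRUE
    nm <- if (!is.null(pk$name)) pk$name else
      sprintf("%s_peak_%d", f, seq_along(pk))
    provenance[[f]] <- lapply(
      split(nm[S4Vectors::subjectHits(hits)], ids[q]), unname)
  }
  methods::new("OccupancyMatrix", calls = calls, provenance = provenance)
}

.regionIds <- function(regions) {
  if (!is.null(regions$enh_id)) as.character(regions$enh_id)
  else if (!is.null(regions$name)) as.character(regions$name)
  else sprintf("region_%d", seq_along(regions))
}

#' Annotate peaks by genomic context
#'
#' A peak is genic when it intersects any gene span extended by
#' `genicFlank` on both sides; otherwise intergenic. The sub-context is
#' decided by the summit position with precedence TSS > TES > gene body:
#' within +/- `tssWindow` of a TSS -> `"TSS"`; within +/- `tssWindow` of a
#' TES -> `"TES"`; inside a gene span -> `"gene_body"`; else
#' `"intergenic"`.
#'
#' @param peaks `GRanges` with a `summit` metadata column (absolute
#'   1-based positions, as from [readNarrowPeak()]).
#' @param genes `GRanges` from [readGeneTable()].
#' @param genicFlank Flank in bp added to gene spans for the
#'   genic/intergenic call (default 2000).
#' @param tssWindow Half-width of the TSS/TES windows (default 1000).
#' @return data.frame with columns `name`, `context`
#'   (`genic`/`intergenic`) and `subcontext`.
#' @export
annotatePeaks <- function(peaks, genes, genicFlank = 2000L,
                          tssWindow = 1000L) {
  stopifnot(genicFlank >= 0)
  ext <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(genes),
    ranges = IRanges::IRanges(
      start = pmax(1L, GenomicRanges::start(genes) - genicFlank),
      end = GenomicRanges::end(genes) + genicFlank))
  genic <- GenomicRanges::countOverlaps(peaks, ext,
                                        ignore.strand = TRUE) > 0L
  summit <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(peaks),
    ranges = IRanges::IRanges(start = peaks$summit, width = 1L))
  win <- function(pos) {
    GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(genes),
      ranges = IRanges::IRanges(start = pmax(1L, pos - tssWindow),
                                end = pos + tssWindow))
  }
  inTSS <- GenomicRanges::countOverlaps(summit, win(genes$tss),
                                        ignore.strand = TRUE) > 0L
  inTES <- GenomicRanges::countOverlaps(summit, win(genes$tes),
                                        ignore.strand = TRUE) > 0L
  inBody <- GenomicRanges::countOverlaps(summit, genes,
                                         ignore.strand = TRUE) > 0L
  sub <- ifelse(inTSS, "TSS",
                ifelse(inTES, "TES",
                       ifelse(inBody, "gene_body", "intergenic")))
  data.frame(
    name = if (!is.null(peaks$name)) peaks$name
           else sprintf("peak_%d", seq_along(peaks)),
    context = ifelse(genic, "genic", "intergenic"),
    subcontext = sub, stringsAsFactors = FALSE)
}

#' Classify enhancer chromatin states
#'
#' From an occupancy matrix: `active` when H3K27ac is present, `poised`
#' when H3K4me1 is present without H3K27ac, `unmarked` otherwise. The
#' three states partition the regions.
#'
#' @param matrix An [OccupancyMatrix-class] containing `H3K27ac` and
#'   `H3K4me1` columns (and optionally `Ctr9`).
#' @return data.frame with `region_id`, `state`, `ctr9_bound` (`NA` when
#'   the matrix has no Ctr9 column).
#' @export
classifyStates <- function(matrix) {
  calls <- occupancyCalls(matrix)
  for (f in c("H3K27ac", "H3K4me1")) {
    if (!f %in% colnames(calls)) {
      .stopf("occupancy matrix is missing required factor column '%s'", f)
    }
  }
  state <- ifelse(calls[, "H3K27ac"], "active",
                  ifelse(calls[, "H3K4me1"], "poised", "unmarked"))
  data.frame(region_id = rownames(calls), state = state,
             ctr9_bound = if ("Ctr9" %in% colnames(calls))
               calls[, "Ctr9"] else NA,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Venn subset counts over factors
#'
#' Counts regions in each of the `2^k` presence/absence subsets of the
#' requested factors (disjoint subsets; counts sum to the region count).
#'
#' @param matrix An [OccupancyMatrix-class].
#' @param factors Character vector of factor columns.
#' @return Named integer vector; names like `"Ctr9+H3K27ac-"`.
#' @export
vennCounts <- function(matrix, factors) {
  calls <- occupancyCalls(matrix)
  missing <- setdiff(factors, colnames(calls))
  if (length(missing) > 0L) {
    .stopf("occupancy matrix is missing required factor column '%s'",
           missing[1L])
  }
  sub <- calls[, factors, drop = FALSE]
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), length(factors)))
  colnames(combos) <- factors
  counts <- apply(combos, 1L, function(row) {
    sum(apply(sub, 1L, function(x) all(x == row)))
  })
  names(counts) <- apply(combos, 1L, function(row) {
    paste0(factors, ifelse(row, "+", "-"), collapse = "")
  })
  counts
}

#' Predict active enhancers from H3K27ac + Ctr9 co-occupancy
#'
#' Nominates H3K27ac peak intervals that (i) intersect at least one Ctr9
#' peak and (ii) do not intersect any promoter window (TSS +/-
#' `promoterExclusion`); overlapping survivors are merged and the result
#' sorted.
#'
#' @param h3k27ac,ctr9 `GRanges` of peaks.
#' @param genes `GRanges` from [readGeneTable()].
#' @param promoterExclusion Half-width of the promoter window around each
#'   TSS (default 1000 bp).
#' @return Sorted `GRanges` of predicted active-enhancer intervals.
#' @export
predictActiveEnhancers <- function(h3k27ac, ctr9, genes,
                                   promoterExclusion = 1000L) {
  stopifnot(promoterExclusion >= 0)
  if (length(ctr9) == 0L || length(h3k27ac) == 0L) {
    return(GenomicRanges::GRanges())
  }
  co <- GenomicRanges::countOverlaps(h3k27ac, ctr9, minoverlap = 1L,
                                     ignore.strand = TRUE) > 0L
  prom <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(genes),
    ranges = IRanges::IRanges(
      start = pmax(1L, genes$tss - promoterExclusion),
      end = genes$tss + promoterExclusion))
  nearProm <- GenomicRanges::countOverlaps(h3k27ac, prom,
                                           ignore.strand = TRUE) > 0L
  survivors <- h3k27ac[co & !nearProm]
  out <- GenomicRanges::reduce(GenomicRanges::granges(survivors),
                               ignore.strand = TRUE)
  BiocGenerics::sort(out, ignore.strand = TRUE)
}
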