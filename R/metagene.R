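#' Expression strata
#'
#' Splits genes into four expression categories: `silent` (control tpm
#' below the expressed threshold), and the remaining genes ranked by tpm
#' into `high` (top 25%), `medium` (middle 50%) and `low` (bottom 25%).
#' Quartile boundaries are by rank, ties broken by gene id.
#'
#' @param expression data.frame with `gene_id` and `tpm_control`.
#' @param threshold Expressed threshold in tpm (default 1).
#' @return Named list of gene-id character vectors: `high`, `medium`,
#'   `low`, `silent` (a disjoint cover of all genes).
#' @export
expressionStrata <- function(expression, threshold = 1.0) {
  if (nrow(expression) == 0L) {
    stop("empty expression table", call. = FALSE)
  }
  silent <- expression$gene_id[expression$tpm_control < threshold]
  expr <- expression[expression$tpm_control >= threshold, , drop = FALSE]
  o <- order(-expr$tpm_control, expr$gene_id)
  ids <- expr$gene_id[o]
  n <- length(ids)
  nQ <- floor(n / 4)
  list(high = ids[seq_len(nQ)],
       medium = if (n > 2L * nQ) ids[seq(nQ + 1L, n - nQ)] else character(),
       low = if (nQ > 0L) ids[seq(n - nQ + 1L, n)] else character(),
       silent = silent)
}

# per-bp mean signal over arbitrary real-valued bin edges on one chromosome
.binDensities <- function(v, bw, edges) {
  m <- .prefixMass(v, bw, edges)
  diff(m) / diff(edges)
}

#' Scaled gene-body metagene profile
#'
#' For each gene: fixed-width flank bins upstream and downstream plus a
#' gene body resampled to `bodyBins` bins by length-weighted averaging on
#' the strand-corrected axis (minus-strand genes reversed). The profile is
#' the mean per-bp signal across genes, rescaled so the track total
#' corresponds to 10 million reads. Length-weighted resampling conserves
#' signal mass per gene exactly (up to the track's bin discretization).
#'
#' @param track A [SignalTrack-class].
#' @param genes `GRanges` from [readGeneTable()] (a gene set / stratum).
#' @param flankBp Flank width in bp (default 2000).
#' @param bodyBins Number of scaled gene-body bins (default 60).
#' @param flankBins Number of bins per flank (default 20).
#' @return List of class `"MetageneProfile"`: `values` (mean per-bp
#'   signal, length `2 * flankBins + bodyBins`), `n_genes`, `geometry`,
#'   and `perGeneMass` (profiled signal mass per used gene, on the output
#'   scale).
#' @export
scaledGeneProfile <- function(track, genes, flankBp = 2000L,
                              bodyBins = 60L, flankBins = 20L) {
  bw <- binWidth(track)
  vals <- trackValues(track)
  scale <- 1e7 / totalMass(track)
  if (trackNorm(track) == "rpm") scale <- 10
  nBins <- 2L * flankBins + bodyBins
  acc <- numeric(nBins)
  masses <- numeric()
  used <- 0L
  flankW <- flankBp / flankBins
  chrom <- as.character(GenomicRanges::seqnames(genes))
  strand <- as.character(GenomicRanges::strand(genes))
  for (i in seq_along(genes)) {
    len <- GenomicRanges::width(genes)[i]
    if (len < bodyBins) {
      .warnf("gene %s (%d bp) shorter than bodyBins; skipped",
             if (!is.null(genes$gene_id)) genes$gene_id[i]
             else as.character(i), len)
      next
    }
    v <- vals[[chrom[i]]]
    if (is.null(v)) next
    s0 <- GenomicRanges::start(genes)[i] - 1L
    e0 <- GenomicRanges::end(genes)[i]
    edges <- c(seq(s0 - flankBp, s0, by = flankW),
               seq(s0, e0, length.out = bodyBins + 1L)[-1L],
               seq(e0, e0 + flankBp, by = flankW)[-1L])
    dens <- .binDensities(v, bw, edges)
    if (strand[i] == "-") dens <- rev(dens)
    acc <- acc + dens
    masses <- c(masses, sum(dens * diff(edges)) * scale)
    used <- used + 1L
  }
  structure(list(
    values = if (used > 0L) acc / used * scale else rep(NA_real_, nBins),
    n_genes = used,
    geometry = list(flankBp = flankBp, bodyBins = bodyBins,
                    flankBins = flankBins),
    perGeneMass = masses), class = "MetageneProfile")
}

#' @export
print.MetageneProfile <- function(x, ...) {
  cat(sprintf("MetageneProfile: %d genes, %d bins (%d flank + %d body + %d flank)\n",
              x$n_genes, length(x$values), x$geometry$flankBins,
              x$geometry$bodyBins, x$geometry$flankBins))
  invisible(x)
}

#' Fixed-width TSS window profile
#'
#' Mean coverage per bin across genes in a window centered on the TSS,
#' strand-corrected (downstream to the right), at the track's bin width.
#'
#' @param track A [SignalTrack-class].
#' @param genes `GRanges` from [readGeneTable()].
#' @param windowBp Window width in bp (default 4000).
#' @return Numeric vector of `windowBp / binWidth` mean per-bp values;
#'   names give the bin-center offset from the TSS.
#' @export
tssWindowProfile <- function(track, genes, windowBp = 4000L) {
  bw <- binWidth(track)
  vals <- trackValues(track)
  nb <- as.integer(windowBp / bw)
  half <- windowBp / 2
  acc <- numeric(nb)
  used <- 0L
  chrom <- as.character(GenomicRanges::seqnames(genes))
  strand <- as.character(GenomicRanges::strand(genes))
  for (i in seq_along(genes)) {
    v <- vals[[chrom[i]]]
    if (is.null(v)) next
    t0 <- genes$tss[i] - 0.5           # continuous TSS coordinate
    edges <- seq(t0 - half, t0 + half, by = bw)
    dens <- .binDensities(v, bw, edges)
    if (strand[i] == "-") dens <- rev(dens)
    acc <- acc + dens
    used <- used + 1L
  }
  out <- if (used > 0L) acc / used else acc
  names(out) <- seq(-half + bw / 2, half - bw / 2, by = bw)
  out
}

#' Anchored, oriented heatmap matrices
#'
#' One matrix per track: rows are windows centered on NELFA summits (the
#' anchors from [pairNelfaCtr9()]); a row is reversed when the nearest
#' Ctr9 summit lies at a lower coordinate, so Ctr9 signal always points
#' right. Windows exceeding chromosome bounds are zero-padded and
#' flagged.
#'
#' @param tracks Named list of [SignalTrack-class] objects.
#' @param anchors data.frame from [pairNelfaCtr9()] (needs `chrom`,
#'   `nelfa_summit`, `ctr9_summit`, `region_id`).
#' @param windowBp Window width in bp (default 2000; use 50000 for a
#'   zoomed-out view).
#' @return List with `matrices` (named list of row-anchored matrices) and
#'   `meta` (data.frame: `region_id`, `flipped`, `padded`).
#' @export
anchoredHeatmap <- function(tracks, anchors, windowBp = 2000L) {
  stopifnot(length(tracks) > 0L)
  bw <- binWidth(tracks[[1L]])
  nb <- as.integer(windowBp / bw)
  half <- windowBp / 2
  flipped <- !is.na(anchors$ctr9_summit) &
    anchors$ctr9_summit < anchors$nelfa_summit
  padded <- logical(nrow(anchors))
  matrices <- lapply(tracks, function(tr) {
    vals <- trackValues(tr)
    m <- matrix(0, nrow = nrow(anchors), ncol = nb)
    for (i in seq_len(nrow(anchors))) {
      v <- vals[[anchors$chrom[i]]]
      if (is.null(v)) next
      a0 <- anchors$nelfa_summit[i] - 0.5
      edges <- seq(a0 - half, a0 + half, by = bw)
      lo <- 0
      hi <- length(v) * bw
      if (edges[1L] < lo || edges[length(edges)] > hi) {
        padded[i] <<- TRUE
      }
      dens <- .binDensities(v, bw, pmin(pmax(edges, lo), hi))
      dens[!is.finite(dens)] <- 0
      if (flipped[i]) dens <- rev(dens)
      m[i, ] <- dens
    }
    rownames(m) <- anchors$region_id
    m
  })
  list(matrices = matrices,
       meta = data.frame(region_id = anchors$region_id, flipped = flipped,
                         padded = padded, stringsAsFactors = FALSE))
}

#' Quantile-normalize a set of heatmap matrices
#'
#' Pools all values of each matrix and maps them, by rank, onto the mean
#' order-statistic distribution across the matrices (rank ties receive
#' the average of the tied order statistics), so every matrix shares one
#' value distribution while within-matrix rank order is preserved.
#'
#' @param matrices Named list of equal-dimension numeric matrices.
#' @return List of normalized matrices with the same names/dimensions.
#' @export
quantileNormalizeMatrices <- function(matrices) {
  stopifnot(length(matrices) > 0L)
  dims <- dim(matrices[[1L]])
  if (!all(vapply(matrices, function(m) identical(dim(m), dims),
                  logical(1L)))) {
    stop("all matrices must share the same dimensions", call. = FALSE)
  }
  flat <- vapply(matrices, as.vector, numeric(prod(dims)))
  normed <- limma::normalizeQuantiles(flat, ties = TRUE)
  out <- lapply(seq_along(matrices), function(j) {
    m <- matrix(normed[, j], nrow = dims[1L], ncol = dims[2L])
    dimnames(m) <- dimnames(matrices[[j]])
    m
  })
  names(out) <- names(matrices)
  out
}
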