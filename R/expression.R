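#' Filter to expressed genes
#'
#' Keeps genes whose control expression meets the expressed threshold
#' (inclusive: tpm >= threshold).
#'
#' @param expression data.frame with a `tpm_control` column.
#' @param threshold Expressed threshold in tpm (default 1).
#' @return The filtered data.frame.
#' @export
filterExpressed <- function(expression, threshold = 1.0) {
  expression[expression$tpm_control >= threshold, , drop = FALSE]
}

#' Log2 fold change of knockdown versus control expression
#'
#' `log2((tpm_kd + eps) / (tpm_ctrl + eps))`. With the default `eps = 0`
#' a zero knockdown tpm yields `-Inf` (an explicit sentinel, logged as a
#' warning) rather than a silently pseudocounted value.
#'
#' @param expression data.frame with `tpm_control` and `tpm_knockdown`
#'   (conventionally already filtered with [filterExpressed()]).
#' @param eps Pseudocount (default 0).
#' @return Numeric vector of log2 fold changes.
#' @export
log2FoldChange <- function(expression, eps = 0) {
  lfc <- log2((expression$tpm_knockdown + eps) /
                (expression$tpm_control + eps))
  nInf <- sum(is.infinite(lfc) & lfc < 0)
  if (nInf > 0L) {
    .warnf("%d gene(s) with zero knockdown tpm produced -Inf log2 fold change",
           nInf)
  }
  lfc
}

#' Assign genes to enhancer-association groups
#'
#' A gene is `SE`-associated when the nearest enhancer within
#' `maxDistance` of its TSS (distance from the TSS to the region edge, 0
#' inside) is a super enhancer, `TE` when it is a typical enhancer, and
#' `other` otherwise. SE beats TE at equal distance.
#'
#' @param genes `GRanges` from [readGeneTable()].
#' @param enhancers `GRanges` from [readEnhancerBed()].
#' @param maxDistance Association window in bp (default 100000).
#' @return Character vector of groups (`SE`/`TE`/`other`), one per gene.
#' @export
associateGenes <- function(genes, enhancers, maxDistance = 1e5) {
  tss <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(genes),
    ranges = IRanges::IRanges(start = genes$tss, width = 1L))
  edgeDist <- function(cls) {
    e <- enhancers[enhancers$enh_class == cls]
    if (length(e) == 0L) return(rep(Inf, length(genes)))
    hits <- GenomicRanges::distanceToNearest(tss, e, ignore.strand = TRUE)
    d <- rep(Inf, length(genes))
    # distanceToNearest counts strictly intervening bases; convert to
    # edge distance (bases from the TSS to the region boundary)
    dd <- S4Vectors::mcols(hits)$distance
    d[S4Vectors::queryHits(hits)] <- ifelse(dd == 0, 0, dd + 1)
    d
  }
  dSE <- edgeDist("SE")
  dTE <- edgeDist("TE")
  ifelse(pmin(dSE, dTE) > maxDistance, "other",
         ifelse(dSE <= dTE, "SE", "TE"))
}

#' Mann-Whitney U statistic
#'
#' Number of (a, b) pairs with a > b, counting ties as 1/2 — the
#' pair-counting definition of the rank-sum U.
#'
#' @param a,b Numeric samples.
#' @return The U statistic for sample `a`.
#' @export
uStatistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Fraction of down-regulated genes
#'
#' Percentage of genes with a negative log2 fold change.
#'
#' @param lfc Numeric vector of log2 fold changes.
#' @return Percentage in `[0, 100]`.
#' @export
fractionDecreased <- function(lfc) {
  100 * mean(lfc < 0)
}

#' Knockdown contrast across enhancer-association groups
#'
#' Per group: size, median log2 fold change and fraction decreased;
#' plus two-sided Mann-Whitney U p-values (with tie correction for large
#' samples, exact for small tie-free ones) for every group pair.
#'
#' @param lfc Numeric vector of log2 fold changes.
#' @param group Character vector of group labels, parallel to `lfc`.
#' @return List of class `"GroupContrast"`: `summary` (data.frame with
#'   `group`, `n`, `median_lfc`, `fraction_decreased`) and `pairwise`
#'   (data.frame with `group_a`, `group_b`, `U`, `p`). Pairs with an
#'   empty group are skipped with a warning.
#' @export
groupContrast <- function(lfc, group) {
  stopifnot(length(lfc) == length(group))
  groups <- unique(group)
  summary <- do.call(rbind, lapply(groups, function(g) {
    x <- lfc[group == g]
    data.frame(group = g, n = length(x), median_lfc = stats::median(x),
               fraction_decreased = fractionDecreased(x),
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  pw <- lapply(pairs, function(pr) {
    x <- lfc[group == pr[1L]]
    y <- lfc[group == pr[2L]]
    if (length(x) == 0L || length(y) == 0L) {
      .warnf("group pair %s/%s skipped: empty group", pr[1L], pr[2L])
      return(NULL)
    }
    data.frame(group_a = pr[1L], group_b = pr[2L], U = uStatistic(x, y),
               p = rankSumP(x, y), stringsAsFactors = FALSE)
  })
  pairwise <- do.call(rbind, pw)
  structure(list(summary = summary, pairwise = pairwise),
            class = "GroupContrast")
}

#' @export
print.GroupContrast <- function(x, ...) {
  cat("Knockdown contrast by enhancer association\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("pairwise Mann-Whitney:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' MA-plot data for the knockdown contrast
#'
#' Mean expression, log2 fold change and association group per expressed
#' gene, ready for plotting or export.
#'
#' @param expression data.frame with `gene_id`, `tpm_control`,
#'   `tpm_knockdown` and `group`.
#' @param threshold Expressed threshold in tpm (default 1).
#' @return data.frame with `gene_id`, `mean_tpm`, `lfc`, `group`.
#' @export
maPlotData <- function(expression, threshold = 1.0) {
  expr <- filterExpressed(expression, threshold)
  data.frame(gene_id = expr$gene_id,
             mean_tpm = (expr$tpm_control + expr$tpm_knockdown) / 2,
             lfc = log2FoldChange(expr), group = expr$group,
             stringsAsFactors = FALSE)
}
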