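#' Read a narrowPeak file
#'
#' Parses a 10-column narrowPeak file (0-based half-open intervals as
#' emitted by common peak callers) into a `GRanges` of peaks. Column 10 is
#' the summit offset from the interval start; when it is -1 the summit
#' falls back to the interval midpoint (rounded down). Summits are stored
#' as absolute 1-based genomic positions in the `summit` metadata column.
#'
#' @param path Path to a narrowPeak file.
#' @param factor Factor label to attach to every peak (e.g. `"Ctr9"`).
#' @return `GRanges` with metadata columns `name`, `score`, `signalValue`,
#'   `pValue`, `qValue`, `peak` (raw summit offset), `summit` (absolute,
#'   1-based) and `factor`. Input order is preserved.
#' @examples
#' tf <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr1\t100\t200\tp1\t0\t.\t5\t3\t2\t50", tf)
#' readNarrowPeak(tf, "Ctr9")
#' @export
readNarrowPeak <- function(path, factor) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(.peakGRanges(character(), integer(), integer(), character(),
                        numeric(), character(), numeric(), numeric(),
                        numeric(), integer(), factor))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 10L)) {
    .stopf("narrowPeak parse error at line %d of '%s': expected 10 columns, found %d",
           which(nf != 10L)[1L], path, nf[which(nf != 10L)[1L]])
  }
  m <- do.call(rbind, fields)
  num <- function(col, what) {
    x <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(x)) {
      .stopf("narrowPeak parse error at line %d of '%s': non-numeric %s",
             which(is.na(x))[1L], path, what)
    }
    x
  }
  start0 <- num(2L, "start")
  end0 <- num(3L, "end")
  bad <- which(end0 <= start0 | start0 < 0)
  if (length(bad) > 0L) {
    .stopf("narrowPeak validation error at line %d of '%s': end <= start",
           bad[1L], path)
  }
  offset <- num(10L, "summit offset")
  bad <- which(offset >= end0 - start0)
  if (length(bad) > 0L) {
    .stopf("narrowPeak validation error at line %d of '%s': summit offset %d >= peak length %d",
           bad[1L], path, offset[bad[1L]], end0[bad[1L]] - start0[bad[1L]])
  }
  summit0 <- ifelse(offset >= 0, start0 + offset,
                    start0 + floor((end0 - start0) / 2))
  .peakGRanges(m[, 1L], start0, end0, m[, 4L], num(5L, "score"), m[, 6L],
               num(7L, "signalValue"), num(8L, "pValue"), num(9L, "qValue"),
               as.integer(offset), factor, summit0)
}

.peakGRanges <- function(chrom, start0, end0, name, score, strand,
                         signalValue, pValue, qValue, peak, factor,
                         summit0 = integer()) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = ifelse(strand %in% c("+", "-"), strand, "*"))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = name, score = score, signalValue = signalValue,
    pValue = pValue, qValue = qValue, peak = peak,
    summit = as.integer(summit0) + 1L,
    factor = rep(factor, length(chrom)))
  gr
}

#' Write peaks as narrowPeak
#'
#' Deterministic writer (chromosome lexicographic, then start) inverse to
#' [readNarrowPeak()].
#'
#' @param peaks `GRanges` as returned by [readNarrowPeak()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeNarrowPeak <- function(peaks, path) {
  o <- .canonicalOrder(GenomicRanges::seqnames(peaks),
                       GenomicRanges::start(peaks))
  p <- peaks[o]
  strand <- as.character(GenomicRanges::strand(p))
  strand[strand == "*"] <- "."
  lines <- paste(as.character(GenomicRanges::seqnames(p)),
                 GenomicRanges::start(p) - 1L, GenomicRanges::end(p),
                 p$name, .fmtNum(p$score), strand, .fmtNum(p$signalValue),
                 .fmtNum(p$pValue), .fmtNum(p$qValue), p$peak, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# canonical plain-text number format shared by all writers
.fmtNum <- function(x) {
  vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE,
                               digits = 15L), character(1L))
}

#' Read a BED file of genomic intervals
#'
#' Accepts BED3/BED6 (0-based half-open). Additional columns beyond the
#' sixth are ignored.
#'
#' @param path Path to a BED file.
#' @return `GRanges`; `name` and `score` metadata columns are present when
#'   the file has >= 5 columns.
#' @export
readBed <- function(path) {
  m <- .readBedMatrix(path, minCols = 3L)
  gr <- GenomicRanges::GRanges(
    seqnames = m$chrom,
    ranges = IRanges::IRanges(start = m$start0 + 1L, end = m$end0),
    strand = m$strand)
  if (!is.null(m$name)) {
    gr$name <- m$name
    gr$score <- m$score
  }
  gr
}

.readBedMatrix <- function(path, minCols) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(list(chrom = character(), start0 = integer(), end0 = integer(),
                strand = character(), name = NULL, score = NULL,
                fields = list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < minCols)) {
    .stopf("BED parse error at line %d of '%s': expected >= %d columns, found %d",
           which(nf < minCols)[1L], path, minCols, nf[which(nf < minCols)[1L]])
  }
  ncol <- min(nf)
  m <- do.call(rbind, lapply(fields, `[`, seq_len(ncol)))
  start0 <- suppressWarnings(as.numeric(m[, 2L]))
  end0 <- suppressWarnings(as.numeric(m[, 3L]))
  if (anyNA(start0) || anyNA(end0)) {
    .stopf("BED parse error at line %d of '%s': non-numeric coordinates",
           which(is.na(start0) | is.na(end0))[1L], path)
  }
  bad <- which(end0 <= start0 | start0 < 0)
  if (length(bad) > 0L) {
    .stopf("BED validation error at line %d of '%s': end <= start",
           bad[1L], path)
  }
  strand <- if (ncol >= 6L) ifelse(m[, 6L] %in% c("+", "-"), m[, 6L], "*")
            else rep("*", nrow(m))
  list(chrom = m[, 1L], start0 = start0, end0 = end0, strand = strand,
       name = if (ncol >= 4L) m[, 4L] else NULL,
       score = if (ncol >= 5L) suppressWarnings(as.numeric(m[, 5L]))
               else NULL,
       fields = fields)
}

#' Write intervals as BED
#'
#' Writes BED3, or BED6 when `name`/`score` metadata are present, in
#' deterministic order.
#'
#' @param gr `GRanges` to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  o <- .canonicalOrder(GenomicRanges::seqnames(gr), GenomicRanges::start(gr))
  g <- gr[o]
  base <- paste(as.character(GenomicRanges::seqnames(g)),
                GenomicRanges::start(g) - 1L, GenomicRanges::end(g),
                sep = "\t")
  if (!is.null(g$name)) {
    strand <- as.character(GenomicRanges::strand(g))
    strand[strand == "*"] <- "."
    score <- if (is.null(g$score)) rep(0, length(g)) else g$score
    base <- paste(base, g$name, .fmtNum(score), strand, sep = "\t")
  }
  writeLines(base, path)
  invisible(path)
}

#' Read enhancer annotations
#'
#' BED-like file with class in column 4: `chrom start end class [enh_id]
#' [target_genes]`. Class must be `SE` or `TE`; `target_genes` is a
#' comma-separated list (`"."` for none).
#'
#' @param path Path to the enhancer BED file.
#' @return `GRanges` with metadata `enh_class`, `enh_id` and
#'   `target_genes` (CharacterList).
#' @export
readEnhancerBed <- function(path) {
  m <- .readBedMatrix(path, minCols = 4L)
  cls <- vapply(m$fields, `[`, character(1L), 4L)
  bad <- which(!cls %in% c("SE", "TE"))
  if (length(bad) > 0L) {
    .stopf("enhancer validation error at line %d of '%s': unknown class '%s' (expected SE or TE)",
           bad[1L], path, cls[bad[1L]])
  }
  n <- length(m$chrom)
  ids <- if (all(lengths(m$fields) >= 5L)) {
    vapply(m$fields, `[`, character(1L), 5L)
  } else {
    sprintf("enh_%05d", seq_len(n))
  }
  tg <- if (all(lengths(m$fields) >= 6L)) {
    lapply(strsplit(vapply(m$fields, `[`, character(1L), 6L), ",",
                    fixed = TRUE),
           function(x) x[x != "."])
  } else {
    rep(list(character()), n)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = m$chrom,
    ranges = IRanges::IRanges(start = m$start0 + 1L, end = m$end0))
  gr$enh_class <- cls
  gr$enh_id <- ids
  gr$target_genes <- IRanges::CharacterList(tg)
  gr
}

#' Write enhancer annotations
#'
#' @param enhancers `GRanges` as returned by [readEnhancerBed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeEnhancerBed <- function(enhancers, path) {
  o <- .canonicalOrder(GenomicRanges::seqnames(enhancers),
                       GenomicRanges::start(enhancers))
  g <- enhancers[o]
  tg <- vapply(as.list(g$target_genes), function(x) {
    if (length(x) == 0L) "." else paste(x, collapse = ",")
  }, character(1L))
  lines <- paste(as.character(GenomicRanges::seqnames(g)),
                 GenomicRanges::start(g) - 1L, GenomicRanges::end(g),
                 g$enh_class, g$enh_id, tg, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene model table
#'
#' Tab-separated file with header `gene_id chrom strand tss tes`;
#' coordinates are 1-based positions of the transcription start and end
#' sites (so `tss > tes` on the minus strand). Converted to `GRanges` of
#' gene bodies at the reader boundary.
#'
#' @param path Path to the gene TSV.
#' @return `GRanges` spanning `min(tss, tes)..max(tss, tes)` with metadata
#'   `gene_id`, `tss`, `tes`.
#' @export
readGeneTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  .checkColumns(df, c("gene_id", "chrom", "strand", "tss", "tes"),
                sprintf("gene table '%s'", path))
  if (any(!df$strand %in% c("+", "-"))) {
    .stopf("gene table validation error in '%s': strand must be '+' or '-' (gene %s)",
           path, df$gene_id[which(!df$strand %in% c("+", "-"))[1L]])
  }
  bad <- which((df$strand == "+" & df$tss >= df$tes) |
                 (df$strand == "-" & df$tss <= df$tes))
  if (length(bad) > 0L) {
    .stopf("gene table validation error in '%s': gene %s violates the strand/TSS orientation invariant",
           path, df$gene_id[bad[1L]])
  }
  if (anyDuplicated(df$gene_id)) {
    .stopf("gene table validation error in '%s': duplicate gene ids", path)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = pmin(df$tss, df$tes),
                              end = pmax(df$tss, df$tes)),
    strand = df$strand)
  gr$gene_id <- df$gene_id
  gr$tss <- as.integer(df$tss)
  gr$tes <- as.integer(df$tes)
  gr
}

#' Write a gene model table
#'
#' @param genes `GRanges` as returned by [readGeneTable()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genes, path) {
  o <- .canonicalOrder(GenomicRanges::seqnames(genes),
                       GenomicRanges::start(genes))
  g <- genes[o]
  df <- data.frame(gene_id = g$gene_id,
                   chrom = as.character(GenomicRanges::seqnames(g)),
                   strand = as.character(GenomicRanges::strand(g)),
                   tss = g$tss, tes = g$tes)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression table
#'
#' Tab-separated file with header `gene_id tpm_control tpm_knockdown`
#' (optionally `group`). When the same `gene_id` appears on several rows
#' (transcript-level input) only the representative row with the highest
#' control expression per gene is kept.
#'
#' @param path Path to the expression TSV.
#' @return data.frame with columns `gene_id`, `tpm_control`,
#'   `tpm_knockdown` and `group` (`NA` when absent from the file).
#' @export
readExpressionTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  .checkColumns(df, c("gene_id", "tpm_control", "tpm_knockdown"),
                sprintf("expression table '%s'", path))
  if (any(df$tpm_control < 0) || any(df$tpm_knockdown < 0)) {
    .stopf("expression table validation error in '%s': tpm values must be >= 0",
           path)
  }
  if (is.null(df$group)) df$group <- NA_character_
  if (anyDuplicated(df$gene_id)) {
    # transcript-level table: keep the highest-expressed representative
    o <- order(df$gene_id, -df$tpm_control)
    df <- df[o, , drop = FALSE]
    df <- df[!duplicated(df$gene_id), , drop = FALSE]
  }
  df <- df[order(df$gene_id), c("gene_id", "tpm_control", "tpm_knockdown",
                                "group")]
  rownames(df) <- NULL
  df
}

#' Write an expression table
#'
#' @param expression data.frame as returned by [readExpressionTable()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(expression, path) {
  df <- expression[order(expression$gene_id),
                   c("gene_id", "tpm_control", "tpm_knockdown", "group")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
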