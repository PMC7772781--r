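#' Read a bedGraph file into a SignalTrack
#'
#' Parses 4-column bedGraph (0-based half-open, value = coverage per bp)
#' and re-bins it at a fixed bin width. Where interval boundaries do not
#' align with the bin grid, values are length-weighted into bins so signal
#' mass is conserved exactly.
#'
#' @param path Path to a bedGraph file.
#' @param binWidth Bin width in bp.
#' @param genomeSizes Optional named vector of chromosome lengths; when
#'   omitted each chromosome is sized to its last covered bin.
#' @return A [SignalTrack-class] with `norm = "raw"`.
#' @examples
#' tf <- tempfile(fileext = ".bedGraph")
#' writeLines("chr1\t0\t100\t2", tf)
#' tr <- readBedGraph(tf, binWidth = 10L)
#' totalMass(tr)  # 2 * 100
#' @export
readBedGraph <- function(path, binWidth, genomeSizes = NULL) {
  binWidth <- as.integer(binWidth)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    values <- list()
    if (!is.null(genomeSizes)) {
      values <- lapply(genomeSizes,
                       function(s) numeric(ceiling(s / binWidth)))
      names(values) <- names(genomeSizes)
    }
    return(SignalTrack(values, binWidth))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    .stopf("bedGraph parse error at line %d of '%s': expected 4 columns",
           which(nf != 4L)[1L], path)
  }
  m <- do.call(rbind, fields)
  start0 <- as.numeric(m[, 2L])
  end0 <- as.numeric(m[, 3L])
  val <- as.numeric(m[, 4L])
  if (anyNA(start0) || anyNA(end0) || anyNA(val)) {
    .stopf("bedGraph parse error in '%s': non-numeric fields", path)
  }
  if (any(end0 <= start0)) {
    .stopf("bedGraph validation error at line %d of '%s': end <= start",
           which(end0 <= start0)[1L], path)
  }
  if (any(val < 0)) {
    .stopf("bedGraph validation error in '%s': negative coverage", path)
  }
  chrom <- m[, 1L]
  chroms <- if (!is.null(genomeSizes)) names(genomeSizes)
            else sort(unique(chrom))
  values <- vector("list", length(chroms))
  names(values) <- chroms
  for (ch in chroms) {
    sel <- which(chrom == ch)
    size <- if (!is.null(genomeSizes)) genomeSizes[[ch]]
            else if (length(sel) > 0L) max(end0[sel]) else binWidth
    nb <- as.integer(ceiling(size / binWidth))
    v <- numeric(nb)
    if (length(sel) > 0L) {
      o <- sel[order(start0[sel])]
      if (any(start0[o][-1L] < end0[o][-length(o)])) {
        .stopf("bedGraph validation error in '%s': overlapping intervals on %s",
               path, ch)
      }
      for (i in o) {
        b0 <- floor(start0[i] / binWidth)
        b1 <- ceiling(end0[i] / binWidth) - 1L
        bins <- b0:b1
        lo <- pmax(start0[i], bins * binWidth)
        hi <- pmin(end0[i], (bins + 1L) * binWidth)
        v[bins + 1L] <- v[bins + 1L] + val[i] * (hi - lo) / binWidth
      }
    }
    values[[ch]] <- v
  }
  SignalTrack(values, binWidth)
}

#' Write a SignalTrack as bedGraph
#'
#' Adjacent equal-valued bins are merged into runs; zero-valued runs are
#' omitted. Chromosomes are written in lexicographic order, making the
#' writer deterministic and the write-then-read round trip exact for
#' tracks on the same bin grid.
#'
#' @param track A [SignalTrack-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(track, path) {
  bw <- binWidth(track)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in sort(names(trackValues(track)))) {
    v <- trackValues(track)[[ch]]
    if (length(v) == 0L) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(paste(ch, starts[keep] * bw, ends[keep] * bw,
                     .fmtNum(r$values[keep]), sep = "\t"), con)
  }
  invisible(path)
}

#' @describeIn accessors Scale a raw track to reads per million: every bin
#'   is multiplied by `1e6 / totalMass(x)`, so the rpm masses sum to 1e6.
#'   Raises a degenerate-input error when the track carries no signal.
#' @export
setMethod("toRPM", "SignalTrack", function(x, ...) {
  if (x@norm == "rpm") return(x)
  if (x@totalMass <= 0) {
    stop("cannot rpm-normalize a track with zero total mass",
         call. = FALSE)
  }
  f <- 1e6 / x@totalMass
  methods::new("SignalTrack", values = lapply(x@values, `*`, f),
               binWidth = x@binWidth, totalMass = x@totalMass,
               norm = "rpm")
})

# mass of [a0, b0) (0-based bp, real-valued allowed) on one chromosome
# vector; piecewise-constant density within bins.
.prefixMass <- function(v, bw, x) {
  nb <- length(v)
  x <- pmin(pmax(x, 0), nb * bw)
  idx <- pmin(floor(x / bw), nb - 1L)
  cs <- c(0, cumsum(v)) * bw
  cs[idx + 1L] + v[idx + 1L] * (x - idx * bw)
}

.intervalMass <- function(v, bw, a0, b0) {
  if (length(v) == 0L) return(rep(0, length(a0)))
  .prefixMass(v, bw, b0) - .prefixMass(v, bw, a0)
}

#' Signal mass over regions
#'
#' Total signal mass (coverage integrated over bp, length-weighted at
#' partial edge bins) of a track over each region.
#'
#' @param track A [SignalTrack-class].
#' @param regions `GRanges`.
#' @param warn Warn about regions on chromosomes absent from the track
#'   (their mass is 0).
#' @return Numeric vector, one mass per region.
#' @export
binnedMass <- function(track, regions, warn = TRUE) {
  bw <- binWidth(track)
  vals <- trackValues(track)
  chrom <- as.character(GenomicRanges::seqnames(regions))
  out <- numeric(length(regions))
  missing <- setdiff(unique(chrom), names(vals))
  if (length(missing) > 0L && warn) {
    .warnf("regions on chromosome(s) %s absent from track: mass set to 0",
           paste(missing, collapse = ", "))
  }
  for (ch in intersect(unique(chrom), names(vals))) {
    sel <- chrom == ch
    out[sel] <- .intervalMass(vals[[ch]], bw,
                              GenomicRanges::start(regions)[sel] - 1L,
                              GenomicRanges::end(regions)[sel])
  }
  out
}
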