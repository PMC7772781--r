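#' SignalTrack: binned genome coverage
#'
#' Per-chromosome coverage at a fixed bin width. Bin values are coverage
#' *per base pair* (the bedGraph convention), so the mass of a bin is
#' `value * binWidth`. The `totalMass` slot always records the mass of the
#' track on the raw scale; after reads-per-million scaling (`norm = "rpm"`)
#' the values sum (times bin width) to 1e6 while `totalMass` still holds the
#' raw library mass used for the scaling.
#'
#' @slot values Named list of numeric vectors, one per chromosome.
#' @slot binWidth Integer bin width in bp.
#' @slot totalMass Total raw signal mass (sum of values times bin width at
#'   raw scale).
#' @slot norm Either `"raw"` or `"rpm"`.
#' @aliases SignalTrack-class
#' @exportClass SignalTrack
setClass("SignalTrack",
  representation(values = "list", binWidth = "integer",
                 totalMass = "numeric", norm = "character"))

setValidity("SignalTrack", function(object) {
  msgs <- character()
  v <- object@values
  if (length(v) > 0L && (is.null(names(v)) || anyDuplicated(names(v)) ||
                         any(!nzchar(names(v))))) {
    msgs <- c(msgs, "'values' must be a uniquely named list of chromosomes")
  }
  if (!all(vapply(v, is.numeric, logical(1L)))) {
    msgs <- c(msgs, "'values' must contain numeric vectors")
  } else if (any(vapply(v, function(x) any(x < 0), logical(1L)))) {
    msgs <- c(msgs, "coverage values must be non-negative")
  }
  if (length(object@binWidth) != 1L || object@binWidth < 1L) {
    msgs <- c(msgs, "'binWidth' must be a single positive integer")
  }
  if (length(object@totalMass) != 1L || object@totalMass < 0) {
    msgs <- c(msgs, "'totalMass' must be a single non-negative number")
  }
  if (!object@norm %in% c("raw", "rpm")) {
    msgs <- c(msgs, "'norm' must be \"raw\" or \"rpm\"")
  }
  if (length(msgs) > 0L) msgs else TRUE
})

#' Construct a SignalTrack
#'
#' @param values Named list of per-chromosome numeric vectors (coverage per
#'   bp in each bin).
#' @param binWidth Bin width in bp.
#' @param norm `"raw"` (default) or `"rpm"`.
#' @param totalMass Raw-scale total mass. Computed from `values` when the
#'   track is raw; must be supplied for an rpm track.
#' @return A [SignalTrack-class] object.
#' @examples
#' tr <- SignalTrack(list(chr1 = c(2, 2, 0, 1)), binWidth = 100L)
#' totalMass(tr)
#' @export
SignalTrack <- function(values, binWidth, norm = "raw", totalMass = NULL) {
  binWidth <- as.integer(binWidth)
  if (is.null(totalMass)) {
    if (norm != "raw") {
      stop("'totalMass' must be supplied for a non-raw track")
    }
    totalMass <- sum(vapply(values, sum, numeric(1L))) * binWidth
  }
  methods::new("SignalTrack", values = values, binWidth = binWidth,
               totalMass = as.numeric(totalMass), norm = norm)
}

setMethod("show", "SignalTrack", function(object) {
  cat(sprintf("SignalTrack: %d chromosome(s), bin width %d bp, %s scale\n",
              length(object@values), object@binWidth, object@norm))
  cat(sprintf("  total raw mass: %.6g; bins: %s\n", object@totalMass,
              paste(vapply(object@values, length, integer(1L)),
                    collapse = ", ")))
})

#' CalibrationProfile: parameters of the synthetic-data generator
#'
#' Bundles every magnitude the generator plants: promoter summit offsets per
#' factor, NELFA-Ctr9 enhancer distances per class, enhancer counts,
#' per-class factor occupancy probabilities, the SE:TE density ratio, the
#' knockdown effect model, expression levels, coverage-kernel geometry, and
#' genome layout.
#'
#' @slot name Profile name.
#' @slot promoterOffsets Matrix (factors x `mean`,`sd`) of summit offsets
#'   downstream of the TSS, bp.
#' @slot pairDistance Matrix (`SE`,`TE` x `mean`,`sd`) of NELFA-Ctr9 summit
#'   distances, bp.
#' @slot counts Named numeric, enhancer counts per class (`SE`, `TE`).
#' @slot occProb Matrix (`SE`,`TE` x factors) of occupancy probabilities;
#'   the `Ser2p` column is conditional on Ctr9 binding (containment).
#' @slot ernaProb Named numeric (`SE`, `TE`): probability of an eRNA
#'   interval conditional on Ctr9 binding.
#' @slot unilateralFraction Fraction of NELFA+/Ctr9+ enhancers with a single
#'   (unilateral) Ctr9 peak; the rest get symmetric flanking peaks.
#' @slot densityRatio Target SE:TE ratio of mean Ctr9 coverage density.
#' @slot knockdown List: `downFraction` (per association group), `downLog2`
#'   and `upLog2` (`mean`, `sd` of the half-normal log2 effect magnitudes),
#'   `ser2pDivisor` (per class).
#' @slot expression List: `silentFraction`, `levels` (tpm level per
#'   expressed category), `sdLog` (lognormal jitter).
#' @slot coverage List: `binWidth`, `kernelHalfWidth`, `noisePerBp`,
#'   `seBoundDensity`, per-factor kernel masses, histone densities.
#' @slot genome List: chromosome count, slot/feature widths, gene length
#'   range, fraction of genes on the enhancer-free chromosome, optional
#'   fixed chromosome length.
#' @aliases CalibrationProfile-class
#' @exportClass CalibrationProfile
setClass("CalibrationProfile",
  representation(name = "character", promoterOffsets = "matrix",
                 pairDistance = "matrix", counts = "numeric",
                 occProb = "matrix", ernaProb = "numeric",
                 unilateralFraction = "numeric", densityRatio = "numeric",
                 knockdown = "list", expression = "list",
                 coverage = "list", genome = "list"))

setValidity("CalibrationProfile", function(object) {
  msgs <- character()
  if (any(object@promoterOffsets[, "sd"] < 0) ||
      any(object@pairDistance[, "sd"] < 0)) {
    msgs <- c(msgs, "standard deviations must be >= 0")
  }
  if (any(object@counts < 0)) msgs <- c(msgs, "enhancer counts must be >= 0")
  if (any(object@occProb < 0 | object@occProb > 1) ||
      any(object@ernaProb < 0 | object@ernaProb > 1)) {
    msgs <- c(msgs, "probabilities must lie in [0, 1]")
  }
  kd <- object@knockdown$downFraction
  if (any(kd < 0 | kd > 1)) {
    msgs <- c(msgs, "knockdown down-fractions must lie in [0, 1]")
  }
  if (object@unilateralFraction < 0 || object@unilateralFraction > 1) {
    msgs <- c(msgs, "'unilateralFraction' must lie in [0, 1]")
  }
  if (length(msgs) > 0L) msgs else TRUE
})

setMethod("show", "CalibrationProfile", function(object) {
  cat(sprintf("CalibrationProfile \"%s\"\n", object@name))
  cat(sprintf("  enhancers: %d SE, %d TE; genes: %d on %d chromosome(s)\n",
              object@counts[["SE"]], object@counts[["TE"]],
              object@genome$nGenes, object@genome$nChrom))
  off <- object@promoterOffsets
  cat(sprintf("  promoter offsets (bp downstream of TSS): %s\n",
              paste(sprintf("%s=%g", rownames(off), off[, "mean"]),
                    collapse = ", ")))
  cat(sprintf("  NELFA-Ctr9 distance: SE=%g, TE=%g bp; density ratio %.2g\n",
              object@pairDistance["SE", "mean"],
              object@pairDistance["TE", "mean"], object@densityRatio))
})

#' OccupancyMatrix: region-by-factor bound/unbound calls
#'
#' Boolean occupancy calls (a region is bound by a factor when at least one
#' peak of that factor intersects it by >= 1 bp) with, for every TRUE cell,
#' the names of the supporting peaks.
#'
#' @slot calls Logical matrix, rows = region ids, columns = factor labels.
#' @slot provenance List keyed by factor; each element is a list keyed by
#'   region id holding the character vector of supporting peak names. An
#'   entry exists if and only if the corresponding cell is TRUE.
#' @aliases OccupancyMatrix-class
#' @exportClass OccupancyMatrix
setClass("OccupancyMatrix",
  representation(calls = "matrix", provenance = "list"))

setValidity("OccupancyMatrix", function(object) {
  msgs <- character()
  calls <- object@calls
  if (!is.logical(calls)) msgs <- c(msgs, "'calls' must be logical")
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    msgs <- c(msgs, "'calls' must have region-id rownames and factor colnames")
  } else {
    if (anyDuplicated(rownames(calls))) {
      msgs <- c(msgs, "region ids must be unique")
    }
    if (!setequal(names(object@provenance), colnames(calls))) {
      msgs <- c(msgs, "'provenance' must be keyed by the factor columns")
    } else {
      for (f in colnames(calls)) {
        tr <- rownames(calls)[which(calls[, f])]
        if (!setequal(names(object@provenance[[f]]), tr)) {
          msgs <- c(msgs, sprintf(
            "provenance entries for factor '%s' must match TRUE cells", f))
        }
      }
    }
  }
  if (length(msgs) > 0L) msgs else TRUE
})

setMethod("show", "OccupancyMatrix", function(object) {
  cat(sprintf("OccupancyMatrix: %d regions x %d factors\n",
              nrow(object@calls), ncol(object@calls)))
  cat("  bound fractions:",
      paste(sprintf("%s=%.3f", colnames(object@calls),
                    colMeans(object@calls)), collapse = ", "), "\n")
})

#' SyntheticDataset: a generated genome with full ground truth
#'
#' Everything one simulation run produces: genome sizes, gene models,
#' enhancer annotations, per-factor peak sets, coverage tracks (control and
#' knockdown where applicable), an expression table, eRNA intervals, and a
#' plant map recording exactly what was planted where (sampled offsets,
#' pair distances, occupancy draws, knockdown effects), sufficient to
#' recompute every downstream summary without re-simulation.
#'
#' @slot genomeSizes Named numeric of chromosome lengths (bp).
#' @slot genes GRanges of gene bodies with `gene_id`, `tss`, `tes` metadata.
#' @slot enhancers GRanges with `enh_id`, `enh_class` metadata.
#' @slot peaks Named list (factor -> GRanges of peaks with `summit`,
#'   `score`, `name`, `factor` metadata).
#' @slot tracks Named list of [SignalTrack-class] objects (may be empty when
#'   tracks were not requested).
#' @slot expression data.frame with `gene_id`, `tpm_control`,
#'   `tpm_knockdown`, `group`.
#' @slot ernas GRanges of eRNA intervals.
#' @slot plantMap List with `genes`, `enhancers` data.frames and `params`.
#' @slot profileName Name of the calibration profile used.
#' @slot seed Integer seed used.
#' @aliases SyntheticDataset-class
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
  representation(genomeSizes = "numeric", genes = "GRanges",
                 enhancers = "GRanges", peaks = "list", tracks = "list",
                 expression = "data.frame", ernas = "GRanges",
                 plantMap = "list", profileName = "character",
                 seed = "integer"))

setValidity("SyntheticDataset", function(object) {
  msgs <- character()
  gs <- object@genomeSizes
  if (is.null(names(gs))) msgs <- c(msgs, "'genomeSizes' must be named")
  inBounds <- function(gr) {
    length(gr) == 0L ||
      all(GenomicRanges::start(gr) >= 1L &
            GenomicRanges::end(gr) <=
              gs[as.character(GenomicRanges::seqnames(gr))])
  }
  if (!inBounds(object@genes)) msgs <- c(msgs, "genes exceed genome bounds")
  if (!inBounds(object@enhancers)) {
    msgs <- c(msgs, "enhancers exceed genome bounds")
  }
  if (!all(vapply(object@peaks, inBounds, logical(1L)))) {
    msgs <- c(msgs, "peaks exceed genome bounds")
  }
  if (length(msgs) > 0L) msgs else TRUE
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset (profile \"%s\", seed %d)\n",
              object@profileName, object@seed))
  cat(sprintf("  genome: %d chromosome(s), %.3g Mb total\n",
              length(object@genomeSizes), sum(object@genomeSizes) / 1e6))
  cat(sprintf("  %d genes, %d enhancers (%d SE / %d TE), %d eRNA intervals\n",
              length(object@genes), length(object@enhancers),
              sum(object@enhancers$enh_class == "SE"),
              sum(object@enhancers$enh_class == "TE"), length(object@ernas)))
  cat(sprintf("  peaks: %s\n",
              paste(sprintf("%s=%d", names(object@peaks),
                            vapply(object@peaks, length, integer(1L))),
                    collapse = ", ")))
  cat(sprintf("  tracks: %s\n",
              if (length(object@tracks) == 0L) "(none)" else
                paste(names(object@tracks), collapse = ", ")))
})
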