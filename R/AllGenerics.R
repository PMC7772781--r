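#' @title Accessors for pafEnhancers S4 classes
#' @description CamelCase accessor generics for the package's central data
#'   objects; user code should use these rather than reaching into slots.
#' @param x An object of the documented class.
#' @param ... Passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("binWidth", function(x, ...) standardGeneric("binWidth"))

#' @rdname accessors
#' @export
setGeneric("totalMass", function(x, ...) standardGeneric("totalMass"))

#' @rdname accessors
#' @export
setGeneric("trackNorm", function(x, ...) standardGeneric("trackNorm"))

#' @rdname accessors
#' @export
setGeneric("trackValues", function(x, ...) standardGeneric("trackValues"))

#' @rdname accessors
#' @export
setGeneric("toRPM", function(x, ...) standardGeneric("toRPM"))

#' @rdname accessors
#' @export
setGeneric("occupancyCalls", function(x, ...)
  standardGeneric("occupancyCalls"))

#' @rdname accessors
#' @export
setGeneric("occupancyProvenance", function(x, ...)
  standardGeneric("occupancyProvenance"))

#' @rdname accessors
#' @export
setGeneric("profileName", function(x, ...) standardGeneric("profileName"))

#' @rdname accessors
#' @export
setGeneric("promoterOffsets", function(x, ...)
  standardGeneric("promoterOffsets"))

#' @rdname accessors
#' @export
setGeneric("pairDistanceParams", function(x, ...)
  standardGeneric("pairDistanceParams"))

#' @rdname accessors
#' @export
setGeneric("enhancerCounts", function(x, ...)
  standardGeneric("enhancerCounts"))

#' @rdname accessors
#' @export
setGeneric("occupancyProbs", function(x, ...)
  standardGeneric("occupancyProbs"))

#' @rdname accessors
#' @export
setGeneric("knockdownModel", function(x, ...)
  standardGeneric("knockdownModel"))

#' @rdname accessors
#' @export
setGeneric("genomeSizes", function(x, ...) standardGeneric("genomeSizes"))

#' @rdname accessors
#' @export
setGeneric("datasetGenes", function(x, ...) standardGeneric("datasetGenes"))

#' @rdname accessors
#' @export
setGeneric("datasetEnhancers", function(x, ...)
  standardGeneric("datasetEnhancers"))

#' @rdname accessors
#' @export
setGeneric("datasetPeaks", function(x, ...) standardGeneric("datasetPeaks"))

#' @rdname accessors
#' @export
setGeneric("datasetTracks", function(x, ...)
  standardGeneric("datasetTracks"))

#' @rdname accessors
#' @export
setGeneric("datasetExpression", function(x, ...)
  standardGeneric("datasetExpression"))

#' @rdname accessors
#' @export
setGeneric("datasetErnas", function(x, ...) standardGeneric("datasetErnas"))

#' @rdname accessors
#' @export
setGeneric("plantMap", function(x, ...) standardGeneric("plantMap"))

#' @rdname accessors
#' @export
setMethod("binWidth", "SignalTrack", function(x, ...) x@binWidth)

#' @rdname accessors
#' @export
setMethod("totalMass", "SignalTrack", function(x, ...) x@totalMass)

#' @rdname accessors
#' @export
setMethod("trackNorm", "SignalTrack", function(x, ...) x@norm)

#' @rdname accessors
#' @export
setMethod("trackValues", "SignalTrack", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("occupancyCalls", "OccupancyMatrix", function(x, ...) x@calls)

#' @describeIn accessors Supporting peak names for one cell (empty if the
#'   cell is FALSE).
#' @param region Region id (single string).
#' @param factor Factor label (single string).
#' @export
setMethod("occupancyProvenance", "OccupancyMatrix",
  function(x, region, factor, ...) {
    if (!factor %in% colnames(x@calls)) {
      .stopf("unknown factor '%s'", factor)
    }
    if (!region %in% rownames(x@calls)) {
      .stopf("unknown region '%s'", region)
    }
    out <- x@provenance[[factor]][[region]]
    if (is.null(out)) character() else out
  })

#' @rdname accessors
#' @export
setMethod("profileName", "CalibrationProfile", function(x, ...) x@name)

#' @rdname accessors
#' @export
setMethod("promoterOffsets", "CalibrationProfile",
          function(x, ...) x@promoterOffsets)

#' @rdname accessors
#' @export
setMethod("pairDistanceParams", "CalibrationProfile",
          function(x, ...) x@pairDistance)

#' @rdname accessors
#' @export
setMethod("enhancerCounts", "CalibrationProfile", function(x, ...) x@counts)

#' @rdname accessors
#' @export
setMethod("occupancyProbs", "CalibrationProfile", function(x, ...) x@occProb)

#' @rdname accessors
#' @export
setMethod("knockdownModel", "CalibrationProfile",
          function(x, ...) x@knockdown)

#' @rdname accessors
#' @export
setMethod("genomeSizes", "SyntheticDataset", function(x, ...) x@genomeSizes)

#' @rdname accessors
#' @export
setMethod("datasetGenes", "SyntheticDataset", function(x, ...) x@genes)

#' @rdname accessors
#' @export
setMethod("datasetEnhancers", "SyntheticDataset",
          function(x, ...) x@enhancers)

#' @rdname accessors
#' @export
setMethod("datasetPeaks", "SyntheticDataset", function(x, ...) x@peaks)

#' @rdname accessors
#' @export
setMethod("datasetTracks", "SyntheticDataset", function(x, ...) x@tracks)

#' @rdname accessors
#' @export
setMethod("datasetExpression", "SyntheticDataset",
          function(x, ...) x@expression)

#' @rdname accessors
#' @export
setMethod("datasetErnas", "SyntheticDataset", function(x, ...) x@ernas)

#' @rdname accessors
#' @export
setMethod("plantMap", "SyntheticDataset", function(x, ...) x@plantMap)
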