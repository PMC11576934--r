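#' Accessors for hyposeg containers
#'
#' @param object a hyposeg S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(object) standardGeneric("volData"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))
#' @rdname accessors
#' @export
setGeneric("lutTable", function(object) standardGeneric("lutTable"))
#' @rdname accessors
#' @export
setGeneric("probData", function(object) standardGeneric("probData"))
#' @rdname accessors
#' @export
setGeneric("classIds", function(object) standardGeneric("classIds"))
#' @rdname accessors
#' @export
setGeneric("labelMap", function(object) standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setGeneric("structureVolumes", function(object) standardGeneric("structureVolumes"))
#' @rdname accessors
#' @export
setGeneric("metricRows", function(object) standardGeneric("metricRows"))
#' @rdname accessors
#' @export
setGeneric("metricAggregates", function(object) standardGeneric("metricAggregates"))

#' Count trainable parameters of a network
#'
#' Counts every trainable scalar: convolution kernels and biases,
#' batch-norm scale/shift, per-channel PReLU slopes, the two global fusion
#' weights (hetero-modal networks) and the classifier.
#'
#' @param object an [HMVINN-class] network.
#' @return integer count.
#' @export
setGeneric("countParameters", function(object) standardGeneric("countParameters"))

#' @rdname accessors
#' @export
setMethod("volData", "BrainVolume", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("voxelSize", "BrainVolume", function(object) object@voxelSize)
#' @rdname accessors
#' @export
setMethod("modality", "BrainVolume", function(object) object@modality)
#' @rdname accessors
#' @export
setMethod("voxelSize", "ProbabilityMap", function(object) object@voxelSize)
#' @rdname accessors
#' @export
setMethod("lutTable", "LabelLookup", function(object) object@table)
#' @rdname accessors
#' @export
setMethod("probData", "ProbabilityMap", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("classIds", "ProbabilityMap", function(object) object@classIds)
#' @rdname accessors
#' @export
setMethod("labelMap", "SegmentationResult", function(object) object@labelmap)
#' @rdname accessors
#' @export
setMethod("structureVolumes", "SegmentationResult",
          function(object) object@volumes)
#' @rdname accessors
#' @export
setMethod("metricRows", "MetricsReport", function(object) object@rows)
#' @rdname accessors
#' @export
setMethod("metricAggregates", "MetricsReport",
          function(object) object@aggregates)
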