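#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes. Slots are never
#' accessed directly by user code.
#'
#' @param x an object of one of the package's classes.
#' @return `depth` the tag count of a [TagSet]; `sampleId` the sample
#'   label; `tags` the width-1 tag `GRanges`; `cutWindows` the window
#'   `GRanges` of a [CutTrack]; `trueDhs`/`tssSites` the planted truth
#'   intervals of a [SimTruth]; `assignments`, `centroids` and
#'   `clusterLabels` the components of a [ClusterModel];
#'   `fdrEstimate` and `fdrThreshold` the components of an
#'   [FdrCalibration].
#' @name accessors
#' @aliases depth sampleId tags cutWindows trueDhs tssSites assignments
#'   centroids clusterLabels fdrEstimate fdrThreshold
NULL

#' @rdname accessors
#' @export
setGeneric("depth", function(x) standardGeneric("depth"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("tags", function(x) standardGeneric("tags"))
#' @rdname accessors
#' @export
setGeneric("cutWindows", function(x) standardGeneric("cutWindows"))
#' @rdname accessors
#' @export
setGeneric("trueDhs", function(x) standardGeneric("trueDhs"))
#' @rdname accessors
#' @export
setGeneric("tssSites", function(x) standardGeneric("tssSites"))
#' @rdname accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))
#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("fdrEstimate", function(x) standardGeneric("fdrEstimate"))
#' @rdname accessors
#' @export
setGeneric("fdrThreshold", function(x) standardGeneric("fdrThreshold"))
#' @rdname accessors
#' @export
setGeneric("nullHotspotCounts", function(x) standardGeneric("nullHotspotCounts"))

#' @rdname accessors
#' @export
setMethod("depth", "TagSet", function(x) length(x@tags))
#' @rdname accessors
#' @export
setMethod("sampleId", "TagSet", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("sampleId", "CutTrack", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("tags", "TagSet", function(x) x@tags)
#' @rdname accessors
#' @export
setMethod("cutWindows", "CutTrack", function(x) x@windows)
#' @rdname accessors
#' @export
setMethod("trueDhs", "SimTruth", function(x) x@dhs)
#' @rdname accessors
#' @export
setMethod("tssSites", "SimTruth", function(x) x@tss)
#' @rdname accessors
#' @export
setMethod("assignments", "ClusterModel", function(x) x@assignments)
#' @rdname accessors
#' @export
setMethod("centroids", "ClusterModel", function(x) x@centroids)
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterModel", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("fdrEstimate", "FdrCalibration", function(x) x@fdrEstimate)
#' @rdname accessors
#' @export
setMethod("fdrThreshold", "FdrCalibration", function(x) x@threshold)
#' @rdname accessors
#' @export
setMethod("nullHotspotCounts", "FdrCalibration", function(x) x@nullCounts)
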