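#' Pixel calibration accessor
#'
#' @param object an object carrying a pixel calibration.
#' @return Micrometres per pixel edge.
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname pixelSize
setMethod("pixelSize", "CalibratedImage", function(object) object@pixelSize)
#' @rdname pixelSize
setMethod("pixelSize", "LabelMask", function(object) object@pixelSize)
#' @rdname pixelSize
setMethod("pixelSize", "RelativeDepthField", function(object) object@pixelSize)
#' @rdname pixelSize
setMethod("pixelSize", "DabBlobSet", function(object) object@pixelSize)
#' @rdname pixelSize
setMethod("pixelSize", "DetectionParams", function(object) object@pixelSize)

#' Pixel data accessor
#'
#' @param object a [CalibratedImage-class].
#' @return The H x W x 3 intensity array (values 0-255).
#' @export
setGeneric("pixelArray", function(object) standardGeneric("pixelArray"))

#' @rdname pixelArray
setMethod("pixelArray", "CalibratedImage", function(object) object@pixels)

#' Tissue label accessor
#'
#' @param object a [LabelMask-class].
#' @return Integer matrix of tissue codes (see [TISSUE_CLASSES]).
#' @export
setGeneric("tissueLabels", function(object) standardGeneric("tissueLabels"))

#' @rdname tissueLabels
setMethod("tissueLabels", "LabelMask", function(object) object@labels)

#' Tissue mask accessors
#'
#' @param object a [TissueMasks-class].
#' @return Logical matrix.
#' @export
setGeneric("innerMask", function(object) standardGeneric("innerMask"))
#' @rdname innerMask
setMethod("innerMask", "TissueMasks", function(object) object@inner)

#' @rdname innerMask
#' @export
setGeneric("outerMask", function(object) standardGeneric("outerMask"))
#' @rdname innerMask
setMethod("outerMask", "TissueMasks", function(object) object@outer)

#' Depth-field accessors
#'
#' @param object a [RelativeDepthField-class].
#' @return Numeric matrix (relative depth, or micrometre distances).
#' @export
setGeneric("depthRel", function(object) standardGeneric("depthRel"))
#' @rdname depthRel
setMethod("depthRel", "RelativeDepthField", function(object) object@dRel)

#' @rdname depthRel
#' @export
setGeneric("depthFromEpi", function(object) standardGeneric("depthFromEpi"))
#' @rdname depthRel
setMethod("depthFromEpi", "RelativeDepthField", function(object) object@dTopEpi)

#' @rdname depthRel
#' @export
setGeneric("depthFromDerm", function(object) standardGeneric("depthFromDerm"))
#' @rdname depthRel
setMethod("depthFromDerm", "RelativeDepthField",
    function(object) object@dTopDerm)

#' Blob accessors
#'
#' @param object a [DabBlobSet-class].
#' @return `blobTable` returns the per-blob measurement data.frame;
#'   `blobPixels` the list of (row, col) pixel matrices; `nBlobs` the
#'   number of detected areas.
#' @export
setGeneric("blobTable", function(object) standardGeneric("blobTable"))
#' @rdname blobTable
setMethod("blobTable", "DabBlobSet", function(object) object@blobs)

#' @rdname blobTable
#' @export
setGeneric("blobPixels", function(object) standardGeneric("blobPixels"))
#' @rdname blobTable
setMethod("blobPixels", "DabBlobSet", function(object) object@pixels)

#' @rdname blobTable
#' @export
setGeneric("nBlobs", function(object) standardGeneric("nBlobs"))
#' @rdname blobTable
setMethod("nBlobs", "DabBlobSet", function(object) nrow(object@blobs))

#' Depth-distribution accessors
#'
#' @param object a [DepthDistribution-class].
#' @return `perPixelDepths` returns the pooled per-pixel relative depths,
#'   `perBlobDepths` the per-blob mean depths.
#' @export
setGeneric("perPixelDepths", function(object) standardGeneric("perPixelDepths"))
#' @rdname perPixelDepths
setMethod("perPixelDepths", "DepthDistribution",
    function(object) object@perPixelRel)

#' @rdname perPixelDepths
#' @export
setGeneric("perBlobDepths", function(object) standardGeneric("perBlobDepths"))
#' @rdname perPixelDepths
setMethod("perBlobDepths", "DepthDistribution",
    function(object) object@perBlobRel)

#' @rdname perPixelDepths
#' @export
setGeneric("phantomImage", function(object) standardGeneric("phantomImage"))
#' @rdname perPixelDepths
setMethod("phantomImage", "SkinPhantom", function(object) object@image)

#' @rdname perPixelDepths
#' @export
setGeneric("phantomTruth", function(object) standardGeneric("phantomTruth"))
#' @rdname perPixelDepths
setMethod("phantomTruth", "SkinPhantom", function(object) object@truth)

#' @rdname perPixelDepths
#' @export
setGeneric("phantomBlobs", function(object) standardGeneric("phantomBlobs"))
#' @rdname perPixelDepths
setMethod("phantomBlobs", "SkinPhantom", function(object) object@blobs)

setMethod("dim", "CalibratedImage", function(x) dim(x@pixels)[1:2])
setMethod("dim", "LabelMask", function(x) dim(x@labels))
setMethod("dim", "RelativeDepthField", function(x) dim(x@dRel))
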