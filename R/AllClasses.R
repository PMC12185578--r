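#' @import methods
NULL

#' Tissue class codes
#'
#' Integer codes used throughout the package for per-pixel tissue labels:
#' 0 = outside the sample, 1 = squamous layer (stratum corneum),
#' 2 = epidermis, 3 = dermis.
#'
#' @format Named integer vector of length 4.
#' @export
TISSUE_CLASSES <- c(outside = 0L, squamous = 1L, epidermis = 2L, dermis = 3L)

#' CalibratedImage: an RGB brightfield image with pixel calibration
#'
#' Holds an H x W x 3 array of integer intensities in \[0, 255\] together
#' with the physical pixel size in micrometres per pixel edge (isotropic).
#' Pixel centres sit at integer coordinates; the image origin is the
#' top-left pixel, x indexes columns and y indexes rows (0-based in all
#' micrometre/pixel coordinate conversions).
#'
#' @slot pixels numeric array, H x W x 3, values in \[0, 255\].
#' @slot pixelSize positive numeric, micrometres per pixel.
#' @export
setClass("CalibratedImage",
    representation(pixels = "array", pixelSize = "numeric"))

setValidity("CalibratedImage", function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3] != 3L)
        return("pixels must be an H x W x 3 array (expected 3 channels)")
    if (d[1] < 1L || d[2] < 1L)
        return("image must have at least one row and one column")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
        return("pixelSize must be a single positive number")
    if (anyNA(object@pixels) || min(object@pixels) < 0 ||
        max(object@pixels) > 255)
        return("pixel intensities must lie in [0, 255]")
    TRUE
})

#' Construct a CalibratedImage
#'
#' @param pixels H x W x 3 numeric array of intensities in \[0, 255\].
#' @param pixelSize micrometres per pixel edge (isotropic).
#' @return A [CalibratedImage-class] object.
#' @examples
#' img <- CalibratedImage(array(255, dim = c(4, 4, 3)), pixelSize = 0.6892)
#' pixelSize(img)
#' @export
CalibratedImage <- function(pixels, pixelSize) {
    storage.mode(pixels) <- "double"
    new("CalibratedImage", pixels = pixels, pixelSize = as.numeric(pixelSize))
}

#' SquareRegion: an axis-aligned square region of interest
#'
#' Regions are defined in micrometres in the image frame (origin at the
#' centre of the top-left pixel). Typical use mirrors the 3-5 square
#' regions of 500 x 500 um placed on a section for analysis.
#'
#' @slot originX,originY numeric, top-left corner in micrometres.
#' @slot side positive numeric, side length in micrometres.
#' @export
setClass("SquareRegion",
    representation(originX = "numeric", originY = "numeric", side = "numeric"))

setValidity("SquareRegion", function(object) {
    if (object@side <= 0) return("side must be positive")
    TRUE
})

#' @rdname SquareRegion-class
#' @param originX,originY top-left corner of the square, micrometres.
#' @param side side length, micrometres.
#' @export
SquareRegion <- function(originX, originY, side) {
    new("SquareRegion", originX = as.numeric(originX),
        originY = as.numeric(originY), side = as.numeric(side))
}

#' LabelMask: per-pixel tissue classification
#'
#' @slot labels integer matrix with values in \{0, 1, 2, 3\}
#'   (see [TISSUE_CLASSES]).
#' @slot pixelSize positive numeric, micrometres per pixel.
#' @export
setClass("LabelMask",
    representation(labels = "matrix", pixelSize = "numeric"))

setValidity("LabelMask", function(object) {
    if (!all(object@labels %in% 0:3))
        return("labels must take values in {0, 1, 2, 3}")
    if (object@pixelSize <= 0) return("pixelSize must be positive")
    TRUE
})

#' Construct a LabelMask
#'
#' @param labels integer matrix of tissue codes in \{0, 1, 2, 3\}.
#' @param pixelSize micrometres per pixel.
#' @return A [LabelMask-class].
#' @export
LabelMask <- function(labels, pixelSize) {
    storage.mode(labels) <- "integer"
    new("LabelMask", labels = labels, pixelSize = as.numeric(pixelSize))
}

#' StainBasis: per-channel optical-density vectors for the two stains
#'
#' Unit 3-vectors of per-channel optical-density fractions for the DAB
#' chromogen and the (fast-red-type) nuclear counterstain, plus the white
#' reference intensity.
#'
#' @slot dab,counterstain non-negative unit 3-vectors.
#' @slot i0 white reference intensity (default 255).
#' @export
setClass("StainBasis",
    representation(dab = "numeric", counterstain = "numeric", i0 = "numeric"))

setValidity("StainBasis", function(object) {
    for (v in list(object@dab, object@counterstain)) {
        if (length(v) != 3L || any(v < 0))
            return("stain vectors must be non-negative 3-vectors")
        if (abs(sqrt(sum(v^2)) - 1) > 1e-6)
            return("stain vectors must have unit Euclidean norm")
    }
    cr <- crossprod(cbind(object@dab, object@counterstain))
    if (abs(det(cr)) < 1e-8) return("stain vectors must be linearly independent")
    if (object@i0 <= 0) return("i0 must be positive")
    TRUE
})

#' TissueMasks: the two binary masks used for the distance maps
#'
#' `inner` covers epidermis plus flood-filled dermis; `outer` covers
#' outside/squamous plus epidermis. The two overlap exactly on the
#' epidermis and jointly cover the image.
#'
#' @slot inner,outer logical matrices of the image shape.
#' @slot pixelSize micrometres per pixel.
#' @export
setClass("TissueMasks",
    representation(inner = "matrix", outer = "matrix", pixelSize = "numeric"))

setValidity("TissueMasks", function(object) {
    if (!identical(dim(object@inner), dim(object@outer)))
        return("inner and outer masks must share a shape")
    if (!is.logical(object@inner) || !is.logical(object@outer))
        return("masks must be logical")
    if (!all(object@inner | object@outer))
        return("inner and outer masks must jointly cover every pixel")
    TRUE
})

#' RelativeDepthField: per-pixel depth coordinate within the epidermis
#'
#' Carries the two Euclidean distance maps (micrometres) and the relative
#' depth d_rel = D_top-epidermis / (D_top-epidermis + D_top-dermis), which
#' is 0 on outside/squamous pixels, 1 on dermis pixels and strictly inside
#' (0, 1) on epidermis pixels.
#'
#' @slot dTopEpi,dTopDerm numeric matrices, micrometres.
#' @slot dRel numeric matrix in \[0, 1\].
#' @slot pixelSize micrometres per pixel.
#' @export
setClass("RelativeDepthField",
    representation(dTopEpi = "matrix", dTopDerm = "matrix", dRel = "matrix",
                   pixelSize = "numeric"))

setValidity("RelativeDepthField", function(object) {
    if (!identical(dim(object@dRel), dim(object@dTopEpi)) ||
        !identical(dim(object@dRel), dim(object@dTopDerm)))
        return("distance maps and dRel must share a shape")
    if (anyNA(object@dRel) || any(!is.finite(object@dRel)))
        return("dRel must be finite everywhere")
    if (min(object@dRel) < 0 || max(object@dRel) > 1)
        return("dRel must lie in [0, 1]")
    TRUE
})

#' DetectionParams: DAB area-detection parameters
#'
#' The parameter block of the automated DAB detection, with the optimized
#' values used for CD1a sections as defaults: detection operates on the
#' optical-density sum at a working pixel size of 0.6892 um, subtracts a
#' 20 um local background, blurs with a 2 um Gaussian, thresholds at OD
#' 0.20, keeps 8-connected components between 5 and 40000 um^2, and
#' excludes pixels whose background exceeds OD 2.0.
#'
#' @slot pixelSize working pixel size, um (0.6892).
#' @slot backgroundRadius background opening radius, um (20).
#' @slot medianRadius median pre-filter radius, um (0 = off).
#' @slot gaussianSigma Gaussian blur sigma, um (2).
#' @slot minArea,maxArea area bounds, um^2 (5, 40000).
#' @slot threshold OD-sum threshold (0.20).
#' @slot maxBackground maximum tolerated background OD (2.0).
#' @slot splitByShape logical, watershed splitting of touching areas
#'   (FALSE: plain connected components).
#' @slot smoothBoundaries logical, smooth component boundaries (TRUE).
#' @export
setClass("DetectionParams",
    representation(pixelSize = "numeric", backgroundRadius = "numeric",
                   medianRadius = "numeric", gaussianSigma = "numeric",
                   minArea = "numeric", maxArea = "numeric",
                   threshold = "numeric", maxBackground = "numeric",
                   splitByShape = "logical", smoothBoundaries = "logical"))

setValidity("DetectionParams", function(object) {
    lens <- c(object@pixelSize, object@backgroundRadius, object@medianRadius,
              object@gaussianSigma)
    if (object@pixelSize <= 0) return("pixelSize must be positive")
    if (any(lens < 0)) return("lengths must be non-negative")
    if (object@minArea > object@maxArea)
        return("minArea must not exceed maxArea")
    if (object@threshold <= 0) return("threshold must be positive")
    TRUE
})

#' DabBlobSet: detected DAB-positive areas of one region
#'
#' A table of per-blob measurements plus the per-blob pixel coordinate
#' sets and boundary polygons. Blobs are ordered by the (row, column) of
#' their topmost-leftmost pixel and numbered from 1.
#'
#' @slot blobs data.frame with one row per blob (id, n_pixels, area_um2,
#'   centroid_x_um, centroid_y_um, mean_od_sum and, once depths are
#'   attached, mean_d_rel, mean_dist_from_epi_um, mean_dist_from_derm_um).
#' @slot pixels list of 2-column integer matrices (row, col), 1-based on
#'   the detection grid.
#' @slot polygons list of 2-column matrices (x_um, y_um) tracing each
#'   blob boundary.
#' @slot pixelDepths list of numeric vectors: d_rel at each blob pixel
#'   (empty until depths are attached).
#' @slot pixelSize detection-grid pixel size, um.
#' @export
setClass("DabBlobSet",
    representation(blobs = "data.frame", pixels = "list", polygons = "list",
                   pixelDepths = "list", pixelSize = "numeric"))

setValidity("DabBlobSet", function(object) {
    n <- nrow(object@blobs)
    if (length(object@pixels) != n || length(object@polygons) != n)
        return("pixels and polygons must have one entry per blob")
    TRUE
})

#' PixelClassifierModel: trained tissue pixel classifier
#'
#' A seed-fixed ensemble of decision trees over multiscale
#' intensity/optical-density features, together with the feature recipe
#' needed to reproduce the feature stack at prediction time.
#'
#' @slot model the fitted ranger forest.
#' @slot scales Gaussian feature scales, micrometres.
#' @slot featureNames character, deterministic feature ordering.
#' @slot i0 white reference used for optical densities.
#' @slot trainAccuracy training-set accuracy.
#' @slot seed integer seed the forest was grown with.
#' @slot version package version string.
#' @export
setClass("PixelClassifierModel",
    representation(model = "ANY", scales = "numeric",
                   featureNames = "character", i0 = "numeric",
                   trainAccuracy = "numeric", seed = "integer",
                   version = "character"))

#' SkinPhantom: synthetic skin section with ground truth
#'
#' @slot image the rendered [CalibratedImage-class].
#' @slot truth ground-truth [LabelMask-class].
#' @slot blobs data.frame of planted DAB blobs (id, center_row, center_col,
#'   radius_um, d_rel).
#' @slot blobPixels list of (row, col) matrices for each planted blob.
#' @slot config the generating configuration list.
#' @export
setClass("SkinPhantom",
    representation(image = "CalibratedImage", truth = "LabelMask",
                   blobs = "data.frame", blobPixels = "list",
                   config = "list"))

#' DepthDistribution: pooled depth values for one condition
#'
#' Per-pixel relative depths (one value per DAB-positive pixel, pooled
#' over replicate sections), the matching absolute distances in
#' micrometres, per-blob mean depths, and replicate provenance.
#'
#' @slot condition condition identifier.
#' @slot perPixelRel numeric, d_rel per DAB-positive pixel.
#' @slot perPixelAbsEpi,perPixelAbsDerm numeric, per-pixel absolute
#'   distances from the epidermis top / the dermis, micrometres.
#' @slot perBlobRel numeric, mean d_rel per blob.
#' @slot pixelReplicate,blobReplicate character provenance per value.
#' @export
setClass("DepthDistribution",
    representation(condition = "character", perPixelRel = "numeric",
                   perPixelAbsEpi = "numeric", perPixelAbsDerm = "numeric",
                   perBlobRel = "numeric", pixelReplicate = "character",
                   blobReplicate = "character"))

setValidity("DepthDistribution", function(object) {
    if (length(object@perPixelRel) &&
        (min(object@perPixelRel) < 0 || max(object@perPixelRel) > 1))
        return("per-pixel relative depths must lie in [0, 1]")
    if (length(object@pixelReplicate) != length(object@perPixelRel))
        return("pixel provenance must match per-pixel values")
    TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "CalibratedImage", function(object) {
    d <- dim(object@pixels)
    cat(sprintf("CalibratedImage: %d x %d px (RGB), %.4f um/px (%.1f x %.1f um)\n",
        d[1], d[2], object@pixelSize,
        d[2] * object@pixelSize, d[1] * object@pixelSize))
})

setMethod("show", "LabelMask", function(object) {
    tab <- table(factor(object@labels, levels = 0:3,
                        labels = names(TISSUE_CLASSES)))
    cat(sprintf("LabelMask: %d x %d px, %.4f um/px\n",
        nrow(object@labels), ncol(object@labels), object@pixelSize))
    print(tab)
})

setMethod("show", "RelativeDepthField", function(object) {
    epi <- object@dRel > 0 & object@dRel < 1
    cat(sprintf(
        "RelativeDepthField: %d x %d px, %d epidermis px (d_rel in (0,1))\n",
        nrow(object@dRel), ncol(object@dRel), sum(epi)))
})

setMethod("show", "DetectionParams", function(object) {
    cat("DetectionParams (DAB area detection on OD sum):\n")
    cat(sprintf("  pixelSize        %.4f um\n", object@pixelSize))
    cat(sprintf("  backgroundRadius %g um   medianRadius %g um\n",
        object@backgroundRadius, object@medianRadius))
    cat(sprintf("  gaussianSigma    %g um   threshold %g OD\n",
        object@gaussianSigma, object@threshold))
    cat(sprintf("  area bounds      [%g, %g] um^2   maxBackground %g OD\n",
        object@minArea, object@maxArea, object@maxBackground))
    cat(sprintf("  splitByShape %s   smoothBoundaries %s\n",
        object@splitByShape, object@smoothBoundaries))
})

setMethod("show", "DabBlobSet", function(object) {
    cat(sprintf("DabBlobSet: %d DAB-positive areas, %.4f um/px\n",
        nrow(object@blobs), object@pixelSize))
    if (nrow(object@blobs))
        print(utils::head(object@blobs, 5))
})

setMethod("show", "DepthDistribution", function(object) {
    cat(sprintf(
        "DepthDistribution '%s': %d DAB-positive pixels, %d blobs, %d replicates\n",
        object@condition, length(object@perPixelRel),
        length(object@perBlobRel),
        length(unique(object@pixelReplicate))))
    if (length(object@perPixelRel))
        cat(sprintf("  per-pixel d_rel: mean %.3f, median %.3f\n",
            mean(object@perPixelRel), stats::median(object@perPixelRel)))
})

setMethod("show", "SkinPhantom", function(object) {
    cat(sprintf("SkinPhantom: %d planted DAB blobs, seed %s\n",
        nrow(object@blobs), format(object@config$seed)))
    show(object@image)
})
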