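#' Read a calibrated RGB brightfield image
#'
#' Reads a TIFF or PNG image into a [CalibratedImage-class]. For TIFF
#' input the pixel calibration is taken from the resolution tags when
#' present; otherwise (and always for PNG) the `pixelSize` argument is
#' used and the fallback is reported with a message.
#'
#' @param path path to a TIFF or PNG file.
#' @param pixelSize fallback pixel size, micrometres per pixel.
#' @return A [CalibratedImage-class].
#' @examples
#' f <- tempfile(fileext = ".png")
#' img <- CalibratedImage(array(200, dim = c(8, 8, 3)), 0.6892)
#' writeCalibratedImage(img, f)
#' readCalibratedImage(f, pixelSize = 0.6892)
#' @export
readCalibratedImage <- function(path, pixelSize = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    ps <- NULL
    if (ext %in% c("tif", "tiff")) {
        raw <- tiff::readTIFF(path, info = TRUE)
        xres <- attr(raw, "x.resolution")
        unit <- attr(raw, "resolution.unit")
        if (!is.null(xres) && is.finite(xres) && xres > 0) {
            ps <- switch(as.character(if (is.null(unit)) "inch" else unit),
                cm = 10000 / xres, inch = 25400 / xres, NULL)
        }
    } else if (ext == "png") {
        raw <- png::readPNG(path)
    } else {
        stop("unsupported image format: ", ext, " (expected TIFF or PNG)")
    }
    if (is.null(ps)) {
        sidecar <- paste0(path, ".calibration.json")
        if (file.exists(sidecar)) {
            ps <- jsonlite::read_json(sidecar)$pixel_size_um
        } else {
            if (is.null(pixelSize))
                stop("no pixel calibration in file or sidecar and no ",
                     "pixelSize supplied")
            message("using configured pixel size ", pixelSize,
                    " um/px for ", path)
            ps <- pixelSize
        }
    }
    if (ps <= 0) stop("non-positive pixel calibration")
    if (length(dim(raw)) != 3L || dim(raw)[3] < 3L)
        stop("expected 3 channels (RGB), got ",
             if (length(dim(raw)) == 2L) 1L else dim(raw)[3])
    arr <- round(raw[, , 1:3, drop = FALSE] * 255)
    CalibratedImage(arr, ps)
}

#' Write a calibrated image to TIFF or PNG
#'
#' The calibration travels in a JSON sidecar file
#' (`<path>.calibration.json`) that [readCalibratedImage()] recognises;
#' TIFF resolution tags, when present in externally produced files, take
#' precedence on re-read.
#'
#' @param img a [CalibratedImage-class].
#' @param path destination path, extension .tif/.tiff or .png.
#' @return `path`, invisibly.
#' @export
writeCalibratedImage <- function(img, path) {
    arr <- pixelArray(img) / 255
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
        tiff::writeTIFF(arr, path, bits.per.sample = 8L)
    } else if (ext == "png") {
        png::writePNG(arr, path)
    } else {
        stop("unsupported image format: ", ext)
    }
    jsonlite::write_json(list(pixel_size_um = pixelSize(img)),
                         paste0(path, ".calibration.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Crop a square region out of a calibrated raster
#'
#' The region is given in micrometres in the image frame and converted to
#' 0-based half-open pixel ranges with round-half-up on both the origin
#' and the side length, so a 500 um square at 0.6892 um/px yields a
#' round(500/0.6892) = 725 px crop. Calibration is preserved.
#'
#' @param x a [CalibratedImage-class], [LabelMask-class] or
#'   [RelativeDepthField-class].
#' @param region a [SquareRegion-class] fully inside the image.
#' @return An object of the same class covering only the region.
#' @export
setGeneric("cropRegion", function(x, region) standardGeneric("cropRegion"))

.regionToPx <- function(region, pixelSize, dims) {
    c0 <- .umToPx(region@originX, pixelSize)
    r0 <- .umToPx(region@originY, pixelSize)
    n <- .umToPx(region@side, pixelSize)
    if (n < 1L) stop("region smaller than one pixel")
    if (c0 < 0L || r0 < 0L || c0 + n > dims[2] || r0 + n > dims[1])
        stop(sprintf(
            "region [%d..%d) x [%d..%d) px exceeds image bounds %d x %d",
            r0, r0 + n, c0, c0 + n, dims[1], dims[2]))
    list(rows = (r0 + 1L):(r0 + n), cols = (c0 + 1L):(c0 + n))
}

#' @rdname cropRegion
setMethod("cropRegion", "CalibratedImage", function(x, region) {
    px <- .regionToPx(region, x@pixelSize, dim(x))
    CalibratedImage(x@pixels[px$rows, px$cols, , drop = FALSE], x@pixelSize)
})

#' @rdname cropRegion
setMethod("cropRegion", "LabelMask", function(x, region) {
    px <- .regionToPx(region, x@pixelSize, dim(x))
    LabelMask(x@labels[px$rows, px$cols, drop = FALSE], x@pixelSize)
})

#' @rdname cropRegion
setMethod("cropRegion", "RelativeDepthField", function(x, region) {
    px <- .regionToPx(region, x@pixelSize, dim(x))
    new("RelativeDepthField",
        dTopEpi = x@dTopEpi[px$rows, px$cols, drop = FALSE],
        dTopDerm = x@dTopDerm[px$rows, px$cols, drop = FALSE],
        dRel = x@dRel[px$rows, px$cols, drop = FALSE],
        pixelSize = x@pixelSize)
})

#' Read a tissue label mask
#'
#' Raster input (PNG/TIFF) must be a single-channel image whose raw
#' values are the tissue codes 0-3 (see [TISSUE_CLASSES]); GeoJSON input
#' (.json/.geojson) is rasterised onto the grid given by `dims`, with
#' polygons applied in file order over an all-outside base.
#'
#' @param path path to an indexed PNG/TIFF or a GeoJSON FeatureCollection.
#' @param pixelSize micrometres per pixel.
#' @param dims image dimensions c(H, W); required for GeoJSON input.
#' @return A [LabelMask-class].
#' @export
readLabelMask <- function(path, pixelSize, dims = NULL) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("json", "geojson")) {
        if (is.null(dims))
            stop("dims = c(H, W) required to rasterise GeoJSON annotations")
        annots <- readAnnotations(path)
        return(rasterizeAnnotations(annots, dims, pixelSize))
    }
    raw <- switch(ext,
        png = png::readPNG(path),
        tif = ,
        tiff = tiff::readTIFF(path),
        stop("unsupported label mask format: ", ext))
    if (length(dim(raw)) == 3L) {
        if (!all(raw[, , 1] == raw[, , 2]) || !all(raw[, , 1] == raw[, , 3]))
            stop("label mask must be single-channel")
        raw <- raw[, , 1]
    }
    lab <- round(raw * 255)
    if (!all(lab %in% 0:3))
        stop("labels outside {0..3}: found ",
             paste(utils::head(setdiff(unique(as.vector(lab)), 0:3), 5),
                   collapse = ", "))
    LabelMask(matrix(as.integer(lab), nrow(lab), ncol(lab)), pixelSize)
}

#' @rdname readLabelMask
#' @param mask a [LabelMask-class] to write.
#' @export
writeLabelMask <- function(mask, path) {
    ext <- tolower(tools::file_ext(path))
    x <- mask@labels / 255
    if (ext == "png") png::writePNG(x, path)
    else if (ext %in% c("tif", "tiff"))
        tiff::writeTIFF(x, path, bits.per.sample = 8L)
    else stop("unsupported label mask format: ", ext)
    invisible(path)
}

#' Read polygon annotations from GeoJSON
#'
#' Coordinates are micrometres in the image frame (x right, y down,
#' origin at the centre of the top-left pixel). Each feature must be a
#' Polygon whose `properties$classification` is one of outside, squamous,
#' epidermis, dermis. Self-intersecting rings are rejected.
#'
#' @param path path to a GeoJSON FeatureCollection.
#' @return List of annotations, each `list(label =, x =, y =)` with the
#'   label as an integer tissue code.
#' @export
readAnnotations <- function(path) {
    gj <- jsonlite::read_json(path)
    feats <- gj$features
    if (is.null(feats)) stop("not a GeoJSON FeatureCollection")
    lapply(seq_along(feats), function(i) {
        ft <- feats[[i]]
        if (!identical(ft$geometry$type, "Polygon"))
            stop("feature ", i, ": only Polygon geometries are supported")
        cls <- ft$properties$classification
        if (is.list(cls)) cls <- cls$name  # tolerate nested classification objects
        if (is.null(cls) || !cls %in% names(TISSUE_CLASSES))
            stop("feature ", i, ": classification must be one of ",
                 paste(names(TISSUE_CLASSES), collapse = ", "))
        ring <- ft$geometry$coordinates[[1]]
        x <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
        y <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
        # drop duplicated closing vertex
        if (length(x) > 1 && x[1] == x[length(x)] && y[1] == y[length(y)]) {
            x <- x[-length(x)]; y <- y[-length(y)]
        }
        if (length(x) < 3) stop("feature ", i, ": degenerate polygon")
        if (.polygonSelfIntersects(x, y))
            stop("feature ", i, ": self-intersecting polygon")
        list(label = unname(TISSUE_CLASSES[cls]), x = x, y = y)
    })
}

#' Rasterise polygon annotations to a label mask
#'
#' A pixel belongs to a polygon iff its centre lies inside it; polygons
#' are painted in list order, so later annotations overwrite earlier ones.
#'
#' @param annots annotations as returned by [readAnnotations()].
#' @param dims image dimensions c(H, W).
#' @param pixelSize micrometres per pixel.
#' @param base optional starting [LabelMask-class] to paint onto
#'   (default: all outside).
#' @return A [LabelMask-class].
#' @export
rasterizeAnnotations <- function(annots, dims, pixelSize, base = NULL) {
    lab <- if (is.null(base)) matrix(0L, dims[1], dims[2]) else base@labels
    for (a in annots) {
        inside <- .rasterizePolygon(a$x, a$y, pixelSize, dims[1], dims[2])
        lab[inside] <- as.integer(a$label)
    }
    LabelMask(lab, pixelSize)
}

#' Write detected DAB areas as GeoJSON
#'
#' Boundary polygons are written in micrometre coordinates with the blob
#' measurements attached as feature properties.
#'
#' @param blobs a [DabBlobSet-class] with depths attached (or not).
#' @param path destination .geojson path.
#' @return `path`, invisibly.
#' @export
writeBlobGeoJSON <- function(blobs, path) {
    tab <- blobTable(blobs)
    feats <- lapply(seq_len(nBlobs(blobs)), function(i) {
        poly <- blobs@polygons[[i]]
        ring <- lapply(seq_len(nrow(poly)), function(k) c(poly[k, 1], poly[k, 2]))
        ring[[length(ring) + 1]] <- ring[[1]]
        props <- as.list(tab[i, , drop = FALSE])
        list(type = "Feature",
             geometry = list(type = "Polygon", coordinates = list(ring)),
             properties = props)
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Write / read a depth field as 32-bit TIFF
#'
#' Writes three pages - relative depth, distance from the top of the
#' epidermis and distance from the dermis - as 32-bit samples. The
#' micrometre pages are stored normalised to \[0, 1\] with their scale
#' factors in a JSON sidecar (`<path>.scale.json`), which
#' [readDepthTiff()] uses to restore the original units.
#'
#' @param field a [RelativeDepthField-class].
#' @param path destination .tif path.
#' @return `path`, invisibly.
#' @export
writeDepthTiff <- function(field, path) {
    sEpi <- max(field@dTopEpi, 1)
    sDerm <- max(field@dTopDerm, 1)
    tiff::writeTIFF(list(field@dRel, field@dTopEpi / sEpi,
                         field@dTopDerm / sDerm),
                    path, bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(
        list(pages = c("d_rel", "dist_from_epi_um", "dist_from_derm_um"),
             scale = c(1, sEpi, sDerm),
             pixel_size_um = field@pixelSize),
        paste0(path, ".scale.json"), auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeDepthTiff
#' @export
readDepthTiff <- function(path) {
    meta <- jsonlite::read_json(paste0(path, ".scale.json"),
                                simplifyVector = TRUE)
    pages <- tiff::readTIFF(path, all = TRUE)
    toM <- function(x) matrix(as.numeric(x), nrow(x), ncol(x))
    new("RelativeDepthField",
        dRel = toM(pages[[1]]) * meta$scale[1],
        dTopEpi = toM(pages[[2]]) * meta$scale[2],
        dTopDerm = toM(pages[[3]]) * meta$scale[3],
        pixelSize = meta$pixel_size_um)
}
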