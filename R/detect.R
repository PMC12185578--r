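#' DAB area-detection parameters (optimized defaults)
#'
#' Constructor for [DetectionParams-class]; the defaults are the
#' parameter block optimized for DAB-stained CD1a sections. The minimum
#' and maximum area are interpreted in um^2 for dimensional consistency
#' with area semantics. `splitByShape = FALSE` means touching areas are
#' clustered by plain connected components, with no watershed splitting.
#'
#' @param pixelSize working pixel size, um.
#' @param backgroundRadius background opening radius, um.
#' @param medianRadius median pre-filter radius, um (0 disables).
#' @param gaussianSigma Gaussian blur sigma, um.
#' @param minArea,maxArea blob area bounds, um^2.
#' @param threshold OD-sum threshold.
#' @param maxBackground maximum tolerated background OD.
#' @param splitByShape watershed splitting of touching areas.
#' @param smoothBoundaries morphological boundary smoothing.
#' @return A [DetectionParams-class].
#' @examples
#' detectionParams()
#' @export
detectionParams <- function(pixelSize = 0.6892, backgroundRadius = 20,
                            medianRadius = 0, gaussianSigma = 2,
                            minArea = 5, maxArea = 40000,
                            threshold = 0.20, maxBackground = 2.0,
                            splitByShape = FALSE, smoothBoundaries = TRUE) {
    if (isTRUE(splitByShape))
        stop("shape-based splitting is not implemented; ",
             "the optimized parameter set disables it")
    new("DetectionParams", pixelSize = pixelSize,
        backgroundRadius = backgroundRadius, medianRadius = medianRadius,
        gaussianSigma = gaussianSigma, minArea = minArea, maxArea = maxArea,
        threshold = threshold, maxBackground = maxBackground,
        splitByShape = splitByShape, smoothBoundaries = smoothBoundaries)
}

#' Resample an image to the detection grid
#'
#' Bilinear resampling to the requested pixel size; identity when the
#' calibration already matches to within one part in 10^4.
#'
#' @param img a [CalibratedImage-class].
#' @param target target pixel size, um.
#' @return A [CalibratedImage-class] at the target calibration.
#' @export
resampleImage <- function(img, target) {
    if (target <= 0) stop("target pixel size must be positive")
    ps <- pixelSize(img)
    if (abs(ps - target) / target <= 1e-4) return(img)
    d <- dim(img)
    newH <- max(1L, as.integer(round(d[1] * ps / target)))
    newW <- max(1L, as.integer(round(d[2] * ps / target)))
    arr <- array(0, c(newH, newW, 3))
    for (c in 1:3)
        arr[, , c] <- as.matrix(EBImage::resize(
            pixelArray(img)[, , c], w = newH, h = newW, filter = "bilinear"))
    arr[arr < 0] <- 0; arr[arr > 255] <- 255
    CalibratedImage(arr, target)
}

#' Background estimation and subtraction for the detection channel
#'
#' The local background of the OD-sum image is estimated by grayscale
#' morphological opening with a disk structuring element, which removes
#' features smaller than the element while following slow intensity
#' trends; the corrected image is the non-negative residual. Pixels
#' whose background exceeds `maxBackground` (e.g. tissue folds, debris)
#' are flagged for exclusion.
#'
#' @param os OD-sum matrix.
#' @param radius background radius, um (0: background is identically 0).
#' @param maxBackground maximum tolerated background OD.
#' @param pixelSize um per pixel of `os`.
#' @return List with `corrected`, `background` (matrices) and
#'   `exclusion` (logical matrix).
#' @export
subtractBackground <- function(os, radius, maxBackground = 2.0,
                               pixelSize = 1) {
    if (radius < 0) stop("radius must be non-negative")
    rpx <- .roundHalfUp(radius / pixelSize)
    if (radius == 0 || rpx < 1) {
        bg <- matrix(0, nrow(os), ncol(os))
    } else {
        brush <- EBImage::makeBrush(2L * as.integer(rpx) + 1L, shape = "disc")
        # flat-SE opening is scale-equivariant; normalise to [0, 1] so the
        # morphology backend's intensity clamp cannot bite OD values > 1
        mx <- max(os, 1e-9)
        bg <- as.matrix(EBImage::opening(os / mx, brush)) * mx
    }
    corrected <- os - bg
    corrected[corrected < 0] <- 0
    list(corrected = corrected, background = bg,
         exclusion = bg > maxBackground)
}

# Extract the boundary polygon of one blob, in micrometres on the
# detection grid, optionally Douglas-Peucker simplified (tolerance px).
.blobPolygon <- function(pix, H, W, pixelSize, simplifyTol = 0) {
    r0 <- min(pix[, 1]); r1 <- max(pix[, 1])
    c0 <- min(pix[, 2]); c1 <- max(pix[, 2])
    sub <- matrix(0L, r1 - r0 + 3L, c1 - c0 + 3L)
    sub[cbind(pix[, 1] - r0 + 2L, pix[, 2] - c0 + 2L)] <- 1L
    ct <- EBImage::ocontour(sub)
    if (!length(ct)) {
        # single-pixel safety: unit square around the pixel centre
        return(matrix(c(pix[1, 2] - 1.5, pix[1, 2] - 0.5, pix[1, 2] - 0.5,
                        pix[1, 2] - 1.5, pix[1, 1] - 1.5, pix[1, 1] - 1.5,
                        pix[1, 1] - 0.5, pix[1, 1] - 0.5),
                      4, 2) * pixelSize)
    }
    poly <- ct[[1]]  # 0-based (dim1, dim2) = (row, col) of boundary pixels
    rows <- poly[, 1] + r0 - 1L   # back to 1-based full-grid rows
    cols <- poly[, 2] + c0 - 1L
    pts <- cbind(cols - 1, rows - 1)  # (x, y) in pixel units
    if (simplifyTol > 0 && nrow(pts) > 3)
        pts <- .douglasPeucker(pts, simplifyTol)
    pts * pixelSize
}

#' Detect DAB-positive areas
#'
#' Runs the detection chain on a calibrated RGB image: optional crop to
#' a square region, resampling to the working pixel size, conversion to
#' the OD-sum detection channel, optional median filter, Gaussian blur,
#' local background subtraction, fixed OD threshold, removal of pixels
#' under the background-exclusion mask, 8-connected component
#' clustering, an area filter, and optional boundary smoothing
#' (morphological closing of radius 1 px per component plus polygon
#' simplification at 0.5 px). Blobs are ordered by the (row, column) of
#' their topmost-leftmost pixel.
#'
#' @param img a [CalibratedImage-class].
#' @param params a [DetectionParams-class] (defaults: [detectionParams()]).
#' @param region optional [SquareRegion-class] to crop first.
#' @param i0 white reference intensity for the OD conversion.
#' @return A [DabBlobSet-class]; attach depths with
#'   [measureBlobDepths()].
#' @export
detectDabAreas <- function(img, params = detectionParams(), region = NULL,
                           i0 = 255) {
    validObject(params)
    if (!is.null(region)) img <- cropRegion(img, region)
    img <- resampleImage(img, params@pixelSize)
    ps <- pixelSize(img)
    os <- odSum(img, i0)
    if (params@medianRadius > 0) {
        rpx <- max(1L, .umToPx(params@medianRadius, ps))
        mx <- max(os, 1e-9)
        os <- as.matrix(EBImage::medianFilter(os / mx, size = rpx)) * mx
    }
    if (params@gaussianSigma > 0)
        os <- .gblur(os, params@gaussianSigma / ps)
    bg <- subtractBackground(os, params@backgroundRadius,
                             params@maxBackground, ps)
    bin <- bg$corrected > params@threshold
    bin[bg$exclusion] <- FALSE
    lab <- .labelConnected(bin, connectivity = 8)
    H <- nrow(bin); W <- ncol(bin)
    pxArea <- ps^2
    idx <- which(lab > 0L)
    groups <- split(idx, lab[idx])
    blobs <- list()
    for (g in groups) {
        pix <- cbind(row = ((g - 1L) %% H) + 1L, col = ((g - 1L) %/% H) + 1L)
        area <- nrow(pix) * pxArea
        if (area < params@minArea || area > params@maxArea) next
        if (params@smoothBoundaries) {
            r0 <- max(1L, min(pix[, 1]) - 2L); r1 <- min(H, max(pix[, 1]) + 2L)
            c0 <- max(1L, min(pix[, 2]) - 2L); c1 <- min(W, max(pix[, 2]) + 2L)
            sub <- matrix(0L, r1 - r0 + 1L, c1 - c0 + 1L)
            sub[cbind(pix[, 1] - r0 + 1L, pix[, 2] - c0 + 1L)] <- 1L
            closed <- as.matrix(EBImage::closing(
                sub, EBImage::makeBrush(3, shape = "diamond"))) > 0
            w <- which(closed, arr.ind = TRUE)
            pix <- cbind(row = w[, 1] + r0 - 1L, col = w[, 2] + c0 - 1L)
            keep <- !bg$exclusion[pix]      # closing must not re-add excluded px
            pix <- pix[keep, , drop = FALSE]
            area <- nrow(pix) * pxArea
        }
        blobs[[length(blobs) + 1]] <- list(pix = pix, area = area)
    }
    # deterministic ordering by topmost-leftmost pixel
    if (length(blobs)) {
        keys <- t(vapply(blobs, function(b) {
            r <- min(b$pix[, 1])
            c(r, min(b$pix[b$pix[, 1] == r, 2]))
        }, numeric(2)))
        blobs <- blobs[order(keys[, 1], keys[, 2])]
    }
    tab <- data.frame(id = seq_along(blobs),
        n_pixels = vapply(blobs, function(b) nrow(b$pix), integer(1)),
        area_um2 = vapply(blobs, function(b) b$area, numeric(1)),
        centroid_x_um = vapply(blobs, function(b)
            mean(b$pix[, 2] - 1) * ps, numeric(1)),
        centroid_y_um = vapply(blobs, function(b)
            mean(b$pix[, 1] - 1) * ps, numeric(1)),
        mean_od_sum = vapply(blobs, function(b)
            mean(bg$corrected[b$pix]), numeric(1)))
    if (!length(blobs))
        tab <- tab[0, ]
    polys <- lapply(blobs, function(b)
        .blobPolygon(b$pix, H, W, ps,
                     simplifyTol = if (params@smoothBoundaries) 0.5 else 0))
    new("DabBlobSet", blobs = tab,
        pixels = lapply(blobs, function(b) b$pix),
        polygons = polys, pixelDepths = vector("list", length(blobs)),
        pixelSize = ps)
}

#' Attach relative depths to detected blobs
#'
#' Samples the relative-depth field at every blob pixel (nearest-pixel
#' lookup if the detection grid and the field grid differ in
#' calibration) and adds the mean relative depth and the mean absolute
#' distances from the epidermis top and from the dermis to the blob
#' table.
#'
#' @param blobs a [DabBlobSet-class].
#' @param field a [RelativeDepthField-class] covering the same region.
#' @return The [DabBlobSet-class] with per-pixel depths and the columns
#'   `mean_d_rel`, `mean_dist_from_epi_um`, `mean_dist_from_derm_um`.
#' @export
measureBlobDepths <- function(blobs, field) {
    psd <- pixelSize(blobs); psf <- pixelSize(field)
    dimF <- dim(field)
    depths <- lapply(blobPixels(blobs), function(pix) {
        if (abs(psd - psf) / psf <= 1e-4 &&
            all(pix[, 1] <= dimF[1]) && all(pix[, 2] <= dimF[2])) {
            rr <- pix[, 1]; cc <- pix[, 2]
        } else {
            rr <- pmin(dimF[1], pmax(1L, .roundHalfUp((pix[, 1] - 1) * psd / psf) + 1L))
            cc <- pmin(dimF[2], pmax(1L, .roundHalfUp((pix[, 2] - 1) * psd / psf) + 1L))
        }
        ij <- cbind(rr, cc)
        data.frame(d_rel = field@dRel[ij],
                   dist_epi_um = field@dTopEpi[ij],
                   dist_derm_um = field@dTopDerm[ij])
    })
    tab <- blobTable(blobs)
    tab$mean_d_rel <- vapply(depths, function(d)
        if (nrow(d)) mean(d$d_rel) else NA_real_, numeric(1))
    tab$mean_dist_from_epi_um <- vapply(depths, function(d)
        if (nrow(d)) mean(d$dist_epi_um) else NA_real_, numeric(1))
    tab$mean_dist_from_derm_um <- vapply(depths, function(d)
        if (nrow(d)) mean(d$dist_derm_um) else NA_real_, numeric(1))
    new("DabBlobSet", blobs = tab, pixels = blobs@pixels,
        polygons = blobs@polygons, pixelDepths = depths,
        pixelSize = blobs@pixelSize)
}
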