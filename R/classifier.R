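#' Extract multiscale per-pixel features for tissue classification
#'
#' The feature stack holds, for every requested Gaussian scale, the
#' smoothed R, G, B intensities (0-1), the smoothed per-channel optical
#' densities and the smoothed OD sum: 7 features per scale, in a fixed,
#' documented order (R, G, B, ODR, ODG, ODB, ODsum per scale, scales in
#' the order given).
#'
#' @param img a [CalibratedImage-class].
#' @param scales Gaussian smoothing scales in micrometres (>= 1 scale,
#'   all positive). Scales below ~0.3 px are applied as identity.
#' @param i0 white reference for the optical densities.
#' @return Numeric matrix, (H*W) x (7 * length(scales)), pixels in
#'   column-major order, with an attribute `featureNames`.
#' @export
extractFeatures <- function(img, scales = c(1, 4), i0 = 255) {
    if (length(scales) < 1) stop("at least one scale required")
    if (any(scales <= 0)) stop("non-positive scale")
    arr <- pixelArray(img) / 255
    odl <- rgbToOD(img, i0)
    base <- list(R = arr[, , 1], G = arr[, , 2], B = arr[, , 3],
                 ODR = odl$od[, , 1], ODG = odl$od[, , 2],
                 ODB = odl$od[, , 3], ODsum = odl$odSum)
    ps <- pixelSize(img)
    cols <- list()
    nms <- character(0)
    for (s in scales) {
        sigma <- s / ps
        for (nm in names(base)) {
            f <- base[[nm]]
            if (sigma >= 0.3) f <- .gblur(f, sigma)
            cols[[length(cols) + 1]] <- as.vector(f)
            nms <- c(nms, sprintf("%s_s%g", nm, s))
        }
    }
    feat <- do.call(cbind, cols)
    colnames(feat) <- nms
    attr(feat, "featureNames") <- nms
    feat
}

#' Train the tissue pixel classifier
#'
#' Fits a seed-fixed random forest on sparse training scribbles. All
#' three tissue classes (squamous, epidermis, dermis) must be
#' represented; the outside class is never trained - it is derived at
#' prediction time from a whiteness rule.
#'
#' @param img a [CalibratedImage-class] (training image).
#' @param scribbles data.frame with columns `row`, `col` (1-based pixel
#'   indices) and `label` (integer codes 1-3, see [TISSUE_CLASSES]).
#' @param scales feature scales, micrometres (see [extractFeatures()]).
#' @param nTrees,maxDepth forest size and depth (0 = unlimited depth).
#' @param seed integer seed; identical inputs and seed give identical
#'   forests and predictions.
#' @param i0 white reference for OD features.
#' @return A [PixelClassifierModel-class]; its training accuracy is
#'   stored in the `trainAccuracy` slot.
#' @export
trainPixelClassifier <- function(img, scribbles, scales = c(1, 4),
                                 nTrees = 50, maxDepth = 0, seed = 1,
                                 i0 = 255) {
    need <- c(squamous = 1L, epidermis = 2L, dermis = 3L)
    present <- need %in% scribbles$label
    if (!all(present))
        stop("missing training class(es): ",
             paste(names(need)[!present], collapse = ", "))
    if (!all(scribbles$label %in% 1:3))
        stop("scribble labels must be tissue codes 1, 2, 3")
    feat <- extractFeatures(img, scales, i0)
    idx <- (scribbles$col - 1L) * nrow(pixelArray(img)[, , 1]) + scribbles$row
    df <- data.frame(label = factor(scribbles$label, levels = 1:3),
                     feat[idx, , drop = FALSE])
    fit <- ranger::ranger(label ~ ., data = df, num.trees = nTrees,
                          max.depth = maxDepth, seed = seed,
                          num.threads = 1)
    acc <- mean(stats::predict(fit, df, num.threads = 1)$predictions ==
                df$label)
    new("PixelClassifierModel", model = fit, scales = as.numeric(scales),
        featureNames = attr(feat, "featureNames"), i0 = i0,
        trainAccuracy = acc, seed = as.integer(seed),
        version = as.character(utils::packageVersion("skinDepth")))
}

#' Classify every pixel of an image into tissue classes
#'
#' Recomputes the model's feature stack, takes the per-pixel argmax
#' class, applies majority smoothing over a disk neighbourhood, and
#' finally forces near-white pixels (OD sum below `whiteThreshold`) to
#' the outside class - mirroring how background is excluded when the
#' tissue masks are built.
#'
#' @param model a [PixelClassifierModel-class].
#' @param img a [CalibratedImage-class].
#' @param smoothRadius majority-vote disk radius in pixels (0 = raw
#'   argmax; default 2).
#' @param whiteThreshold OD-sum threshold below which a pixel is outside
#'   the sample (default 0.05).
#' @return A [LabelMask-class].
#' @export
classifyPixels <- function(model, img, smoothRadius = 2,
                           whiteThreshold = 0.05) {
    feat <- extractFeatures(img, model@scales, model@i0)
    if (!identical(colnames(feat), model@featureNames))
        stop("feature recipe mismatch: model was trained with a ",
             "different scale set")
    H <- dim(img)[1]; W <- dim(img)[2]
    pred <- stats::predict(model@model, data.frame(feat),
                           num.threads = 1)$predictions
    lab <- matrix(as.integer(as.character(pred)), H, W)
    # the whiteness rule runs before smoothing so the (untrained) outside
    # class takes part in the majority vote: isolated noise specks in the
    # background are then outvoted instead of surviving as stray tissue
    os <- odSum(img, model@i0)
    lab[os < whiteThreshold] <- 0L
    if (smoothRadius > 0) {
        size <- 2L * as.integer(smoothRadius) + 1L
        disk <- EBImage::makeBrush(size, shape = "disc")
        votes <- lapply(0:3, function(k)
            as.matrix(EBImage::filter2(1 * (lab == k), disk,
                                       boundary = "replicate")))
        # argmax over classes; ties resolve to the lowest class code
        best <- votes[[1]]
        lab <- matrix(0L, H, W)
        for (k in 2:4) {
            better <- votes[[k]] > best
            lab[better] <- as.integer(k - 1L)
            best[better] <- votes[[k]][better]
        }
    }
    lab[os < whiteThreshold] <- 0L
    LabelMask(lab, pixelSize(img))
}

#' Apply file-based refinement edits to a label mask
#'
#' Replaces the interactive brush correction of a GUI workflow: each
#' polygon (micrometre coordinates) overwrites the pixels whose centres
#' it contains with its target label, in file/list order, so later
#' polygons win where edits overlap.
#'
#' @param mask a [LabelMask-class].
#' @param edits annotations as returned by [readAnnotations()], or a
#'   path to a GeoJSON file of them.
#' @return The refined [LabelMask-class].
#' @export
applyRefinement <- function(mask, edits) {
    if (is.character(edits)) edits <- readAnnotations(edits)
    if (!length(edits)) return(mask)
    rasterizeAnnotations(edits, dim(mask), mask@pixelSize, base = mask)
}

#' Save / load a trained pixel classifier
#'
#' Models are serialised with the package version recorded; loading a
#' model saved by a different feature-recipe version fails at prediction
#' time via the recipe check in [classifyPixels()].
#'
#' @param model a [PixelClassifierModel-class].
#' @param path destination .rds path.
#' @return `path` (save) or the model (load).
#' @export
saveClassifier <- function(model, path) {
    saveRDS(model, path)
    invisible(path)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(path) {
    model <- readRDS(path)
    if (!is(model, "PixelClassifierModel"))
        stop("not a saved PixelClassifierModel")
    model
}
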