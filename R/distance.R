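#' Euclidean distance map
#'
#' For every `TRUE` pixel, the exact Euclidean distance (between pixel
#' centres) to the nearest `FALSE` pixel, scaled to micrometres;
#' `FALSE` pixels map to 0. Exactness (rather than a chamfer
#' approximation) means a brute-force nearest-background search is an
#' equality oracle for this function.
#'
#' @param mask logical matrix with at least one `FALSE` pixel.
#' @param pixelSize micrometres per pixel (default 1: distances in px).
#' @return Numeric matrix of distances in micrometres.
#' @examples
#' m <- matrix(TRUE, 3, 3); m[1, 1] <- FALSE
#' distanceMap(m)[3, 3]  # 2*sqrt(2)
#' @export
distanceMap <- function(mask, pixelSize = 1) {
    if (!is.logical(mask)) storage.mode(mask) <- "logical"
    if (all(mask)) stop("all-true mask: no background pixel to measure from")
    d <- EBImage::distmap(EBImage::Image(mask * 1), metric = "euclidean")
    matrix(as.vector(EBImage::imageData(d)) * pixelSize,
           nrow(mask), ncol(mask))
}

#' Relative-depth field across the epidermis
#'
#' Combines the two Euclidean distance maps into the per-pixel relative
#' depth
#' \deqn{d_{rel} = D_{top\,epidermis} / (D_{top\,epidermis} + D_{top\,dermis})}
#' where \eqn{D_{top\,epidermis}} is the distance map of the inner mask
#' (distance from the squamous/epidermis interface) and
#' \eqn{D_{top\,dermis}} the distance map of the outer mask (distance
#' from the epidermis/dermis interface). Outside/squamous pixels are
#' assigned 0, dermis pixels 1, and epidermis pixels fall strictly in
#' (0, 1): because distances are measured between pixel centres, both
#' maps are at least one pixel on the epidermis, so the denominator
#' never vanishes.
#'
#' @param masks a [TissueMasks-class] from [buildTissueMasks()].
#' @param mask the source [LabelMask-class] (supplies the class of each
#'   pixel for the 0/1 anchors).
#' @return A [RelativeDepthField-class] with distances in micrometres.
#' @export
relativeDepth <- function(masks, mask) {
    lab <- tissueLabels(mask)
    if (!any(lab == 2L)) stop("degenerate epidermis of zero pixels")
    ps <- mask@pixelSize
    dEpi <- distanceMap(masks@inner, ps)
    dDerm <- distanceMap(masks@outer, ps)
    epi <- lab == 2L
    dRel <- matrix(0, nrow(lab), ncol(lab))
    dRel[lab == 3L] <- 1
    dRel[epi] <- dEpi[epi] / (dEpi[epi] + dDerm[epi])
    new("RelativeDepthField", dTopEpi = dEpi, dTopDerm = dDerm,
        dRel = dRel, pixelSize = ps)
}
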