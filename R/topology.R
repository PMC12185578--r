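#' Validate the two-region partition requirement
#'
#' The depth metric is only defined when the epidermis band separates the
#' region into two non-touching parts: the dermis side and the
#' outside/squamous side. Working on the 8-connected components of the
#' non-epidermis pixels, the check passes iff (a) the component holding
#' the dermis seed contains no outside pixel and no squamous pixel on
#' the image border (either would mean an 8-connected path of
#' non-epidermis pixels leaks from the dermis through a gap in the band
#' to the outer side), (b) every dermis pixel lies in the seed
#' component (no dermis fragment stranded on the outer side), and
#' (c) dermis and epidermis are both non-empty. Mislabeled
#' outside/squamous islands fully enclosed by the dermis do not fail
#' the check: the flood fill of [buildTissueMasks()] absorbs them.
#' Failures report the first violating pixel coordinates.
#'
#' @param mask a [LabelMask-class] (typically already cropped to a
#'   square analysis region).
#' @param maxReport maximum number of violating pixels to list.
#' @return List with elements `pass` (logical), `reasons` (character)
#'   and `violations` (data.frame of row/col pixel coordinates, possibly
#'   empty).
#' @export
validatePartition <- function(mask, maxReport = 100) {
    lab <- tissueLabels(mask)
    reasons <- character(0)
    viol <- data.frame(row = integer(0), col = integer(0))
    if (!any(lab == 2L)) reasons <- c(reasons, "epidermis empty")
    if (!any(lab == 3L)) reasons <- c(reasons, "dermis empty")
    if (!length(reasons)) {
        comp <- .labelConnected(lab != 2L, connectivity = 8)
        seed <- dermisSeed(mask)
        sc <- comp[seed[1], seed[2]]
        H <- nrow(lab); W <- ncol(lab)
        onBorder <- matrix(FALSE, H, W)
        onBorder[c(1, H), ] <- TRUE; onBorder[, c(1, W)] <- TRUE
        leak <- comp == sc & (lab == 0L | (lab == 1L & onBorder))
        stranded <- lab == 3L & comp != sc
        if (any(leak))
            reasons <- c(reasons,
                "dermis side connects to the outside through a gap in the epidermis band")
        if (any(stranded))
            reasons <- c(reasons,
                "dermis pixels stranded outside the enclosed dermis side")
        if (any(leak) || any(stranded)) {
            w <- which(leak | stranded, arr.ind = TRUE)
            w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
            w <- utils::head(w, maxReport)
            viol <- data.frame(row = w[, 1], col = w[, 2])
        }
    }
    list(pass = length(reasons) == 0L, reasons = reasons, violations = viol)
}

#' Seed point for the dermis flood fill
#'
#' The centroid of the dermis pixels if that pixel is itself dermis;
#' otherwise (concave dermis) the dermis pixel nearest the centroid,
#' with ties resolved to the smallest row, then the smallest column.
#'
#' @param mask a [LabelMask-class] with a non-empty dermis.
#' @return Integer vector c(row, col), 1-based.
#' @export
dermisSeed <- function(mask) {
    w <- which(tissueLabels(mask) == 3L, arr.ind = TRUE)
    if (!nrow(w)) stop("dermis empty: no seed point")
    cen <- c(.roundHalfUp(mean(w[, 1])), .roundHalfUp(mean(w[, 2])))
    if (tissueLabels(mask)[cen[1], cen[2]] == 3L) return(as.integer(cen))
    d2 <- (w[, 1] - cen[1])^2 + (w[, 2] - cen[2])^2
    cand <- w[d2 == min(d2), , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    as.integer(cand[1, ])
}

#' Build the two binary masks behind the distance maps
#'
#' The inner mask is the epidermis binary image after a 4-connected
#' flood fill seeded at the dermis seed point, so it covers epidermis
#' plus everything the epidermis encloses on the dermis side - any
#' mislabeled island inside the dermis is absorbed by the fill, which is
#' what makes the subsequent distance maps robust to single stray
#' pixels. The outer mask is the complement of the inner mask with the
#' epidermis re-added (outside + squamous + epidermis). The two masks
#' overlap exactly on the epidermis and jointly cover the image.
#'
#' @param mask a [LabelMask-class] that passes [validatePartition()].
#' @param validate check the partition first (default TRUE).
#' @return A [TissueMasks-class].
#' @export
buildTissueMasks <- function(mask, validate = TRUE) {
    if (validate) {
        rep <- validatePartition(mask)
        if (!rep$pass)
            stop("partition requirement violated: ",
                 paste(rep$reasons, collapse = "; "))
    }
    lab <- tissueLabels(mask)
    epi <- matrix(as.integer(lab == 2L), nrow(lab), ncol(lab))
    seed <- dermisSeed(mask)
    if (epi[seed[1], seed[2]] == 1L)
        stop("dermis seed falls on the epidermis; partition degenerate")
    filled <- EBImage::floodFill(epi, matrix(seed, 1), col = 2L)
    inner <- matrix(as.vector(filled) > 0L, nrow(lab), ncol(lab))
    outer <- !inner | (lab == 2L)
    new("TissueMasks", inner = inner, outer = outer,
        pixelSize = mask@pixelSize)
}
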