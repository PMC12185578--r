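#' Default stain basis for DAB with a fast-red-type counterstain
#'
#' The DAB vector is the widely used published unit optical-density
#' vector for 3,3'-diaminobenzidine; the counterstain vector is a
#' fast-red-type nuclear red. Both are configurable because staining
#' chemistry varies between laboratories.
#'
#' @param dab,counterstain per-channel OD 3-vectors (normalised to unit
#'   length internally).
#' @param i0 white reference intensity.
#' @return A [StainBasis-class].
#' @examples
#' defaultStainBasis()
#' @export
defaultStainBasis <- function(dab = c(0.26814753, 0.57031375, 0.77642715),
                              counterstain = c(0.21393921, 0.85112669,
                                               0.47794022),
                              i0 = 255) {
    new("StainBasis",
        dab = dab / sqrt(sum(dab^2)),
        counterstain = counterstain / sqrt(sum(counterstain^2)),
        i0 = as.numeric(i0))
}

#' Convert an RGB image to optical densities
#'
#' Per-channel Beer-Lambert optical density,
#' OD_c = -log10(max(I_c, eps) / i0) with eps = 1 intensity unit guarding
#' saturated black pixels, clipped below at 0. The OD sum over the three
#' channels is the detection channel of the DAB area detector.
#'
#' @param img a [CalibratedImage-class].
#' @param i0 white reference intensity (default 255).
#' @return List with `od` (H x W x 3 array) and `odSum` (H x W matrix).
#' @examples
#' img <- CalibratedImage(array(26, dim = c(2, 2, 3)), 1)
#' rgbToOD(img)$odSum[1, 1]  # ~2.974
#' @export
rgbToOD <- function(img, i0 = 255) {
    if (i0 <= 0) stop("i0 must be positive")
    arr <- pixelArray(img)
    od <- -log10(pmax(arr, 1) / i0)
    od[od < 0] <- 0
    d <- dim(arr)
    list(od = od,
         odSum = matrix(od[, , 1] + od[, , 2] + od[, , 3], d[1], d[2]))
}

#' OD sum of an image
#'
#' Convenience wrapper returning only the optical-density-sum matrix.
#'
#' @inheritParams rgbToOD
#' @return H x W numeric matrix.
#' @export
odSum <- function(img, i0 = 255) rgbToOD(img, i0)$odSum

#' Unmix optical densities into stain concentration maps
#'
#' Least-squares projection of each pixel's OD 3-vector onto the DAB and
#' counterstain vectors; negative coefficients are clipped to zero. The
#' DAB map is intended for quality control; detection itself operates on
#' the OD sum.
#'
#' @param od H x W x 3 OD array (from [rgbToOD()]).
#' @param basis a [StainBasis-class].
#' @return List with matrices `dab` and `counterstain`.
#' @export
unmixStains <- function(od, basis) {
    M <- cbind(basis@dab, basis@counterstain)
    G <- crossprod(M)
    if (abs(det(G)) < 1e-10) stop("collinear stain basis")
    d <- dim(od)
    flat <- matrix(od, d[1] * d[2], 3)
    coef <- flat %*% M %*% solve(G)
    coef[coef < 0] <- 0
    list(dab = matrix(coef[, 1], d[1], d[2]),
         counterstain = matrix(coef[, 2], d[1], d[2]))
}

#' Reconstruct RGB intensities from stain concentrations
#'
#' Inverse of the Beer-Lambert model: I = i0 * 10^-(c_dab * v_dab +
#' c_cs * v_cs). Used by the phantom renderer and for unmixing
#' round-trip checks.
#'
#' @param dab,counterstain concentration matrices.
#' @param basis a [StainBasis-class].
#' @param pixelSize calibration of the returned image, um/px.
#' @return A [CalibratedImage-class].
#' @export
reconstructRGB <- function(dab, counterstain, basis, pixelSize) {
    H <- nrow(dab); W <- ncol(dab)
    od <- array(0, c(H, W, 3))
    for (c in 1:3)
        od[, , c] <- dab * basis@dab[c] + counterstain * basis@counterstain[c]
    arr <- basis@i0 * 10^(-od)
    arr[arr > 255] <- 255
    arr[arr < 0] <- 0
    CalibratedImage(round(arr), pixelSize)
}
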