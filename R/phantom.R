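#' Configuration for a synthetic skin phantom
#'
#' Describes a layered skin cross-section rendered top-to-bottom as
#' outside / squamous layer / epidermis / dermis over a fast-red-type
#' counterstain, with DAB-stained blobs planted at controlled relative
#' depths. Defaults emulate one 500 x 500 um analysis square at the
#' 0.6892 um working pixel size, with layer thicknesses typical of
#' abdominal skin cross-sections and a two-component ("double peak")
#' depth mixture centred mid-epidermis, the shape reported for
#' unexposed-skin Langerhans-cell distributions.
#'
#' @param widthUm,heightUm phantom extent, micrometres.
#' @param pixelSize micrometres per pixel.
#' @param outsideUm thickness of the empty band above the section, um.
#' @param squamousUm squamous-layer (stratum corneum) thickness, um.
#' @param epidermisUm epidermis thickness, um.
#' @param undulationAmpUm,undulationWavelengthUm sinusoidal undulation
#'   of the epidermis/dermis interface (amplitude 0 = flat bands, the
#'   geometry with a closed-form depth oracle).
#' @param nBlobs number of planted DAB blobs.
#' @param blobRadiusUm length-2 range of blob radii, um.
#' @param blobPeakOD peak DAB optical density of a blob.
#' @param depthDistribution one of "point", "uniform", "beta",
#'   "mixture"; planted relative depths are drawn from it.
#' @param depthParams parameters of the depth distribution: `value` for
#'   point; `alpha`, `beta` for beta; for the mixture, two beta
#'   components with weights (`w`, `alpha1`, `beta1`, `alpha2`,
#'   `beta2`).
#' @param counterstainOD named vector of counterstain OD per tissue
#'   class (squamous, epidermis, dermis).
#' @param grayOD named vector of neutral-gray OD per class (adds
#'   brightness contrast between layers).
#' @param noiseSD Gaussian intensity noise, 0-255 units.
#' @param seed integer seed; the generator is deterministic given it.
#' @return A validated configuration list (class `skinPhantomConfig`).
#' @export
phantomConfig <- function(widthUm = 500, heightUm = 500,
                          pixelSize = 0.6892,
                          outsideUm = 60, squamousUm = 40,
                          epidermisUm = 120,
                          undulationAmpUm = 0,
                          undulationWavelengthUm = 200,
                          nBlobs = 25,
                          blobRadiusUm = c(4, 7),
                          blobPeakOD = 1.0,
                          depthDistribution = c("mixture", "point",
                                                "uniform", "beta"),
                          depthParams = list(w = 0.5, alpha1 = 8,
                                             beta1 = 12, alpha2 = 12,
                                             beta2 = 8, value = 0.5,
                                             alpha = 2, beta = 2),
                          counterstainOD = c(squamous = 0.20,
                                             epidermis = 0.55,
                                             dermis = 0.25),
                          grayOD = c(squamous = 0.25, epidermis = 0.05,
                                     dermis = 0.02),
                          noiseSD = 5, seed = 1) {
    depthDistribution <- match.arg(depthDistribution)
    cfg <- list(widthUm = widthUm, heightUm = heightUm,
                pixelSize = pixelSize, outsideUm = outsideUm,
                squamousUm = squamousUm, epidermisUm = epidermisUm,
                undulationAmpUm = undulationAmpUm,
                undulationWavelengthUm = undulationWavelengthUm,
                nBlobs = nBlobs, blobRadiusUm = blobRadiusUm,
                blobPeakOD = blobPeakOD,
                depthDistribution = depthDistribution,
                depthParams = depthParams,
                counterstainOD = counterstainOD, grayOD = grayOD,
                noiseSD = noiseSD, seed = seed)
    if (any(c(squamousUm, epidermisUm) <= 0))
        stop("layer thicknesses must be positive")
    if (max(blobRadiusUm) >= epidermisUm / 2)
        stop("blob radius must be below half the epidermis thickness")
    if (noiseSD < 0) stop("noiseSD must be non-negative")
    class(cfg) <- "skinPhantomConfig"
    cfg
}

# Band geometry per column (1-based rows). Returns, for each of W
# columns: the first epidermis row yTop and the last epidermis row yBot.
.phantomGeometry <- function(cfg) {
    ps <- cfg$pixelSize
    W <- .umToPx(cfg$widthUm, ps)
    H <- .umToPx(cfg$heightUm, ps)
    cols <- seq_len(W)
    und <- if (cfg$undulationAmpUm > 0)
        (cfg$undulationAmpUm / ps) *
            sin(2 * pi * (cols - 1) * ps / cfg$undulationWavelengthUm)
    else rep(0, W)
    ySq <- .roundHalfUp(cfg$outsideUm / ps)          # last outside row
    yTop <- ySq + .roundHalfUp(cfg$squamousUm / ps) + 1L  # first epidermis row
    yBot <- .roundHalfUp(yTop - 1 + cfg$epidermisUm / ps + und)  # last epi row
    yBot <- pmin(pmax(yBot, yTop), H - 1L)
    list(H = H, W = W, lastOutside = ySq, firstEpi = rep(yTop, W),
         lastEpi = as.integer(yBot))
}

#' Closed-form relative depth for flat-band phantoms
#'
#' For a phantom with flat interfaces (undulation amplitude 0), the
#' relative depth of pixel (row, col) is known analytically from the
#' band geometry under the pixel-centre distance convention:
#' (row - yTop + 1) / (T + 1) inside the epidermis of thickness T px,
#' 0 above it and 1 below it. Used as an independent oracle for the
#' distance-map pathway.
#'
#' @param cfg a [phantomConfig()] with `undulationAmpUm = 0`.
#' @param row,col 1-based pixel indices (vectorised over `row`).
#' @return Relative depth values.
#' @export
closedFormDepth <- function(cfg, row, col = 1) {
    if (cfg$undulationAmpUm != 0)
        stop("closed-form depth is only defined for flat bands")
    g <- .phantomGeometry(cfg)
    yTop <- g$firstEpi[1]; yBot <- g$lastEpi[1]
    Tpx <- yBot - yTop + 1L
    d <- ifelse(row < yTop, 0,
         ifelse(row > yBot, 1, (row - yTop + 1) / (Tpx + 1)))
    d
}

#' Generate a synthetic skin phantom
#'
#' Renders the layered section in optical-density space (per-class
#' counterstain and neutral-gray OD, plus planted DAB disks along the
#' published DAB vector), exponentiates through Beer-Lambert
#' (I = i0 * 10^-OD), adds Gaussian intensity noise and clips to
#' \[0, 255\]. Blob centres are placed by sampling a target relative
#' depth and inverting the closed-form depth of the local column, so
#' the planted depth is exact up to pixel rounding. The same seed
#' always yields a byte-identical phantom; the caller's RNG state is
#' left untouched.
#'
#' @param cfg a [phantomConfig()].
#' @param basis a [StainBasis-class] (default [defaultStainBasis()]).
#' @return A [SkinPhantom-class] holding the rendered image, the
#'   ground-truth label mask and the planted-blob table.
#' @export
generatePhantom <- function(cfg, basis = defaultStainBasis()) {
    stopifnot(inherits(cfg, "skinPhantomConfig"))
    .withSeed(cfg$seed, {
        g <- .phantomGeometry(cfg)
        H <- g$H; W <- g$W; ps <- cfg$pixelSize
        rows <- matrix(seq_len(H), H, W)
        firstEpi <- matrix(g$firstEpi, H, W, byrow = TRUE)
        lastEpi <- matrix(g$lastEpi, H, W, byrow = TRUE)
        lab <- matrix(0L, H, W)
        lab[rows > g$lastOutside & rows < firstEpi] <- 1L
        lab[rows >= firstEpi & rows <= lastEpi] <- 2L
        lab[rows > lastEpi] <- 3L
        cs <- matrix(0, H, W); gray <- matrix(0, H, W)
        for (k in 1:3) {
            nm <- names(TISSUE_CLASSES)[k + 1]
            cs[lab == k] <- cfg$counterstainOD[[nm]]
            gray[lab == k] <- cfg$grayOD[[nm]]
        }
        # plant blobs: sample depth, invert the column's depth profile
        dab <- matrix(0, H, W)
        blobs <- data.frame(id = integer(0), center_row = integer(0),
                            center_col = integer(0), radius_um = numeric(0),
                            d_rel = numeric(0))
        blobPix <- list()
        if (cfg$nBlobs > 0) {
            placed <- 0L
            centers <- matrix(numeric(0), 0, 2)
            radii <- numeric(0)
            tries <- 0L
            while (placed < cfg$nBlobs) {
                tries <- tries + 1L
                if (tries > 400L * cfg$nBlobs)
                    stop("blob cannot fit at requested depth/density")
                r_um <- stats::runif(1, cfg$blobRadiusUm[1],
                                     cfg$blobRadiusUm[2])
                rpx <- r_um / ps
                col <- sample(seq(ceiling(rpx + 1), floor(W - rpx - 1)), 1)
                yTop <- g$firstEpi[col]; yBot <- g$lastEpi[col]
                Tpx <- yBot - yTop + 1L
                # a fresh depth draw per attempt keeps dense configurations
                # placeable without distorting the marginal distribution
                d <- .sampleDepths(1, cfg$depthDistribution, cfg$depthParams)
                row <- .roundHalfUp(yTop - 1 + d * (Tpx + 1))
                lo <- ceiling(yTop + rpx); hi <- floor(yBot - rpx)
                if (lo > hi) stop("blob cannot fit at requested depth: ",
                                  "epidermis too thin for radius ", r_um)
                row <- min(max(row, lo), hi)
                # separation keeps thresholded boundaries from coalescing
                # after the detection blur
                if (nrow(centers) &&
                    any(sqrt((centers[, 1] - row)^2 +
                             (centers[, 2] - col)^2) <
                        radii + rpx + 7))
                    next
                placed <- placed + 1L
                centers <- rbind(centers, c(row, col))
                radii <- c(radii, rpx)
                rr <- max(1, floor(row - rpx)):min(H, ceiling(row + rpx))
                ccl <- max(1, floor(col - rpx)):min(W, ceiling(col + rpx))
                sub <- as.matrix(expand.grid(rr, ccl))
                inside <- (sub[, 1] - row)^2 + (sub[, 2] - col)^2 <= rpx^2
                pix <- sub[inside, , drop = FALSE]
                colnames(pix) <- c("row", "col")
                dab[pix] <- cfg$blobPeakOD
                blobs <- rbind(blobs, data.frame(
                    id = placed, center_row = row, center_col = col,
                    radius_um = r_um,
                    d_rel = (row - yTop + 1) / (Tpx + 1)))
                blobPix[[placed]] <- pix
            }
        }
        od <- array(0, c(H, W, 3))
        gv <- c(1, 1, 1) / sqrt(3)
        for (c in 1:3)
            od[, , c] <- cs * basis@counterstain[c] + gray * gv[c] +
                dab * basis@dab[c]
        arr <- basis@i0 * 10^(-od)
        if (cfg$noiseSD > 0)
            arr <- arr + array(stats::rnorm(H * W * 3, 0, cfg$noiseSD),
                               c(H, W, 3))
        arr <- round(pmin(pmax(arr, 0), 255))
        new("SkinPhantom",
            image = CalibratedImage(arr, ps),
            truth = LabelMask(lab, ps),
            blobs = blobs, blobPixels = blobPix, config = unclass(cfg))
    })
}

.sampleDepths <- function(n, kind, p) {
    switch(kind,
        point = rep(p$value, n),
        uniform = stats::runif(n),
        beta = stats::rbeta(n, p$alpha, p$beta),
        mixture = {
            pick <- stats::runif(n) < p$w
            ifelse(pick, stats::rbeta(n, p$alpha1, p$beta1),
                   stats::rbeta(n, p$alpha2, p$beta2))
        },
        stop("unknown depth distribution: ", kind))
}

#' Sample training scribbles from a phantom's ground truth
#'
#' Draws a deterministic (seeded) random subset of pixels per tissue
#' class from the ground-truth mask, for training the pixel classifier
#' without manual annotation.
#'
#' @param phantom a [SkinPhantom-class].
#' @param fraction fraction of each class's pixels to sample.
#' @param seed integer seed.
#' @return data.frame with columns row, col, label (codes 1-3).
#' @export
phantomScribbles <- function(phantom, fraction = 0.05, seed = 1) {
    lab <- tissueLabels(phantomTruth(phantom))
    .withSeed(seed, {
        out <- lapply(1:3, function(k) {
            w <- which(lab == k, arr.ind = TRUE)
            n <- max(1L, round(nrow(w) * fraction))
            w <- w[sample(nrow(w), n), , drop = FALSE]
            data.frame(row = w[, 1], col = w[, 2], label = k)
        })
        do.call(rbind, out)
    })
}
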