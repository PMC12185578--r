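test_that("detection parameter defaults carry the optimized values", {
    p <- detectionParams()
    expect_equal(p@pixelSize, 0.6892)
    expect_equal(p@backgroundRadius, 20)
    expect_equal(p@medianRadius, 0)
    expect_equal(p@gaussianSigma, 2)
    expect_equal(p@minArea, 5)
    expect_equal(p@maxArea, 40000)
    expect_equal(p@threshold, 0.20)
    expect_equal(p@maxBackground, 2.0)
    expect_false(p@splitByShape)
    expect_true(p@smoothBoundaries)
    expect_error(detectionParams(minArea = 50, maxArea = 10), "exceed")
    expect_error(detectionParams(threshold = 0), "positive")
})

test_that("resampling reaches the target grid and is identity-safe", {
    img <- CalibratedImage(array(100, c(40, 40, 3)), 0.6892)
    expect_identical(resampleImage(img, 0.6892), img)
    up <- resampleImage(CalibratedImage(array(100, c(40, 40, 3)), 1.3784),
                        0.6892)
    expect_equal(pixelSize(up), 0.6892)
    expect_true(all(abs(dim(up) - 80) <= 1))
    # constant image stays constant under bilinear resampling
    expect_true(all(pixelArray(up) == 100))
})

test_that("background subtraction follows opening semantics", {
    # constant image: background = the constant, residual = 0
    os <- matrix(1.3, 50, 50)
    r <- subtractBackground(os, radius = 10, pixelSize = 1)
    expect_equal(r$background, os, tolerance = 1e-6)
    expect_true(all(r$corrected == 0))
    expect_false(any(r$exclusion))

    # a bright disk smaller than the element survives subtraction
    os2 <- matrix(0, 80, 80)
    w <- which((row(os2) - 40)^2 + (col(os2) - 40)^2 <= 25)
    os2[w] <- 1
    r2 <- subtractBackground(os2, radius = 20, pixelSize = 1)
    expect_equal(r2$corrected, os2, tolerance = 1e-6)

    # heavy background marks everything for exclusion
    r3 <- subtractBackground(matrix(2.5, 40, 40), radius = 10,
                             maxBackground = 2.0, pixelSize = 1)
    expect_true(all(r3$exclusion))

    # radius 0 disables the estimate
    r4 <- subtractBackground(os, radius = 0, pixelSize = 1)
    expect_true(all(r4$background == 0))
    expect_equal(r4$corrected, os)
    expect_error(subtractBackground(os, radius = -1), "non-negative")
})

detectFixture <- function() cachedFixture("detect", function() {
    cfg <- phantomConfig(nBlobs = 20, blobRadiusUm = c(5, 8),
                         depthDistribution = "mixture", seed = 55)
    ph <- generatePhantom(cfg)
    list(phantom = ph, blobs = detectDabAreas(phantomImage(ph)))
})

test_that("planted blobs are found and specks below minimum area are not", {
    fx <- detectFixture()
    ph <- fx$phantom; blobs <- fx$blobs
    m <- matchBlobs(ph, blobs)
    expect_gte(m$recall, 0.95)
    expect_lte(m$nFalsePositives, 1)
    tab <- blobTable(blobs)
    expect_true(all(tab$area_um2 >= 5 & tab$area_um2 <= 40000))
    # blank region -> no detections
    white <- CalibratedImage(array(255, c(300, 300, 3)), 0.6892)
    expect_equal(nBlobs(detectDabAreas(white)), 0)
})

test_that("one planted disk yields one blob of the blur-dilated area", {
    cfg <- phantomConfig(widthUm = 120, heightUm = 250, epidermisUm = 120,
                         nBlobs = 1, blobRadiusUm = c(10, 10),
                         depthDistribution = "point",
                         depthParams = list(value = 0.5), noiseSD = 0,
                         seed = 77)
    ph <- generatePhantom(cfg)
    blobs <- detectDabAreas(phantomImage(ph))
    expect_equal(nBlobs(blobs), 1)
    # thresholding the sigma-blurred edge of a disk of od-sum amplitude
    # A at level t moves the boundary outward by about
    # sigma * qnorm(1 - t/A); compare against that corrected expectation
    A <- 1.0 * sum(defaultStainBasis()@dab)
    dilation <- 2 * stats::qnorm(1 - 0.20 / A)
    expected <- pi * (10 + dilation)^2
    expect_lt(abs(blobTable(blobs)$area_um2 - expected) / expected, 0.15)
})

test_that("a 2 um^2 speck falls below the minimum-area filter", {
    # paint a sub-threshold-size DAB speck directly
    b <- defaultStainBasis()
    dab <- matrix(0, 200, 200)
    dab[100:101, 100:101] <- 1        # 4 px at 0.6892 um -> 1.9 um^2
    cs <- matrix(0.4, 200, 200)
    img <- reconstructRGB(dab, cs, b, 0.6892)
    p <- detectionParams(gaussianSigma = 0)   # keep the speck compact
    expect_equal(nBlobs(detectDabAreas(img, p)), 0)
})

test_that("touching areas cluster into one 8-connected component", {
    b <- defaultStainBasis()
    dab <- matrix(0, 150, 150)
    mk <- function(cy, cx, r) {
        w <- which((row(dab) - cy)^2 + (col(dab) - cx)^2 <= r^2)
        dab[w] <<- 1
    }
    mk(75, 60, 8); mk(75, 80, 8)   # 20 px apart: separate
    img <- reconstructRGB(dab, matrix(0.3, 150, 150), b, 1)
    p <- detectionParams(pixelSize = 1, gaussianSigma = 0)
    expect_equal(nBlobs(detectDabAreas(img, p)), 2)
    mk(75, 70, 8)                  # bridge them: single component
    img2 <- reconstructRGB(dab, matrix(0.3, 150, 150), b, 1)
    expect_equal(nBlobs(detectDabAreas(img2, p)), 1)
    # diagonal contact counts as connected (8-connectivity)
    dab2 <- matrix(0, 60, 60)
    dab2[20:29, 20:29] <- 1
    dab2[30:39, 30:39] <- 1
    img3 <- reconstructRGB(dab2, matrix(0.3, 60, 60), b, 1)
    p3 <- detectionParams(pixelSize = 1, gaussianSigma = 0,
                          smoothBoundaries = FALSE)
    expect_equal(nBlobs(detectDabAreas(img3, p3)), 1)
})

test_that("raising the threshold never increases total blob pixels", {
    fx <- detectFixture()
    img <- phantomImage(fx$phantom)
    counts <- vapply(c(0.1, 0.2, 0.4, 0.8), function(t) {
        b <- detectDabAreas(img, detectionParams(threshold = t))
        sum(blobTable(b)$n_pixels)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("detections are stable under 90-degree rotation", {
    fx <- detectFixture()
    img <- phantomImage(fx$phantom)
    arr <- pixelArray(img)
    rot <- array(0, c(dim(arr)[2], dim(arr)[1], 3))
    for (c in 1:3) rot[, , c] <- t(arr[, , c])[, dim(arr)[1]:1]
    bR <- detectDabAreas(CalibratedImage(rot, pixelSize(img)))
    b0 <- fx$blobs
    expect_equal(nBlobs(bR), nBlobs(b0))
    expect_equal(sort(blobTable(bR)$area_um2), sort(blobTable(b0)$area_um2),
                 tolerance = 0.02)
})

test_that("blob ordering and identities are deterministic", {
    fx <- detectFixture()
    again <- detectDabAreas(phantomImage(fx$phantom))
    expect_identical(blobTable(again), blobTable(fx$blobs))
    tab <- blobTable(fx$blobs)
    firstPix <- t(vapply(blobPixels(fx$blobs), function(p) {
        r <- min(p[, 1]); c(r, min(p[p[, 1] == r, 2]))
    }, numeric(2)))
    expect_false(is.unsorted(order(firstPix[, 1], firstPix[, 2])))
    expect_identical(tab$id, seq_len(nrow(tab)))
})

test_that("blob depths average the field over each blob's pixels", {
    fx <- detectFixture()
    ph <- fx$phantom
    truth <- phantomTruth(ph)
    field <- relativeDepth(buildTissueMasks(truth), truth)
    withD <- measureBlobDepths(fx$blobs, field)
    tab <- blobTable(withD)
    expect_true(all(c("mean_d_rel", "mean_dist_from_epi_um",
                      "mean_dist_from_derm_um") %in% names(tab)))
    i <- which.max(tab$n_pixels)
    pix <- blobPixels(withD)[[i]]
    expect_equal(tab$mean_d_rel[i], mean(depthRel(field)[pix]),
                 tolerance = 1e-12)
    expect_equal(tab$mean_dist_from_epi_um[i],
                 mean(depthFromEpi(field)[pix]), tolerance = 1e-12)
})
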