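test_that("phantom configuration rejects impossible geometry", {
    expect_error(phantomConfig(epidermisUm = 10, blobRadiusUm = c(5, 6)),
                 "radius")
    expect_error(phantomConfig(noiseSD = -1), "non-negative")
    expect_s3_class(phantomConfig(), "skinPhantomConfig")
})

test_that("generation is deterministic in the seed and leaves the RNG alone", {
    cfg <- phantomConfig(widthUm = 120, heightUm = 200, nBlobs = 5,
                         seed = 9)
    set.seed(12345)
    before <- stats::runif(1)
    set.seed(12345)
    ph1 <- generatePhantom(cfg)
    after <- stats::runif(1)
    expect_equal(before, after)   # caller RNG stream undisturbed

    ph2 <- generatePhantom(cfg)
    expect_identical(pixelArray(phantomImage(ph1)),
                     pixelArray(phantomImage(ph2)))
    expect_identical(phantomBlobs(ph1), phantomBlobs(ph2))

    ph3 <- generatePhantom(phantomConfig(widthUm = 120, heightUm = 200,
                                         nBlobs = 5, seed = 10))
    expect_false(identical(pixelArray(phantomImage(ph1)),
                           pixelArray(phantomImage(ph3))))
})

test_that("the rendered layers match the ground-truth mask", {
    cfg <- phantomConfig(widthUm = 150, heightUm = 220, nBlobs = 0,
                         noiseSD = 0, seed = 3)
    ph <- generatePhantom(cfg)
    lab <- tissueLabels(phantomTruth(ph))
    img <- phantomImage(ph)
    os <- odSum(img)
    # outside renders white, tissue renders above the whiteness threshold
    expect_lt(max(os[lab == 0L]), 0.05)
    expect_gt(min(os[lab != 0L]), 0.05)
    expect_true(validatePartition(phantomTruth(ph))$pass)
})

test_that("a blob-free phantom stays below the detection threshold", {
    cfg <- phantomConfig(widthUm = 200, heightUm = 250, nBlobs = 0,
                         seed = 19)
    ph <- generatePhantom(cfg)
    expect_equal(nBlobs(detectDabAreas(phantomImage(ph))), 0)
})

test_that("point-mass planting lands on the epidermis midline", {
    cfg <- phantomConfig(widthUm = 400, heightUm = 300, nBlobs = 12,
                         depthDistribution = "point",
                         depthParams = list(value = 0.5), seed = 31)
    ph <- generatePhantom(cfg)
    tr <- phantomBlobs(ph)
    expect_equal(nrow(tr), 12)
    g <- tissueLabels(phantomTruth(ph))
    yTop <- min(which(g[, 10] == 2L)); yBot <- max(which(g[, 10] == 2L))
    mid <- yTop - 1 + 0.5 * (yBot - yTop + 2)
    expect_true(all(abs(tr$center_row - mid) <= 1))
    expect_true(all(abs(tr$d_rel - 0.5) < 0.01))
    # planted pixels lie inside the epidermis
    for (p in ph@blobPixels)
        expect_true(all(g[p] == 2L))
})

test_that("the closed form matches the distance pathway on flat bands", {
    cfg <- phantomConfig(widthUm = 80, heightUm = 260, nBlobs = 0,
                         seed = 1)
    ph <- generatePhantom(cfg)
    truth <- phantomTruth(ph)
    field <- relativeDepth(buildTissueMasks(truth), truth)
    lab <- tissueLabels(truth)
    epiRows <- which(lab[, 5] == 2L)
    Tpx <- length(epiRows)
    for (y in c(min(epiRows), min(epiRows) + 3, max(epiRows)))
        expect_equal(depthRel(field)[y, 5], closedFormDepth(cfg, y),
                     tolerance = 1e-12)
    expect_equal(closedFormDepth(cfg, min(epiRows)), 1 / (Tpx + 1))
    expect_equal(closedFormDepth(cfg, max(epiRows) + 10), 1)
    expect_equal(closedFormDepth(cfg, 1), 0)
    und <- phantomConfig(undulationAmpUm = 10)
    expect_error(closedFormDepth(und, 5), "flat")
})

test_that("planted depths are recovered end-to-end within 0.05", {
    cfg <- phantomConfig(nBlobs = 25, blobRadiusUm = c(5, 8), seed = 47)
    ph <- generatePhantom(cfg)
    truth <- phantomTruth(ph)
    field <- relativeDepth(buildTissueMasks(truth), truth)
    blobs <- measureBlobDepths(detectDabAreas(phantomImage(ph)), field)
    m <- matchBlobs(ph, blobs)
    expect_gte(m$recall, 0.95)
    hit <- !is.na(m$hitOf)
    err <- abs(blobTable(blobs)$mean_d_rel[m$hitOf[hit]] -
               phantomBlobs(ph)$d_rel[hit])
    expect_lt(mean(err), 0.05)
})

test_that("a planted two-component mixture re-emerges as bimodal", {
    cfg <- phantomConfig(nBlobs = 40, blobRadiusUm = c(4, 6),
                         depthDistribution = "mixture",
                         depthParams = list(w = 0.5, alpha1 = 24,
                                            beta1 = 40, alpha2 = 40,
                                            beta2 = 24, value = 0.5,
                                            alpha = 2, beta = 2),
                         seed = 59)
    ph <- generatePhantom(cfg)
    truth <- phantomTruth(ph)
    field <- relativeDepth(buildTissueMasks(truth), truth)
    blobs <- measureBlobDepths(detectDabAreas(phantomImage(ph)), field)
    d <- poolDistribution(blobs, condition = "mixture")
    dens <- depthHistogram(d, nBins = 50)$density
    y <- dens$y
    peaks <- which(diff(sign(diff(y))) == -2) + 1
    peaks <- peaks[y[peaks] > 0.25 * max(y)]
    expect_gte(length(peaks), 2)
})

test_that("undulating interfaces stay valid and depth-consistent", {
    cfg <- phantomConfig(widthUm = 300, heightUm = 300, nBlobs = 8,
                         undulationAmpUm = 12,
                         undulationWavelengthUm = 150, seed = 71)
    ph <- generatePhantom(cfg)
    truth <- phantomTruth(ph)
    expect_true(validatePartition(truth)$pass)
    field <- relativeDepth(buildTissueMasks(truth), truth)
    dr <- depthRel(field)
    expect_true(all(dr >= 0 & dr <= 1))
    lab <- tissueLabels(truth)
    expect_true(all(dr[lab == 3L] == 1))
})
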