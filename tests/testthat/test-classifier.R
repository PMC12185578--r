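test_that("the feature stack has the documented shape and ordering", {
    img <- CalibratedImage(array(128, c(10, 12, 3)), 1)
    f1 <- extractFeatures(img, scales = 1)
    expect_equal(ncol(f1), 7)
    expect_equal(nrow(f1), 120)
    f2 <- extractFeatures(img, scales = c(1, 4))
    expect_equal(ncol(f2), 14)
    expect_match(colnames(f2)[1], "R_s1")
    expect_match(colnames(f2)[14], "ODsum_s4")
    # constant image -> constant features
    expect_true(all(apply(f2, 2, function(x) diff(range(x)) == 0)))
    expect_error(extractFeatures(img, scales = numeric(0)), "scale")
    expect_error(extractFeatures(img, scales = -1), "non-positive")
})

test_that("larger scales flatten gradients at a step edge", {
    arr <- array(0, c(30, 60, 3))
    arr[, 31:60, ] <- 255
    img <- CalibratedImage(arr, 1)
    f <- extractFeatures(img, scales = c(1, 6))
    small <- matrix(f[, "R_s1"], 30, 60)
    large <- matrix(f[, "R_s6"], 30, 60)
    gSmall <- max(abs(diff(t(small[15, , drop = FALSE])[, 1])))
    gLarge <- max(abs(diff(t(large[15, , drop = FALSE])[, 1])))
    expect_lt(gLarge, gSmall)
})

test_that("training demands every tissue class and fixes the seed", {
    fx <- classifierFixture()
    onlyEpi <- fx$scribbles[fx$scribbles$label == 2L, ]
    expect_error(
        trainPixelClassifier(phantomImage(fx$phantom), onlyEpi),
        "missing training class.*squamous.*dermis")
    m2 <- trainPixelClassifier(phantomImage(fx$phantom), fx$scribbles,
                               seed = 103)
    p1 <- classifyPixels(fx$model, phantomImage(fx$phantom))
    p2 <- classifyPixels(m2, phantomImage(fx$phantom))
    expect_identical(tissueLabels(p1), tissueLabels(p2))
})

test_that("the classifier recovers the phantom layers at >= 95% accuracy", {
    fx <- classifierFixture()
    pred <- classifyPixels(fx$model, phantomImage(fx$phantom))
    truth <- tissueLabels(phantomTruth(fx$phantom))
    expect_identical(dim(tissueLabels(pred)), dim(truth))
    expect_true(all(tissueLabels(pred) %in% 0:3))
    expect_gte(mean(tissueLabels(pred) == truth), 0.95)
    expect_gte(fx$model@trainAccuracy, 0.95)
})

test_that("noise-free phantoms classify perfectly away from boundaries", {
    cfg <- phantomConfig(widthUm = 150, heightUm = 200, nBlobs = 0,
                         noiseSD = 0, seed = 41)
    ph <- generatePhantom(cfg)
    scr <- phantomScribbles(ph, fraction = 0.05, seed = 42)
    model <- trainPixelClassifier(phantomImage(ph), scr, seed = 43)
    pred <- tissueLabels(classifyPixels(model, phantomImage(ph)))
    truth <- tissueLabels(phantomTruth(ph))
    margin <- ceiling(2 * max(model@scales) / pixelSize(phantomImage(ph)))
    interior <- matrix(TRUE, nrow(truth), ncol(truth))
    for (k in 0:3) {
        inK <- truth == k
        if (!any(inK) || all(inK)) next
        dK <- distanceMap(inK)
        interior[inK & dK <= margin] <- FALSE
    }
    expect_equal(mean(pred[interior] == truth[interior]), 1)
})

test_that("pure white images map entirely to the outside class", {
    fx <- classifierFixture()
    white <- CalibratedImage(array(255, c(20, 20, 3)), 0.6892)
    pred <- classifyPixels(fx$model, white)
    expect_true(all(tissueLabels(pred) == 0L))
})

test_that("smoothing radius zero returns the raw argmax labels", {
    fx <- classifierFixture()
    img <- phantomImage(fx$phantom)
    raw <- classifyPixels(fx$model, img, smoothRadius = 0)
    smoothed <- classifyPixels(fx$model, img, smoothRadius = 2)
    expect_identical(dim(tissueLabels(raw)), dim(img))
    # the whiteness rule applies in both
    os <- odSum(img)
    expect_true(all(tissueLabels(raw)[os < 0.05] == 0L))
    expect_true(all(tissueLabels(smoothed)[os < 0.05] == 0L))
})

test_that("a feature-recipe mismatch is detected at prediction time", {
    fx <- classifierFixture()
    other <- trainPixelClassifier(phantomImage(fx$phantom), fx$scribbles,
                                  scales = c(2), seed = 1, nTrees = 5)
    feats <- extractFeatures(phantomImage(fx$phantom), c(1, 4))
    expect_identical(colnames(feats), fx$model@featureNames)
    other@featureNames <- fx$model@featureNames  # forge the recipe record
    expect_error(classifyPixels(other, phantomImage(fx$phantom)),
                 "feature recipe mismatch")
})

test_that("refinement polygons overwrite exactly their pixels, in order", {
    m <- flatBandMask(outside = 5, epidermis = 20, dermis = 15, width = 30)
    expect_identical(tissueLabels(applyRefinement(m, list())),
                     tissueLabels(m))
    # relabel a dermis strip (rows 31..35, cols 11..20; um coords are
    # 0-based pixel centres) to epidermis
    edit <- list(list(label = 2L,
                      x = c(9.5, 19.5, 19.5, 9.5),
                      y = c(29.5, 29.5, 34.5, 34.5)))
    ref <- applyRefinement(m, edit)
    changed <- tissueLabels(ref) != tissueLabels(m)
    w <- which(changed, arr.ind = TRUE)
    expect_equal(range(w[, 1]), c(31, 35))
    expect_equal(range(w[, 2]), c(11, 20))
    expect_true(all(tissueLabels(ref)[changed] == 2L))
    # overlapping edits: the last one wins
    edits <- list(list(label = 1L, x = c(-0.5, 29.5, 29.5, -0.5),
                       y = c(29.5, 29.5, 34.5, 34.5)),
                  list(label = 2L, x = c(9.5, 19.5, 19.5, 9.5),
                       y = c(29.5, 29.5, 34.5, 34.5)))
    ref2 <- applyRefinement(m, edits)
    expect_equal(tissueLabels(ref2)[33, 15], 2L)
    expect_equal(tissueLabels(ref2)[33, 5], 1L)
})

test_that("classifiers survive a save/load round trip", {
    fx <- classifierFixture()
    f <- tempfile(fileext = ".rds")
    saveClassifier(fx$model, f)
    back <- loadClassifier(f)
    p1 <- classifyPixels(fx$model, phantomImage(fx$phantom))
    p2 <- classifyPixels(back, phantomImage(fx$phantom))
    expect_identical(tissueLabels(p1), tissueLabels(p2))
})
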