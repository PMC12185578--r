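makeBlobSet <- function(depthList, pixelSize = 1) {
    n <- length(depthList)
    pixels <- lapply(depthList, function(d)
        cbind(row = seq_along(d), col = rep(1L, length(d))))
    depths <- lapply(depthList, function(d)
        data.frame(d_rel = d, dist_epi_um = d * 100,
                   dist_derm_um = (1 - d) * 100))
    zero <- rep(0, n)
    tab <- data.frame(id = seq_len(n),
        n_pixels = lengths(depthList),
        area_um2 = lengths(depthList) * pixelSize^2,
        centroid_x_um = zero, centroid_y_um = zero, mean_od_sum = zero + 1,
        mean_d_rel = vapply(depthList, mean, numeric(1)),
        mean_dist_from_epi_um = vapply(depthList, function(d)
            mean(d * 100), numeric(1)),
        mean_dist_from_derm_um = vapply(depthList, function(d)
            mean((1 - d) * 100), numeric(1)))
    new("DabBlobSet", blobs = tab, pixels = pixels,
        polygons = replicate(n, matrix(0, 4, 2), simplify = FALSE),
        pixelDepths = depths, pixelSize = pixelSize)
}

test_that("pooling keeps per-pixel and per-blob views consistent", {
    bs <- makeBlobSet(list(c(0.2, 0.2, 0.4, 0.4)))
    d <- poolDistribution(bs, condition = "x")
    expect_equal(sort(perPixelDepths(d)), c(0.2, 0.2, 0.4, 0.4))
    expect_equal(perBlobDepths(d), 0.3)

    # a 100-px blob dominates per-pixel pooling but not per-blob pooling
    big <- makeBlobSet(list(rep(0.8, 100), rep(0.2, 4)))
    d2 <- poolDistribution(big, condition = "y")
    expect_equal(mean(perPixelDepths(d2)), (100 * 0.8 + 4 * 0.2) / 104)
    expect_equal(mean(perBlobDepths(d2)), 0.5)

    # equal-sized blobs: both poolings agree on the mean
    eq <- makeBlobSet(list(rep(0.1, 5), rep(0.5, 5), rep(0.9, 5)))
    d3 <- poolDistribution(eq)
    expect_equal(mean(perPixelDepths(d3)), mean(perBlobDepths(d3)))

    # empty input is a valid empty distribution
    empty <- poolDistribution(makeBlobSet(list()), condition = "none")
    expect_length(perPixelDepths(empty), 0)

    # replicate provenance follows the input sections
    two <- poolDistribution(list(a = bs, b = big), condition = "z")
    expect_setequal(unique(two@pixelReplicate), c("a", "b"))
    expect_equal(sum(two@pixelReplicate == "b"), 104)
})

test_that("histograms are normalized and match binomial expectations", {
    h <- depthHistogram(rep(0.5, 40), nBins = 50)
    expect_equal(sum(h$mass), 1)
    expect_equal(sum(h$mass > 0), 1)

    set.seed(21)
    u <- stats::runif(1e5)
    h2 <- depthHistogram(u, nBins = 50)
    expect_equal(sum(h2$mass), 1, tolerance = 1e-12)
    # family-wise bound across the 50 bins (per-bin 3 SE would be
    # exceeded a few times in 50 by chance alone)
    se <- sqrt(0.02 * 0.98 / 1e5)
    z <- stats::qnorm(1 - 0.005 / 50)
    expect_true(all(abs(h2$mass - 0.02) <= z * se))
    # violin density has unit area
    auc <- sum((h2$density$y[-1] + h2$density$y[-256]) / 2 *
               diff(h2$density$x))
    expect_equal(auc, 1, tolerance = 1e-6)

    expect_error(depthHistogram(numeric(0)), "no DAB-positive pixels")
    expect_error(depthHistogram(u, nBins = 0), "nBins")
})

test_that("histogram masses sum to one for arbitrary random inputs", {
    set.seed(31)
    for (k in 1:20) {
        x <- switch(sample(3, 1),
            stats::runif(sample(1:500, 1)),
            stats::rbeta(sample(1:500, 1), 2, 5),
            rep(stats::runif(1), sample(1:50, 1)))
        h <- depthHistogram(x, nBins = sample(1:80, 1))
        expect_equal(sum(h$mass), 1, tolerance = 1e-12)
    }
})

test_that("the rank-sum test matches exact enumeration on small samples", {
    r <- wilcoxonCompare(c(1, 2, 3), c(4, 5, 6), alternative = "greater")
    expect_equal(r$p_value, 1 / 20)
    expect_equal(r$p_value, enumerateRankSumP(c(1, 2, 3), c(4, 5, 6)))
    expect_true(r$exact)

    set.seed(8)
    for (k in 1:10) {
        a <- round(stats::runif(4), 3); b <- round(stats::runif(5), 3)
        r2 <- wilcoxonCompare(a, b, alternative = "greater")
        expect_equal(r2$p_value, enumerateRankSumP(a, b), tolerance = 1e-12)
    }
})

test_that("ties give the symmetric statistic and large shifts vanish p", {
    r <- wilcoxonCompare(c(1, 2, 3), c(1, 2, 3))
    expect_equal(r$statistic, 4.5)   # U = n*m/2 under full symmetry
    expect_false(r$significant)

    set.seed(13)
    a <- stats::runif(1e4, 0, 0.7)
    b <- a + 0.3
    r2 <- wilcoxonCompare(a, b, alternative = "greater")
    expect_lt(r2$p_value, 1e-6)
    expect_error(wilcoxonCompare(numeric(0), 1), "empty")
})

test_that("depth-band comparisons localise a planted shift", {
    set.seed(17)
    a <- stats::runif(600, 0.05, 0.30)            # band 1
    b <- c(stats::runif(300, 0.05, 0.30), stats::runif(300, 0.70, 0.95))
    ter <- tertileCompare(a, b)
    expect_length(ter, 3)
    expect_identical(ter$band2$note, "insufficient data")
    expect_true(is.na(ter$band2$p_value))
    expect_true(ter$band3$n[1] == 0 || !is.na(ter$band3$p_value))
    # identical inputs: all testable bands are non-significant
    terEq <- tertileCompare(a, a)
    expect_false(terEq$band1$significant)
})

test_that("KS normality behaves at its anchors", {
    z <- stats::qnorm(stats::ppoints(1000))
    expect_gt(ksNormality(z), 0.5)
    set.seed(23)
    expect_lt(ksNormality(stats::runif(1000)), 0.05)
    # a constant sample is declared non-normal (D = 0.5 under the
    # sd floor gives p ~ 0.014 at n = 10)
    expect_lt(ksNormality(rep(1, 10)), 0.05)
    expect_error(ksNormality(c(1, 2)), "at least 5")
})

test_that("the rank-sum test holds its nominal size under the null", {
    set.seed(29)
    reject <- vapply(1:500, function(i) {
        a <- stats::runif(20); b <- stats::runif(20)
        wilcoxonCompare(a, b)$p_value < 0.05
    }, logical(1))
    expect_lt(abs(mean(reject) - 0.05), 0.025)
})

test_that("violin plots assemble without error", {
    d1 <- new("DepthDistribution", condition = "Ctrl",
              perPixelRel = stats::rbeta(200, 8, 8),
              perPixelAbsEpi = numeric(200), perPixelAbsDerm = numeric(200),
              perBlobRel = numeric(0),
              pixelReplicate = rep("r1", 200), blobReplicate = character(0))
    p <- plotDepthViolin(list(d1))
    expect_s3_class(p, "ggplot")
})
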