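# Independent oracles and shared fixtures for the test suite.

# Brute-force exact Euclidean distance map: for every TRUE pixel, the
# minimum centre-to-centre distance to a FALSE pixel, by exhaustive
# search (vectorised over background pixels, chunked over foreground).
bruteForceEDM <- function(mask) {
    out <- matrix(0, nrow(mask), ncol(mask))
    fg <- which(mask, arr.ind = TRUE)
    bg <- which(!mask, arr.ind = TRUE)
    if (!nrow(fg)) return(out)
    step <- max(1L, floor(2e6 / nrow(bg)))
    for (start in seq(1, nrow(fg), by = step)) {
        idx <- start:min(start + step - 1, nrow(fg))
        d2 <- outer(fg[idx, 1], bg[, 1], "-")^2 +
              outer(fg[idx, 2], bg[, 2], "-")^2
        out[fg[idx, , drop = FALSE]] <- sqrt(apply(d2, 1, min))
    }
    out
}

# Exact one-sided Mann-Whitney p-value P(rank sum of b >= observed)
# under the null, by enumerating every assignment of the pooled ranks.
enumerateRankSumP <- function(a, b) {
    pooled <- c(a, b)
    r <- rank(pooled)
    m <- length(b)
    obs <- sum(r[(length(a) + 1):(length(a) + m)])
    combs <- utils::combn(length(pooled), m)
    stats <- apply(combs, 2, function(j) sum(r[j]))
    mean(stats >= obs)
}

# A flat-band tissue label mask: outside rows 1..o, squamous o+1..o+s,
# epidermis next T rows, dermis below.
flatBandMask <- function(outside = 10, squamous = 0, epidermis = 100,
                         dermis = 90, width = 60, pixelSize = 1) {
    H <- outside + squamous + epidermis + dermis
    lab <- matrix(0L, H, width)
    if (squamous > 0) lab[(outside + 1):(outside + squamous), ] <- 1L
    top <- outside + squamous
    lab[(top + 1):(top + epidermis), ] <- 2L
    lab[(top + epidermis + 1):H, ] <- 3L
    LabelMask(lab, pixelSize)
}

# Pixel-overlap matching of detected blobs against planted truth.
matchBlobs <- function(phantom, detected) {
    H <- dim(phantomImage(phantom))[1]
    tIdx <- lapply(phantom@blobPixels, function(p) (p[, 2] - 1) * H + p[, 1])
    dIdx <- lapply(blobPixels(detected), function(p) (p[, 2] - 1) * H + p[, 1])
    hitOf <- vapply(tIdx, function(t) {
        m <- which(vapply(dIdx, function(d) any(d %in% t), logical(1)))
        if (length(m)) m[1] else NA_integer_
    }, integer(1))
    falsePos <- if (length(dIdx))
        vapply(seq_along(dIdx), function(i) !i %in% hitOf, logical(1))
    else logical(0)
    list(hitOf = hitOf, recall = mean(!is.na(hitOf)),
         nFalsePositives = sum(falsePos))
}

# Session-level cache for expensive fixtures (built once per test run).
.fixtures <- new.env(parent = emptyenv())

cachedFixture <- function(name, builder) {
    if (!exists(name, envir = .fixtures))
        assign(name, builder(), envir = .fixtures)
    get(name, envir = .fixtures)
}

# A mid-sized phantom with a trained classifier, reused across files.
classifierFixture <- function() cachedFixture("classifier", function() {
    cfg <- phantomConfig(widthUm = 220, heightUm = 260, nBlobs = 6,
                         noiseSD = 8, seed = 101)
    ph <- generatePhantom(cfg)
    scr <- phantomScribbles(ph, fraction = 0.05, seed = 102)
    model <- trainPixelClassifier(phantomImage(ph), scr, seed = 103)
    list(phantom = ph, scribbles = scr, model = model)
})
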