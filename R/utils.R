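# Internal geometry and raster helpers.
# Conventions: matrices are [row, col]; pixel (r, c) (1-based) has its
# centre at micrometre coordinates x = (c-1)*pixelSize, y = (r-1)*pixelSize.

.roundHalfUp <- function(x) floor(x + 0.5)

.umToPx <- function(um, pixelSize) as.integer(.roundHalfUp(um / pixelSize))

# Connected-component labelling. EBImage::bwlabel is 4-connected; for
# 8-connectivity, labels touching across a diagonal are merged by
# union-find and renumbered consecutively.
.labelConnected <- function(mask, connectivity = 8) {
    stopifnot(connectivity %in% c(4, 8))
    lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
    lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
    nlab <- max(lab)
    if (connectivity == 8 && nlab > 1) {
        H <- nrow(lab); W <- ncol(lab)
        pairs <- rbind(
            cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),
            cbind(as.vector(lab[-1, -W]), as.vector(lab[-H, -1])))
        pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                       pairs[, 1] != pairs[, 2], , drop = FALSE]
        if (nrow(pairs)) {
            parent <- seq_len(nlab)
            find <- function(i) {
                while (parent[i] != i) {
                    parent[i] <<- parent[parent[i]]
                    i <- parent[i]
                }
                i
            }
            for (k in seq_len(nrow(pairs))) {
                a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
                if (a != b) parent[max(a, b)] <- min(a, b)
            }
            root <- vapply(seq_len(nlab), find, integer(1))
            newid <- match(root, sort(unique(root)))
            pos <- lab > 0L
            lab[pos] <- newid[lab[pos]]
        }
    }
    lab
}

# Gaussian blur with the kernel capped so it always fits the image;
# degenerate (sub-3-px) images pass through unchanged.
.gblur <- function(x, sigma) {
    r <- 2L * as.integer(ceiling(3 * sigma)) + 1L
    cap <- min(dim(x))
    if (cap %% 2L == 0L) cap <- cap - 1L
    r <- min(r, cap)
    if (r < 3L) return(x)
    as.matrix(EBImage::gblur(x, sigma = sigma, radius = r,
                             boundary = "replicate"))
}

# Even-odd (crossing-number) point-in-polygon test, vectorised over points.
# Points on an edge resolve by the half-open crossing rule; adequate for
# pixel-centre rasterisation.
.pointInPolygon <- function(px, py, xv, yv) {
    n <- length(xv)
    inside <- logical(length(px))
    j <- n
    for (i in seq_len(n)) {
        xi <- xv[i]; yi <- yv[i]; xj <- xv[j]; yj <- yv[j]
        crosses <- ((yi > py) != (yj > py)) &
            (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
        inside <- xor(inside, crosses)
        j <- i
    }
    inside
}

# Proper-intersection test between non-adjacent polygon edges.
.polygonSelfIntersects <- function(xv, yv) {
    n <- length(xv)
    if (n < 4) return(FALSE)
    seg <- cbind(xv, yv, c(xv[-1], xv[1]), c(yv[-1], yv[1]))
    orient <- function(ax, ay, bx, by, cx, cy)
        sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
    for (i in seq_len(n - 2)) {
        jj <- seq(i + 2, n)
        jj <- jj[!(i == 1 & jj == n)]  # skip adjacent (incl. wrap-around)
        for (j in jj) {
            o1 <- orient(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
            o2 <- orient(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
            o3 <- orient(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
            o4 <- orient(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
            if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
                return(TRUE)
        }
    }
    FALSE
}

# Rasterise one polygon (micrometre coordinates) onto an H x W grid:
# a pixel is inside iff its centre is inside the polygon.
.rasterizePolygon <- function(xUm, yUm, pixelSize, H, W) {
    out <- matrix(FALSE, H, W)
    xv <- xUm / pixelSize      # 0-based pixel coordinates of vertices
    yv <- yUm / pixelSize
    c0 <- max(1L, floor(min(xv)) + 1L)
    c1 <- min(W, ceiling(max(xv)) + 1L)
    r0 <- max(1L, floor(min(yv)) + 1L)
    r1 <- min(H, ceiling(max(yv)) + 1L)
    if (c0 > c1 || r0 > r1) return(out)
    cc <- rep(c0:c1, each = r1 - r0 + 1L)
    rr <- rep(r0:r1, times = c1 - c0 + 1L)
    ins <- .pointInPolygon(cc - 1, rr - 1, xv, yv)
    out[cbind(rr[ins], cc[ins])] <- TRUE
    out
}

# Douglas-Peucker polyline simplification (open polyline), tolerance in
# the units of pts.
.douglasPeucker <- function(pts, tol) {
    n <- nrow(pts)
    if (n <= 2) return(pts)
    keep <- logical(n)
    keep[c(1, n)] <- TRUE
    stack <- list(c(1, n))
    while (length(stack)) {
        rng <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        i <- rng[1]; j <- rng[2]
        if (j - i < 2) next
        a <- pts[i, ]; b <- pts[j, ]
        ab <- b - a
        len2 <- sum(ab^2)
        idx <- (i + 1):(j - 1)
        if (len2 == 0) {
            d <- sqrt((pts[idx, 1] - a[1])^2 + (pts[idx, 2] - a[2])^2)
        } else {
            d <- abs(ab[1] * (a[2] - pts[idx, 2]) -
                     (a[1] - pts[idx, 1]) * ab[2]) / sqrt(len2)
        }
        k <- idx[which.max(d)]
        if (max(d) > tol) {
            keep[k] <- TRUE
            stack[[length(stack) + 1]] <- c(i, k)
            stack[[length(stack) + 1]] <- c(k, j)
        }
    }
    pts[keep, , drop = FALSE]
}

# md5 of a character scalar (via a temporary file; tools::md5sum has no
# string interface).
.md5string <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(x, f)
    unname(tools::md5sum(f))
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}
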