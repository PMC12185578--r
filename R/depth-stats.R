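#' Pool blob depths into a condition-level depth distribution
#'
#' Two parallel readings of the same detections are kept: the per-pixel
#' pooling (one value per DAB-positive pixel, so large areas weigh in
#' proportion to their size) and the per-blob pooling (one mean depth
#' per detected area, so every area counts once). The per-pixel reading
#' is what the histograms and violin plots show; the per-blob reading
#' removes the area bias.
#'
#' @param blobSets list of [DabBlobSet-class] objects with depths
#'   attached ([measureBlobDepths()]), one per replicate section.
#' @param condition condition identifier (e.g. "H2O", "MI_30ppm").
#' @param replicates character vector naming each replicate (defaults to
#'   `names(blobSets)` or "rep1", "rep2", ...).
#' @return A [DepthDistribution-class]. An empty blob list yields an
#'   empty (valid) distribution.
#' @export
poolDistribution <- function(blobSets, condition = "condition",
                             replicates = NULL) {
    if (is(blobSets, "DabBlobSet")) blobSets <- list(blobSets)
    if (is.null(replicates))
        replicates <- if (!is.null(names(blobSets)) &&
                          all(nzchar(names(blobSets)))) names(blobSets)
                      else paste0("rep", seq_along(blobSets))
    px <- pxEpi <- pxDerm <- numeric(0)
    pxRep <- blobRep <- character(0)
    blobRel <- numeric(0)
    for (i in seq_along(blobSets)) {
        bs <- blobSets[[i]]
        if (!length(bs@pixelDepths) && nBlobs(bs) > 0)
            stop("blob set ", i, " has no depths attached; run ",
                 "measureBlobDepths() first")
        for (d in bs@pixelDepths) {
            px <- c(px, d$d_rel)
            pxEpi <- c(pxEpi, d$dist_epi_um)
            pxDerm <- c(pxDerm, d$dist_derm_um)
            pxRep <- c(pxRep, rep(replicates[i], nrow(d)))
        }
        if (nBlobs(bs)) {
            blobRel <- c(blobRel, blobTable(bs)$mean_d_rel)
            blobRep <- c(blobRep, rep(replicates[i], nBlobs(bs)))
        }
    }
    new("DepthDistribution", condition = condition, perPixelRel = px,
        perPixelAbsEpi = pxEpi, perPixelAbsDerm = pxDerm,
        perBlobRel = blobRel, pixelReplicate = pxRep,
        blobReplicate = blobRep)
}

#' Normalized depth histogram and violin density
#'
#' Bins the per-pixel relative depths over \[0, 1\]; bin masses sum to
#' 1. The kernel-density curve for violin display is renormalized to
#' unit area over \[0, 1\]. Axis convention for plotting: 0 (stratum
#' corneum) at the top, 1 (basal lamina) at the bottom.
#'
#' @param dist a [DepthDistribution-class], or a numeric vector of
#'   depths in \[0, 1\].
#' @param nBins number of equal-width bins over \[0, 1\] (default 50).
#' @return List with `breaks`, `mid`, `mass` (summing to 1) and
#'   `density` (data.frame x, y of the unit-area violin curve).
#' @export
depthHistogram <- function(dist, nBins = 50) {
    if (nBins < 1) stop("nBins must be >= 1")
    x <- if (is(dist, "DepthDistribution")) perPixelDepths(dist) else dist
    if (!length(x)) stop("no DAB-positive pixels")
    breaks <- seq(0, 1, length.out = nBins + 1)
    cnt <- tabulate(pmin(nBins, pmax(1L, findInterval(
        x, breaks, rightmost.closed = TRUE))), nbins = nBins)
    mass <- cnt / sum(cnt)
    dens <- if (length(x) >= 2 && stats::sd(x) > 0) {
        d <- stats::density(x, from = 0, to = 1, n = 256)
        auc <- sum((d$y[-1] + d$y[-length(d$y)]) / 2 * diff(d$x))
        data.frame(x = d$x, y = d$y / auc)
    } else {
        data.frame(x = numeric(0), y = numeric(0))
    }
    list(breaks = breaks, mid = (breaks[-1] + breaks[-(nBins + 1)]) / 2,
         mass = mass, density = dens)
}

#' Rank-sum comparison of two depth distributions
#'
#' Unpaired Wilcoxon rank-sum (Mann-Whitney) test: exact when both
#' groups have at most 50 values and no ties are present, otherwise the
#' tie-corrected normal approximation with continuity correction.
#' `alternative = "greater"` tests whether `b` is stochastically greater
#' than `a` (deeper distributions give larger depth values).
#'
#' @param a,b numeric vectors of relative depths (or any values).
#' @param alternative "two.sided" or "greater" (b greater than a).
#' @param conditions length-2 character naming the two groups.
#' @return List (class `depthComparison`): test, statistic, p_value,
#'   alternative, significant (at p < 0.05), n per group.
#' @examples
#' wilcoxonCompare(c(1, 2, 3), c(4, 5, 6), alternative = "greater")$p_value
#' @export
wilcoxonCompare <- function(a, b, alternative = c("two.sided", "greater"),
                            conditions = c("a", "b")) {
    alternative <- match.arg(alternative)
    if (!length(a) || !length(b)) stop("empty input group")
    exact <- length(a) <= 50 && length(b) <= 50 &&
        !any(duplicated(c(a, b)))
    alt <- if (alternative == "greater") "less" else "two.sided"
    ht <- suppressWarnings(stats::wilcox.test(
        a, b, alternative = alt, exact = exact, correct = TRUE))
    structure(list(test = "Wilcoxon rank-sum",
                   statistic = unname(ht$statistic),
                   p_value = ht$p.value, alternative = alternative,
                   significant = ht$p.value < 0.05,
                   n = c(length(a), length(b)), conditions = conditions,
                   exact = exact),
              class = "depthComparison")
}

#' @export
print.depthComparison <- function(x, ...) {
    cat(sprintf("%s (%s%s): U = %.4g, p = %.4g%s  [n = %d vs %d]\n",
        x$test, x$alternative, if (x$exact) ", exact" else "",
        x$statistic, x$p_value, if (x$significant) " *" else "",
        x$n[1], x$n[2]))
    invisible(x)
}

#' Depth-band (tertile) comparison
#'
#' Splits the relative-depth axis into three equal bands
#' \[0, 1/3), \[1/3, 2/3), \[2/3, 1\] and runs [wilcoxonCompare()] on
#' the values of each group restricted to each band. A band in which
#' either group is empty is flagged `insufficient data` rather than
#' raising an error.
#'
#' @inheritParams wilcoxonCompare
#' @return List of three `depthComparison` results (or
#'   "insufficient data" markers), named band1-band3, with the band
#'   limits attached.
#' @export
tertileCompare <- function(a, b, alternative = c("two.sided", "greater"),
                           conditions = c("a", "b")) {
    alternative <- match.arg(alternative)
    lims <- rbind(c(0, 1 / 3), c(1 / 3, 2 / 3), c(2 / 3, 1))
    out <- vector("list", 3)
    names(out) <- paste0("band", 1:3)
    for (k in 1:3) {
        inA <- a[a >= lims[k, 1] & (a < lims[k, 2] | (k == 3 & a <= 1))]
        inB <- b[b >= lims[k, 1] & (b < lims[k, 2] | (k == 3 & b <= 1))]
        out[[k]] <- if (!length(inA) || !length(inB)) {
            structure(list(test = "Wilcoxon rank-sum", statistic = NA_real_,
                           p_value = NA_real_, alternative = alternative,
                           significant = NA, n = c(length(inA), length(inB)),
                           conditions = conditions, exact = NA,
                           note = "insufficient data"),
                      class = "depthComparison")
        } else {
            wilcoxonCompare(inA, inB, alternative, conditions)
        }
        out[[k]]$band <- lims[k, ]
    }
    out
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of the values against a normal distribution with
#' moment-matched mean and standard deviation. Because the parameters
#' are estimated from the same sample, the p-value is conservative
#' (biased towards non-rejection); it is used here only as a gate for
#' choosing rank-based tests. Constant samples get a standard-deviation
#' floor and return p ~ 0.
#'
#' @param values numeric vector, n >= 5.
#' @return The KS p-value.
#' @export
ksNormality <- function(values) {
    if (length(values) < 5) stop("need at least 5 values")
    s <- stats::sd(values)
    if (!is.finite(s) || s < 1e-12) s <- 1e-12
    suppressWarnings(stats::ks.test(values, "pnorm", mean(values), s))$p.value
}

#' Violin plot of depth distributions by condition
#'
#' Conditions on the x axis; relative depth on the y axis running from
#' 0 (stratum corneum) at the top to 1 (basal lamina) at the bottom.
#' Violin areas are normalized so shapes, not pixel counts, are
#' compared.
#'
#' @param dists list of [DepthDistribution-class] objects.
#' @return A ggplot object.
#' @export
plotDepthViolin <- function(dists) {
    if (is(dists, "DepthDistribution")) dists <- list(dists)
    df <- do.call(rbind, lapply(dists, function(d)
        if (length(d@perPixelRel))
            data.frame(condition = d@condition, d_rel = d@perPixelRel)
        else NULL))
    if (is.null(df)) stop("no DAB-positive pixels in any condition")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$d_rel,
                                     fill = .data$condition)) +
        ggplot2::geom_violin(scale = "area", trim = TRUE) +
        ggplot2::scale_y_reverse(limits = c(1, 0),
            name = "relative depth (0 = stratum corneum, 1 = basal lamina)") +
        ggplot2::xlab(NULL) +
        ggplot2::theme_minimal() +
        ggplot2::theme(legend.position = "none")
}
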