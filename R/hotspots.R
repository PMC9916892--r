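## Somatic point-mutation hotspot detection.
##
## Null model: sample i contributes a Bernoulli(p_i) indicator of hitting a
## fixed w-bp window, with p_i = 1 - (1 - w/G)^{m_i} under uniform placement
## of that sample's m_i mutations over the usable genome of length G. The
## number of mutated samples in a window is then Poisson-binomial, and a
## window's p-value is the exact upper tail P(K >= k).

#' Tile a genome into fixed-width windows
#'
#' Consecutive non-overlapping tiles per chromosome; a trailing partial
#' tile (width < `w`) is dropped so that every tested window has the same
#' width under the null.
#'
#' @param chromSizes named vector of chromosome lengths (bp).
#' @param w window width in bp (default 21).
#' @return `GRanges` of windows, all of width `w`.
#' @export
tileWindows <- function(chromSizes, w = 21L) {
    if (w < 1L) stop("window width w must be >= 1")
    tiles <- tileGenome(asSeqinfo(chromSizes), tilewidth = w,
                        cut.last.tile.in.chrom = TRUE)
    tiles[width(tiles) == w]
}

#' Count distinct mutated samples per window
#'
#' Multiple mutations from one sample inside a window count once.
#' Mutations on chromosomes absent from the windows are skipped with a
#' warning.
#'
#' @param windows `GRanges` of windows.
#' @param mutations width-1 `GRanges` with a `sample_id` metadata column.
#' @return `windows` with an integer metadata column `k`.
#' @export
countWindowSamples <- function(windows, mutations) {
    known <- as.character(seqnames(mutations)) %in% seqlevels(windows)
    if (!all(known)) {
        warning(sum(!known), " mutation(s) on unknown chromosomes skipped")
        mutations <- mutations[known]
    }
    k <- integer(length(windows))
    if (length(mutations)) {
        hits <- suppressWarnings(findOverlaps(windows, mutations))
        if (length(hits)) {
            pairs <- unique(data.frame(
                w = queryHits(hits),
                s = mcols(mutations)$sample_id[subjectHits(hits)]))
            tab <- table(pairs$w)
            k[as.integer(names(tab))] <- as.integer(tab)
        }
    }
    mcols(windows)$k <- k
    windows
}

#' Per-sample probability of hitting a fixed window
#'
#' Closed form `1 - (1 - w/G)^m` for the probability that a fixed w-bp
#' window contains at least one of `m` mutations placed uniformly and
#' independently on a genome of length `G`.
#'
#' @param m integer vector of per-sample mutation totals.
#' @param G usable genome length in bp.
#' @param w window width in bp.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
perSampleWindowProb <- function(m, G, w) {
    if (w < 1 || w > G) stop("require 1 <= w <= G")
    if (any(m < 0)) stop("mutation counts must be non-negative")
    1 - (1 - w / G)^m
}

## Exact Poisson-binomial PMF over 0..n by iterative convolution.
poissonBinomialPmf <- function(probs) {
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
    f <- 1
    for (p in probs) f <- c(f * (1 - p), 0) + c(0, f * p)
    f
}

#' Poisson-binomial upper tail probability
#'
#' Exact `P(K >= k)` for `K` the sum of independent Bernoulli variables
#' with success probabilities `probs`, computed by dynamic-programming
#' convolution of the PMF (no approximation).
#'
#' @param k integer threshold; `k <= 0` returns 1, `k > length(probs)`
#'   returns 0.
#' @param probs numeric vector of success probabilities in `[0, 1]`.
#' @return tail probability in `[0, 1]`.
#' @export
poissonBinomialSF <- function(k, probs) {
    n <- length(probs)
    if (k <= 0) return(1)
    if (k > n) return(0)
    pmf <- poissonBinomialPmf(probs)
    ## sum the tail from its far end to keep tiny terms from vanishing
    sum(rev(pmf[(k + 1L):(n + 1L)]))
}

#' Flag windows in problematic regions
#'
#' A window is flagged when it overlaps a mappability-masked interval or a
#' repeat interval by at least 1 bp, or lies on an excluded chromosome
#' (chrY by default). Flag precedence: `excluded_chrom` > `masked` >
#' `repeat`.
#'
#' @param windows `GRanges` of windows.
#' @param masked `GRanges` of mappability-masked intervals (thresholding
#'   of the alignability signal happens upstream; this ingests the BED).
#' @param repeats `GRanges` of repeat intervals.
#' @param excludedChroms character vector of chromosomes excluded outright.
#' @return `windows` with a character metadata column `filtered_reason`
#'   (`none` when unflagged).
#' @export
filterProblematic <- function(windows, masked = GRanges(),
                              repeats = GRanges(),
                              excludedChroms = "chrY") {
    reason <- rep("none", length(windows))
    if (length(repeats)) {
        hit <- overlapsAny(windows, repeats, minoverlap = 1L)
        reason[hit] <- "repeat"
    }
    if (length(masked)) {
        hit <- overlapsAny(windows, masked, minoverlap = 1L)
        reason[hit] <- "masked"
    }
    reason[as.character(seqnames(windows)) %in% excludedChroms] <-
        "excluded_chrom"
    mcols(windows)$filtered_reason <- reason
    windows
}

#' Detect somatic point-mutation hotspot windows
#'
#' Full scan: tile the genome, count distinct mutated samples per window,
#' compute exact Poisson-binomial tail p-values from a null model built
#' from every sample's mutation total, flag problematic windows, and
#' report unflagged windows with `p < alpha`. P-values are computed before
#' filtering; flagged windows are excluded from the hotspot list but kept
#' in the candidate table for audit.
#'
#' @param mutations width-1 `GRanges` with a `sample_id` metadata column.
#' @param chromSizes named vector of chromosome lengths.
#' @param masked,repeats problematic-region tracks (`GRanges`).
#' @param w window width in bp (default 21).
#' @param alpha significance threshold (default 0.001).
#' @param minK minimum sample count for a window to be scored (default 1).
#' @param excludedChroms chromosomes dropped from both tiling statistics
#'   and the usable genome length (default chrY).
#' @param bonferroni if `TRUE`, divide `alpha` by the number of tested
#'   (`k >= 1`, non-excluded) windows.
#' @return a [HotspotScan-class] object; see [hotspots()].
#' @export
detectHotspots <- function(mutations, chromSizes, masked = GRanges(),
                           repeats = GRanges(), w = 21L, alpha = 0.001,
                           minK = 1L, excludedChroms = "chrY",
                           bonferroni = FALSE) {
    samples <- sort(unique(mcols(mutations)$sample_id))
    if (length(samples) < 1L) stop("need at least one sample")
    usable <- setdiff(names(chromSizes), excludedChroms)
    G <- sum(as.numeric(chromSizes[usable]))
    if (G < w)
        stop("no usable genome left after chromosome exclusion")
    onUsable <- as.character(seqnames(mutations)) %in% usable
    m <- table(factor(mcols(mutations)$sample_id[onUsable],
                      levels = samples))
    probs <- perSampleWindowProb(as.integer(m), G, w)

    windows <- tileWindows(chromSizes, w)
    windows <- countWindowSamples(windows, mutations)
    cand <- windows[mcols(windows)$k >= max(1L, minK)]
    nTested <- sum(mcols(windows)$k >= 1L &
                   !(as.character(seqnames(windows)) %in% excludedChroms))

    ## convolve in sorted order so results are bit-identical under any
    ## input ordering or sample relabeling
    pmf <- poissonBinomialPmf(sort(probs))
    tail <- rev(cumsum(rev(pmf)))          # tail[k+1] = P(K >= k)
    pv <- tail[pmin(mcols(cand)$k, length(probs)) + 1L]
    pv[mcols(cand)$k > length(probs)] <- 0
    mcols(cand)$p_value <- as.numeric(pv)

    cand <- filterProblematic(cand, masked, repeats, excludedChroms)
    thr <- if (bonferroni) alpha / max(1L, nTested) else alpha
    mcols(cand)$hotspot <- mcols(cand)$filtered_reason == "none" &
        mcols(cand)$p_value < thr
    new("HotspotScan", candidates = cand, windowSize = as.integer(w),
        nSamples = length(samples), nTested = as.integer(nTested),
        alpha = alpha, bonferroni = bonferroni, genomeSize = G,
        nullProbs = as.numeric(probs))
}

#' Recurrence distributions across candidate window sizes
#'
#' Re-tiles and re-counts at each window size and summarizes the
#' distribution of the per-window sample count `k` over windows with
#' `k >= 1`. Because windows nest as the size grows, the maximum `k` is
#' non-decreasing in the window size.
#'
#' @param mutations width-1 `GRanges` with `sample_id`.
#' @param chromSizes named vector of chromosome lengths.
#' @param sizes window widths to compare (default 9, 21, 50, 5000).
#' @param excludedChroms chromosomes to drop (default chrY).
#' @return list with `summary` (data.frame: windowSize, nWindows, meanK,
#'   maxK) and `k` (named list of the k values per size).
#' @export
windowSizeSweep <- function(mutations, chromSizes,
                            sizes = c(9L, 21L, 50L, 5000L),
                            excludedChroms = "chrY") {
    if (any(sizes < 1L)) stop("window sizes must be >= 1")
    mutations <- mutations[!(as.character(seqnames(mutations)) %in%
                             excludedChroms)]
    ks <- lapply(sizes, function(w) {
        win <- countWindowSamples(tileWindows(chromSizes, w), mutations)
        kk <- mcols(win)$k
        kk[kk >= 1L]
    })
    names(ks) <- as.character(sizes)
    list(summary = data.frame(
             windowSize = sizes,
             nWindows = lengths(ks),
             meanK = vapply(ks, function(x) mean(as.numeric(x)), 0),
             maxK = vapply(ks, function(x) if (length(x)) max(x) else 0L, 0L)),
         k = ks)
}

#' Skewness and kurtosis diagnostics
#'
#' Population (biased) central-moment estimators, matching the usual
#' distribution-fitting diagnostics: skewness `m3 / m2^1.5`, kurtosis
#' (non-excess) `m4 / m2^2`. These satisfy `kurtosis >= skewness^2 + 1`.
#'
#' @param values numeric vector, length >= 3, non-constant.
#' @return list with elements `skewness` and `kurtosis`.
#' @export
momentDiagnostics <- function(values) {
    values <- as.numeric(values)
    if (length(values) < 3L) stop("need at least 3 values")
    m <- mean(values)
    m2 <- mean((values - m)^2)
    if (m2 == 0) stop("moments undefined for constant input")
    list(skewness = mean((values - m)^3) / m2^1.5,
         kurtosis = mean((values - m)^4) / m2^2)
}
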