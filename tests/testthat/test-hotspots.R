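test_that("genome tiling drops trailing partial windows", {
    expect_length(tileWindows(c(chr1 = 42L)), 2L)
    expect_length(tileWindows(c(chr1 = 50L)), 2L)      # trailing 8 bp dropped
    expect_length(tileWindows(c(chr1 = 100L, chr2 = 63L)), 4L + 3L)
    win <- tileWindows(c(chr1 = 50L))
    expect_equal(start(win), c(1L, 22L))
    expect_true(all(width(win) == 21L))
    expect_error(tileWindows(c(chr1 = 100L), w = 0L), "w must be")
})

test_that("window counts are per distinct sample", {
    win <- tileWindows(c(chr1 = 63L))
    expect_equal(mcols(countWindowSamples(win, mutGR(character(), character(),
                                                     integer())))$k, c(0L, 0L, 0L))
    ## sample A mutated thrice in window 1, B once: k = 2
    mut <- mutGR(c("A", "A", "A", "B"), "chr1", c(2L, 5L, 20L, 11L))
    expect_equal(mcols(countWindowSamples(win, mut))$k, c(2L, 0L, 0L))
    ## 5 samples spread (3, 2) over two windows
    mut5 <- mutGR(paste0("S", 1:5), "chr1", c(1L, 10L, 21L, 25L, 40L))
    expect_equal(mcols(countWindowSamples(win, mut5))$k, c(3L, 2L, 0L))
    ## unknown chromosome: warning, record skipped
    expect_warning(k <- mcols(countWindowSamples(
        win, mutGR("A", "chrUn", 5L)))$k, "unknown")
    expect_equal(k, c(0L, 0L, 0L))
})

test_that("per-sample window-hit probability follows the closed form", {
    expect_equal(perSampleWindowProb(0L, 100L, 21L), 0)
    expect_equal(perSampleWindowProb(5L, 100L, 100L), 1)
    expect_equal(perSampleWindowProb(2L, 100L, 21L), 1 - 0.79^2)
    expect_error(perSampleWindowProb(2L, 100L, 101L), "w <= G")
})

test_that("Poisson-binomial tail is exact against 2^n enumeration", {
    expect_equal(poissonBinomialSF(0L, runif(5)), 1)
    expect_equal(poissonBinomialSF(1L, rep(0, 4)), 0)
    expect_equal(poissonBinomialSF(4L, c(0.5, 0.5, 0.5)), 0)  # k > n
    expect_equal(poissonBinomialSF(2L, c(0.1, 0.2, 0.3)), 0.098,
                 tolerance = 1e-12)
    set.seed(11)
    for (i in 1:25) {
        n <- sample(2:12, 1L)
        p <- runif(n)
        k <- sample.int(n, 1L)
        expect_equal(poissonBinomialSF(k, p), pbEnumSF(k, p),
                     tolerance = 1e-12)
    }
})

test_that("Poisson-binomial tail reduces to binomial and is monotone", {
    set.seed(12)
    for (i in 1:10) {
        n <- sample(5:50, 1L)
        p <- runif(1L)
        k <- sample.int(n, 1L)
        expect_equal(poissonBinomialSF(k, rep(p, n)),
                     pbinom(k - 1L, n, p, lower.tail = FALSE),
                     tolerance = 1e-10)
    }
    p <- runif(10)
    sfs <- vapply(0:10, poissonBinomialSF, 0, probs = p)
    expect_true(all(diff(sfs) <= 1e-15))          # non-increasing in k
    p2 <- p; p2[3] <- min(1, p2[3] + 0.2)
    for (k in 1:10)                                # non-decreasing in p_i
        expect_gte(poissonBinomialSF(k, p2), poissonBinomialSF(k, p) - 1e-15)
})

test_that("problematic-region filtering flags masked, repeat, and chrY windows", {
    win <- tileWindows(c(chr1 = 63L, chrY = 42L))
    out <- filterProblematic(win)
    expect_equal(mcols(out)$filtered_reason,
                 c("none", "none", "none", "excluded_chrom", "excluded_chrom"))
    out <- filterProblematic(win, repeats = GRanges("chr1", IRanges(11, 30)))
    expect_equal(mcols(out)$filtered_reason[1:3], c("repeat", "repeat", "none"))
    out <- filterProblematic(win, masked = GRanges("chr1", IRanges(25, 26)))
    expect_equal(mcols(out)$filtered_reason[1:3], c("none", "masked", "none"))
})

test_that("hotspot detection recovers a planted window and respects exclusions", {
    spec <- fixtureSpec(seed = 101)
    mut <- simulateMutations(spec)$mutations
    scan <- detectHotspots(mut, spec$chromSizes)
    hot <- hotspots(scan)
    key <- paste(seqnames(hot), start(hot), end(hot))
    plantedKey <- paste(spec$plantedHotspots$chrom,
                        spec$plantedHotspots$start,
                        spec$plantedHotspots$end)
    expect_true(plantedKey %in% key)
    ## the planted window dominates: smallest p-value of the scan
    expect_equal(key[1L], plantedKey)

    ## all mutations on chrY: excluded outright
    mutY <- mutGR(paste0("S", 1:30), "chrY", seq(1000L, by = 1L, length.out = 30L))
    expect_error(detectHotspots(mutY, c(chrY = 10000L)), "usable genome")
    scanY <- detectHotspots(suppressWarnings(c(mutY, mutGR("S1", "chr1", 5L))),
                            c(chr1 = 10000L, chrY = 10000L))
    expect_true(all(seqnames(hotspots(scanY)) != "chrY"))
})

test_that("hotspot output is invariant to record order and sample relabeling", {
    spec <- fixtureSpec(seed = 77, nSamples = 40L,
                        chromSizes = c(chr1 = 300000L))
    mut <- simulateMutations(spec)$mutations
    ref <- hotspots(detectHotspots(mut, spec$chromSizes))
    set.seed(1)
    shuf <- mut[sample(length(mut))]
    expect_identical(as.data.frame(hotspots(detectHotspots(shuf, spec$chromSizes))),
                     as.data.frame(ref))
    relabeled <- mut
    mcols(relabeled)$sample_id <- paste0("X_", mcols(mut)$sample_id)
    expect_identical(as.data.frame(hotspots(detectHotspots(relabeled, spec$chromSizes))),
                     as.data.frame(ref))
})

test_that("window-size sweep shows containment monotonicity", {
    ## one mutation: every size reports exactly one window with k = 1
    one <- mutGR("A", "chr1", 500L)
    sw <- windowSizeSweep(one, c(chr1 = 100000L), sizes = c(9L, 21L, 50L))
    expect_equal(sw$summary$nWindows, c(1L, 1L, 1L))
    expect_equal(sw$summary$maxK, c(1L, 1L, 1L))

    ## two samples 30 bp apart: separate 21 bp tiles, one 50 bp tile
    two <- mutGR(c("A", "B"), "chr1", c(10L, 40L))
    sw2 <- windowSizeSweep(two, c(chr1 = 100000L), sizes = c(21L, 50L))
    expect_equal(sw2$summary$maxK, c(1L, 2L))

    spec <- fixtureSpec(seed = 5, nSamples = 30L,
                        chromSizes = c(chr1 = 300000L))
    mut <- simulateMutations(spec)$mutations
    sw3 <- windowSizeSweep(mut, spec$chromSizes, sizes = c(9L, 21L, 50L, 5000L))
    expect_true(all(diff(sw3$summary$maxK) >= 0))
})

test_that("moment diagnostics use population moments", {
    md <- momentDiagnostics(1:5)
    expect_equal(md$skewness, 0)
    expect_equal(md$kurtosis, 1.7)                 # m2 = 2, m4 = 6.8
    expect_gte(md$kurtosis, md$skewness^2 + 1)
    expect_error(momentDiagnostics(c(3, 3, 3)), "constant")
    expect_error(momentDiagnostics(c(1, 2)), "at least 3")
})
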