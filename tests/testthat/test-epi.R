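test_that("interaction filtering applies all four conditions strictly", {
    expect_equal(nrow(filterInteractions(interDF(character(), integer(),
                                                 character(), integer()))), 0L)
    ## adjacent 5 kb bins: distance exactly 5000, strict bound drops it
    adj <- interDF("chr1", 5001L, "chr1", 10001L)
    expect_equal(nrow(filterInteractions(adj)), 0L)
    ## idempotence
    tab <- rbind(interDF("chr1", 5001L, "chr1", 105001L),
                 interDF("chr1", 5001L, "chr1", 205001L, reads = 5L),
                 interDF("chr1", 5001L, "chr1", 305001L, p = 0.2),
                 interDF("chr1", 5001L, "chr2", 105001L),
                 interDF("chr1", 5001L, "chr1", 10001L))
    f1 <- filterInteractions(tab)
    expect_equal(nrow(f1), 1L)
    expect_identical(filterInteractions(f1), f1)
    ## distance upper bound strict at 10 Mb
    far <- interDF("chr1", 1L, "chr1", 10000001L)
    expect_equal(nrow(filterInteractions(far)), 0L)
})

test_that("anchor normalization orders pairs and enforces one bin width", {
    swapped <- interDF("chr1", 500001L, "chr1", 5001L)
    norm <- normalizeInteractions(swapped)
    expect_lt(norm$start1, norm$start2)
    bad <- interDF("chr1", 1L, "chr1", 100001L)
    bad$end2 <- bad$start2 + 999L
    expect_error(normalizeInteractions(bad), "bin width")
})

test_that("replicate merging sums counts and keeps the smaller p", {
    r1 <- rbind(interDF("chr1", 5001L, "chr1", 105001L, reads = 6L, p = 1e-3),
                interDF("chr1", 5001L, "chr1", 205001L, reads = 9L, p = 1e-2))
    r2 <- rbind(interDF("chr1", 5001L, "chr1", 105001L, reads = 7L, p = 1e-4),
                interDF("chr2", 5001L, "chr2", 105001L, reads = 11L, p = 1e-5))
    m <- mergeReplicates(r1, r2)
    expect_equal(nrow(m), 3L)
    shared <- m[m$chrom1 == "chr1" & m$start2 == 105001L, ]
    expect_equal(shared$read_count, 13L)
    expect_equal(shared$p_value, 1e-4)
    expect_true(shared$merged)
    only2 <- m[m$chrom1 == "chr2", ]
    expect_equal(only2$read_count, 11L)
    expect_false(only2$merged)
    r3 <- interDF("chr1", 1L, "chr1", 100001L, binSize = 10000L)
    expect_error(mergeReplicates(r1, r3), "bin width")
})

test_that("anchor-gene annotation uses the 10% of min(width) rule", {
    genes50k <- makeGenes("chr1", 1L, 50000L, "+", "BIG", "protein_coding")
    ## 50 kb gene overlapping a 5 kb anchor by 400 bp: 400 < 500 fails
    anc <- interDF("chr1", 49601L, "chr1", 200001L)
    expect_equal(nrow(annotateAnchorGenes(anc, genes50k)), 0L)
    ## 500 bp overlap passes (boundary, >=)
    anc2 <- interDF("chr1", 49501L, "chr1", 200001L)
    hits <- annotateAnchorGenes(anc2, genes50k)
    expect_equal(hits$symbol, "BIG")
    expect_equal(hits$overlapBp, 500L)
    ## gene fully inside anchor: assigned (100%)
    tiny <- makeGenes("chr1", 201001L, 202000L, "+", "TINY", "lncRNA")
    expect_equal(annotateAnchorGenes(anc2, tiny)$symbol, "TINY")
    ## 1 kb gene overlapping by exactly 100 bp: assigned at 10%
    edge <- makeGenes("chr1", 204901L, 205900L, "+", "EDGE", "miRNA")
    expect_equal(annotateAnchorGenes(anc2, edge)$overlapBp, 100L)
})

test_that("promoter regions are strand-aware TSS windows, clipped", {
    plus <- makeGenes("chr1", 10001L, 20000L, "+", "P", "protein_coding")
    pr <- promoterRegions(plus)
    expect_equal(c(start(pr), end(pr)), c(8001L, 12000L))  # 0-based [8000,12000)
    minus <- makeGenes("chr1", 10001L, 20000L, "-", "M", "protein_coding")
    pm <- promoterRegions(minus)
    expect_equal(c(start(pm), end(pm)), c(18001L, 22000L))
    ## clipping at chromosome bounds
    early <- makeGenes("chr1", 501L, 3000L, "+", "E", "protein_coding")
    pe <- promoterRegions(early, chromSizes = c(chr1 = 2400L))
    expect_equal(c(start(pe), end(pe)), c(1L, 2400L))
    ## non-coding genes contribute no promoters
    expect_length(promoterRegions(makeGenes("chr1", 1000L, 2000L, "+",
                                            "L", "lncRNA")), 0L)
})

epiFixture <- function() {
    proms <- promoterRegions(makeGenes(c("chr1", "chr1"),
                                       c(400001L, 600001L),
                                       c(420000L, 615000L), c("+", "-"),
                                       c("GA", "GB"),
                                       c("protein_coding", "protein_coding")))
    peaks <- GRanges("chr1", IRanges(c(101001L, 398501L), c(101800L, 398900L)))
    list(proms = proms, peaks = peaks)
}

test_that("EPI calling requires a peak side and a promoter side", {
    fx <- epiFixture()
    ## peak on side 1, promoter on side 2: one EPI
    one <- callEpis(interDF("chr1", 100001L, "chr1", 398001L),
                    fx$peaks[1L], fx$proms)
    expect_equal(nrow(one), 1L)
    expect_equal(one$enhancer_side, 1L)
    expect_equal(one$target_genes, "GA")
    ## peaks and promoters on both sides: both orientations emitted
    both <- callEpis(interDF("chr1", 395001L, "chr1", 400001L),
                     GRanges("chr1", IRanges(c(395501L, 400501L),
                                             c(395600L, 400600L))),
                     fx$proms)
    expect_equal(sort(both$enhancer_side), c(1L, 2L))
    ## peak but no promoter anywhere: nothing
    none <- callEpis(interDF("chr1", 100001L, "chr1", 200001L),
                     fx$peaks[1L], fx$proms)
    expect_equal(nrow(none), 0L)
    ## every emitted EPI re-checks: enhancer anchor hits a peak,
    ## promoter anchor hits a promoter
    for (i in seq_len(nrow(both))) {
        enh <- if (both$enhancer_side[i] == 1L)
            GRanges(both$chrom1[i], IRanges(both$start1[i], both$end1[i]))
        else GRanges(both$chrom2[i], IRanges(both$start2[i], both$end2[i]))
        expect_gte(nrow(bruteOverlap(enh, GRanges("chr1",
            IRanges(c(395501L, 400501L), c(395600L, 400600L))))), 1L)
    }
})

test_that("condition-specific EPIs are a bin-pair set difference", {
    fx <- epiFixture()
    cancer <- callEpis(rbind(interDF("chr1", 100001L, "chr1", 398001L),
                             interDF("chr1", 100001L, "chr1", 613001L)),
                       fx$peaks[1L], fx$proms)
    normal <- callEpis(interDF("chr1", 100001L, "chr1", 398001L),
                       fx$peaks[1L], fx$proms)
    expect_equal(nrow(conditionSpecificEpis(cancer, cancer)), 0L)
    sp <- conditionSpecificEpis(cancer, normal)
    expect_equal(nrow(sp), 1L)
    expect_equal(sp$start2, 613001L)
    ## same bin pair with different targets is still excluded
    normal2 <- normal
    normal2$target_genes <- "OTHER"
    expect_equal(nrow(conditionSpecificEpis(cancer[cancer$start2 == 398001L, ],
                                            normal2)), 0L)
    ## counting identity: |specific| + |shared pairs| = distinct cancer pairs
    key <- paste(cancer$chrom1, cancer$start1, cancer$chrom2, cancer$start2)
    nShared <- length(intersect(key, paste(normal$chrom1, normal$start1,
                                           normal$chrom2, normal$start2)))
    expect_equal(nrow(sp) + nShared, length(unique(key)))
})
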