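test_that("one-sided Fisher p matches hand-derived extreme and worked tables", {
    ## all 10 cases covered, no controls: single extreme table
    expect_equal(fisherCaseEnrichment(10, 0, 0, 10), 1 / choose(20, 10),
                 tolerance = 1e-12)
    ## 8/10 cases vs 1/10 controls
    expect_equal(fisherCaseEnrichment(8, 2, 1, 9), 460 / 167960,
                 tolerance = 1e-12)
    expect_equal(fisherCaseEnrichment(0, 10, 3, 7), 1)
})

test_that("per-base association segments agree with direct per-base tables", {
    case <- cnvGR(c("c1", "c2", "c3"), "chr1",
                  c(10L, 10L, 25L), c(30L, 40L, 45L))
    ctrl <- cnvGR("k1", "chr1", 35L, 60L, cohort = "control")
    region <- GRanges("chr1", IRanges(1, 100))
    assoc <- perBaseAssociation(case, ctrl, region, "duplication",
                                nCase = 3L, nControl = 2L)
    ## segments tile the region exactly
    expect_equal(assoc$start[1L], 1L)
    expect_equal(assoc$end[nrow(assoc)], 100L)
    expect_true(all(assoc$start[-1L] == head(assoc$end, -1L) + 1L))
    ## check a, c at hand-picked bases against interval membership
    baseAt <- function(pos) assoc[assoc$start <= pos & assoc$end >= pos, ]
    expect_equal(baseAt(15)$a, 2L); expect_equal(baseAt(15)$c, 0L)
    expect_equal(baseAt(28)$a, 3L)
    expect_equal(baseAt(38)$a, 2L); expect_equal(baseAt(38)$c, 1L)
    expect_equal(baseAt(70)$a, 0L); expect_equal(baseAt(70)$p, 1)
    ## p equals the closed-form Fisher tail everywhere
    expect_equal(assoc$p,
                 fisherCaseEnrichment(assoc$a, assoc$b, assoc$c, assoc$d))
    ## a sample covering a base twice counts once
    dup <- cnvGR(c("c1", "c1"), "chr1", c(10L, 15L), c(30L, 35L))
    assoc2 <- perBaseAssociation(dup, ctrl, region, "duplication",
                                 nCase = 3L, nControl = 2L)
    expect_true(all(assoc2$a <= 1L))
})

test_that("significant bases merge into maximal disjoint sorted spans", {
    ## synthetic per-base table: significant at 0-based 5..14 and 20..22
    assoc <- data.frame(chrom = "chr1",
                        start = c(1L, 6L, 16L, 21L, 24L),
                        end = c(5L, 15L, 20L, 23L, 30L),
                        a = 0L, b = 10L, c = 0L, d = 10L,
                        p = c(0.9, 0.01, 0.9, 0.01, 0.9))
    case <- cnvGR("c1", "chr1", 6L, 23L)
    spans <- mergeSignificantPositions(assoc, case, "duplication")
    expect_equal(start(spans), c(6L, 21L))        # 0-based [5,15) and [20,23)
    expect_equal(end(spans), c(15L, 23L))
    expect_true(all(mcols(spans)$min_p == 0.01))
    expect_equal(as.character(mcols(spans)$case_samples[[1L]]), "c1")
    ## no significant base -> empty; all significant -> single span
    expect_length(mergeSignificantPositions(
        transform(assoc, p = 1), case, "duplication"), 0L)
    one <- mergeSignificantPositions(transform(assoc, p = 0.001), case,
                                     "duplication")
    expect_equal(c(start(one), end(one)), c(1L, 30L))
})

test_that("uniqueness and IR-score reproduce the worked set-algebra example", {
    spans <- cnvrSpans("chr1", c(100L, 300L), c(200L, 400L),
                       list(paste0("s", 1:5), paste0("s", 4:6)))
    spans <- cnvrUniqueness(spans)
    expect_equal(mcols(spans)$uniqueness, c(3L, 1L))
    mcols(spans)$cluster_id <- c(1L, 1L)
    spans <- irScoreSelect(spans)
    expect_equal(mcols(spans)$ir_score, c(5 - 2, 3 - 2))
    expect_equal(mcols(spans)$is_representative, c(TRUE, FALSE))

    ## single CNVR: uniqueness = |S|; identical sets: both 0, leftmost wins
    single <- cnvrUniqueness(cnvrSpans("chr1", 1L, 50L, list(paste0("s", 1:5))))
    expect_equal(mcols(single)$uniqueness, 5L)
    ident <- cnvrSpans("chr1", c(500L, 100L), c(600L, 200L),
                       list(c("a", "b", "c"), c("a", "b", "c")))
    ident <- cnvrUniqueness(ident)
    expect_equal(mcols(ident)$uniqueness, c(0L, 0L))
    mcols(ident)$cluster_id <- c(1L, 1L)
    ident <- irScoreSelect(ident)
    expect_equal(mcols(ident)$ir_score, c(0, 0))
    expect_equal(which(mcols(ident)$is_representative), 2L)  # leftmost start
})

test_that("DBSCAN clustering separates distant CNVRs and joins close ones", {
    far <- cnvrSpans("chr1", c(1000L, 100001000L), c(2000L, 100002000L),
                     list(c("a", "b"), c("c", "d")))
    far <- cnvrUniqueness(far)
    far <- clusterCnvrs(far, eps = 0.5)
    expect_length(unique(mcols(far)$cluster_id), 2L)

    near <- cnvrSpans("chr1", c(1000L, 1400L, 1800L),
                      c(1300L, 1700L, 2100L),
                      list(c("a", "b"), c("a", "c"), c("b", "c")))
    near <- cnvrUniqueness(near)
    near <- clusterCnvrs(near, eps = 3)
    expect_length(unique(mcols(near)$cluster_id), 1L)

    one <- clusterCnvrs(cnvrUniqueness(cnvrSpans("chr1", 1L, 10L, list("a"))))
    expect_equal(mcols(one)$cluster_id, 1L)
    expect_error(clusterCnvrs(near, eps = 0), "eps")
})

test_that("planted case-enriched CNVR is recovered with exact boundaries", {
    spec <- fixtureSpec(seed = 31, cnvBackgroundRate = 0)
    cnv <- simulateCnvs(spec)
    cs <- runPeakCnv(cnv$cnvs[mcols(cnv$cnvs)$cohort == "case"],
                     cnv$cnvs[mcols(cnv$cnvs)$cohort == "control"],
                     spec$chromSizes, "duplication",
                     nCase = spec$nCase, nControl = spec$nControl)
    rep_ <- representatives(cs)
    expect_length(rep_, 1L)
    expect_equal(start(rep_), spec$plantedCnvrs$start)
    expect_equal(end(rep_), spec$plantedCnvrs$end)
    expect_equal(as.character(mcols(rep_)$case_samples[[1L]]),
                 cnv$truth$caseCarriers[[1L]])
    ## identical cohorts carry no signal
    null <- runPeakCnv(cnv$cnvs[mcols(cnv$cnvs)$cohort == "case"],
                       cnv$cnvs[mcols(cnv$cnvs)$cohort == "case"],
                       spec$chromSizes, "duplication",
                       nCase = spec$nCase, nControl = spec$nCase)
    expect_length(cnvrCandidates(null), 0L)
})

test_that("two distant planted regions yield two representatives", {
    planted <- data.frame(chrom = c("chr1", "chr2"),
                          start = c(100001L, 700001L),
                          end = c(150000L, 720000L),
                          direction = "deletion",
                          caseFraction = c(0.6, 0.5),
                          controlFraction = c(1 / 30, 0))
    spec <- fixtureSpec(seed = 32, cnvBackgroundRate = 0,
                        plantedCnvrs = planted)
    cnv <- simulateCnvs(spec)
    cs <- runPeakCnv(cnv$cnvs[mcols(cnv$cnvs)$cohort == "case"],
                     cnv$cnvs[mcols(cnv$cnvs)$cohort == "control"],
                     spec$chromSizes, "deletion",
                     nCase = spec$nCase, nControl = spec$nControl)
    rep_ <- representatives(cs)
    expect_length(rep_, 2L)
    expect_equal(start(rep_), planted$start)
    expect_equal(end(rep_), planted$end)
    ## exactly one representative per cluster
    cands <- cnvrCandidates(cs)
    perCluster <- tapply(mcols(cands)$is_representative,
                         mcols(cands)$cluster_id, sum)
    expect_true(all(perCluster == 1L))
})

test_that("CNVR pipeline is invariant to record order and sample relabeling", {
    spec <- fixtureSpec(seed = 33)
    cnv <- simulateCnvs(spec)
    case <- cnv$cnvs[mcols(cnv$cnvs)$cohort == "case"]
    ctrl <- cnv$cnvs[mcols(cnv$cnvs)$cohort == "control"]
    run <- function(ca, co) as.data.frame(representatives(
        runPeakCnv(ca, co, spec$chromSizes, "duplication",
                   nCase = spec$nCase, nControl = spec$nControl)))[
        , c("seqnames", "start", "end", "uniqueness", "ir_score")]
    ref <- run(case, ctrl)
    set.seed(2)
    expect_identical(run(case[sample(length(case))],
                         ctrl[sample(length(ctrl))]), ref)
    case2 <- case
    mcols(case2)$sample_id <- paste0("zz", mcols(case)$sample_id)
    expect_identical(run(case2, ctrl), ref)
})
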