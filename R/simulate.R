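## Seeded synthetic-fixture generators.
##
## Every input the pipeline consumes can be generated here with planted
## signals, so each stage is testable against known ground truth without
## external downloads. All generators are deterministic under the spec
## seed; background mutation placement is uniform, matching the
## assumption of the Poisson-binomial null so type-I-error checks are
## well-posed.

#' Specification of a synthetic cohort and regulatory scenario
#'
#' Defaults describe the standard test world: 100 tumor samples on a toy
#' genome of two 1 Mb chromosomes, a background of 50 uniformly placed
#' somatic point mutations per sample, one planted 21 bp hotspot window
#' carried by 30% of samples; 30 case and 30 control CNV samples with one
#' planted duplication carried by 20/30 cases and 1/30 controls
#' (noise-free breakpoints); and a 5 kb-binned Hi-C scenario with two
#' cancer-specific enhancer-promoter interactions.
#'
#' @param seed integer seed governing every stochastic stage.
#' @param chromSizes named vector of chromosome lengths.
#' @param nSamples mutation-cohort size.
#' @param backgroundMutationRate expected background mutations per sample
#'   (Poisson).
#' @param plantedHotspots data.frame with `chrom`, `start`, `end`
#'   (1-based, tile-aligned) and `fraction` (carrier probability).
#' @param nCase,nControl CNV cohort sizes.
#' @param cnvBackgroundRate expected background CNVs per sample (Poisson;
#'   0 = noise-free).
#' @param cnvLengthRange background CNV length range in bp.
#' @param plantedCnvrs data.frame with `chrom`, `start`, `end`,
#'   `direction`, `caseFraction`, `controlFraction`.
#' @param binSize Hi-C bin width in bp.
#' @return object of class `FixtureSpec` (a validated list).
#' @export
fixtureSpec <- function(seed = 1L,
                        chromSizes = c(chr1 = 1000000L, chr2 = 1000000L),
                        nSamples = 100L,
                        backgroundMutationRate = 50,
                        plantedHotspots = data.frame(
                            chrom = "chr1", start = 10501L, end = 10521L,
                            fraction = 0.3),
                        nCase = 30L, nControl = 30L,
                        cnvBackgroundRate = 2,
                        cnvLengthRange = c(10000L, 50000L),
                        plantedCnvrs = data.frame(
                            chrom = "chr1", start = 200001L,
                            end = 250000L, direction = "duplication",
                            caseFraction = 20 / 30,
                            controlFraction = 1 / 30),
                        binSize = 5000L) {
    spec <- list(seed = as.integer(seed), chromSizes = chromSizes,
                 nSamples = as.integer(nSamples),
                 backgroundMutationRate = backgroundMutationRate,
                 plantedHotspots = plantedHotspots,
                 nCase = as.integer(nCase),
                 nControl = as.integer(nControl),
                 cnvBackgroundRate = cnvBackgroundRate,
                 cnvLengthRange = cnvLengthRange,
                 plantedCnvrs = plantedCnvrs, binSize = as.integer(binSize))
    fr <- c(spec$plantedHotspots$fraction, spec$plantedCnvrs$caseFraction,
            spec$plantedCnvrs$controlFraction)
    if (any(fr < 0 | fr > 1)) stop("planted fractions must lie in [0,1]")
    inBounds <- function(df) {
        all(df$chrom %in% names(chromSizes)) &&
            all(df$start >= 1L) &&
            all(df$end <= chromSizes[df$chrom])
    }
    if (nrow(spec$plantedHotspots) && !inBounds(spec$plantedHotspots))
        stop("planted hotspot outside chromosome bounds")
    if (nrow(spec$plantedCnvrs) && !inBounds(spec$plantedCnvrs))
        stop("planted CNVR outside chromosome bounds")
    structure(spec, class = "FixtureSpec")
}

## Uniform random width-1 positions over a genome, chromosome chosen
## proportionally to its length.
randomPositions <- function(n, chromSizes) {
    if (n == 0L)
        return(GRanges(seqinfo = asSeqinfo(chromSizes)))
    chrom <- sample(names(chromSizes), n, replace = TRUE,
                    prob = as.numeric(chromSizes) / sum(as.numeric(chromSizes)))
    pos <- vapply(chrom, function(ch) sample.int(chromSizes[[ch]], 1L), 0L)
    GRanges(chrom, IRanges(pos, width = 1L),
            seqinfo = asSeqinfo(chromSizes))
}

#' Simulate a somatic point-mutation cohort
#'
#' Per sample, `Poisson(backgroundMutationRate)` mutations at uniform
#' genomic positions; for each planted hotspot, each sample independently
#' carries one mutation at a uniform position inside the window with the
#' stated fraction.
#'
#' @param spec a [fixtureSpec()].
#' @return list with `mutations` (width-1 `GRanges`, `sample_id` column,
#'   sorted) and `truth` (the planted-hotspot data.frame).
#' @export
simulateMutations <- function(spec) {
    set.seed(spec$seed)
    samples <- sprintf("S%03d", seq_len(spec$nSamples))
    parts <- list()
    for (s in samples) {
        n <- rpois(1L, spec$backgroundMutationRate)
        gr <- randomPositions(n, spec$chromSizes)
        if (length(gr)) mcols(gr)$sample_id <- s
        parts[[length(parts) + 1L]] <- gr
        if (nrow(spec$plantedHotspots)) {
            for (h in seq_len(nrow(spec$plantedHotspots))) {
                ph <- spec$plantedHotspots[h, ]
                if (runif(1L) < ph$fraction) {
                    pos <- ph$start +
                        sample.int(ph$end - ph$start + 1L, 1L) - 1L
                    g <- GRanges(ph$chrom, IRanges(pos, width = 1L),
                                 seqinfo = asSeqinfo(spec$chromSizes))
                    mcols(g)$sample_id <- s
                    parts[[length(parts) + 1L]] <- g
                }
            }
        }
    }
    mutations <- sort(suppressWarnings(do.call(c, parts)))
    list(mutations = mutations, truth = spec$plantedHotspots)
}

#' Simulate case/control CNV cohorts
#'
#' Background CNVs are uniform random intervals (length uniform in
#' `cnvLengthRange`, direction coin-flip) in both cohorts at rate
#' `cnvBackgroundRate` per sample; each planted CNVR is carried with
#' identical breakpoints by `round(fraction * cohort size)` samples drawn
#' at random from each cohort.
#'
#' @param spec a [fixtureSpec()].
#' @return list with `cnvs` (`GRanges`, metadata `sample_id`,
#'   `direction`, `cohort`), `caseSamples`, `controlSamples`, and `truth`
#'   (planted data.frame with carrier id lists).
#' @export
simulateCnvs <- function(spec) {
    set.seed(spec$seed + 1L)
    caseSamples <- sprintf("case%03d", seq_len(spec$nCase))
    ctrlSamples <- sprintf("ctrl%03d", seq_len(spec$nControl))
    parts <- list()
    addRec <- function(chrom, start, end, sample, direction, cohort) {
        g <- GRanges(chrom, IRanges(start, end),
                     seqinfo = asSeqinfo(spec$chromSizes))
        mcols(g) <- DataFrame(sample_id = sample, direction = direction,
                              cohort = cohort)
        parts[[length(parts) + 1L]] <<- g
    }
    background <- function(samples, cohort) {
        for (s in samples) {
            n <- rpois(1L, spec$cnvBackgroundRate)
            for (i in seq_len(n)) {
                chrom <- sample(names(spec$chromSizes), 1L)
                len <- sample(spec$cnvLengthRange[1L]:spec$cnvLengthRange[2L], 1L)
                maxStart <- spec$chromSizes[[chrom]] - len + 1L
                start <- sample.int(maxStart, 1L)
                addRec(chrom, start, start + len - 1L, s,
                       sample(c("deletion", "duplication"), 1L), cohort)
            }
        }
    }
    background(caseSamples, "case")
    background(ctrlSamples, "control")
    truth <- spec$plantedCnvrs
    truth$caseCarriers <- vector("list", nrow(truth))
    truth$controlCarriers <- vector("list", nrow(truth))
    for (i in seq_len(nrow(spec$plantedCnvrs))) {
        pc <- spec$plantedCnvrs[i, ]
        nCa <- round(pc$caseFraction * spec$nCase)
        nCo <- round(pc$controlFraction * spec$nControl)
        carCa <- sort(sample(caseSamples, nCa))
        carCo <- sort(sample(ctrlSamples, nCo))
        for (s in carCa) addRec(pc$chrom, pc$start, pc$end, s,
                                pc$direction, "case")
        for (s in carCo) addRec(pc$chrom, pc$start, pc$end, s,
                                pc$direction, "control")
        truth$caseCarriers[[i]] <- carCa
        truth$controlCarriers[[i]] <- carCo
    }
    cnvs <- if (length(parts)) sort(suppressWarnings(do.call(c, parts)))
            else GRanges(seqinfo = asSeqinfo(spec$chromSizes))
    list(cnvs = cnvs, caseSamples = caseSamples,
         controlSamples = ctrlSamples, truth = truth)
}

#' Simulate a complete regulatory scenario
#'
#' Builds a deterministic toy regulatory landscape on the spec genome:
#' protein-coding and lncRNA genes, H3K27ac peaks, Hi-C interaction
#' tables for a cancer and a normal condition where two planted EPIs
#' exist only in cancer (plus one shared EPI and distractor interactions
#' failing each filter), variants placed inside enhancer bins (planted),
#' inside promoter bins and intergenic space (distractors), WGS calls
#' replicating a chosen subset, and gene sets over the toy gene universe.
#'
#' @param spec a [fixtureSpec()].
#' @return list with `genes`, `peaks`, `interactionsCancer`,
#'   `interactionsNormal`, `variants`, `wgsSnvs`, `wgsCnvSegments`,
#'   `geneSets`, and `truth` (expected candidate table: variant id,
#'   target genes, replication flag).
#' @export
simulateRegulatoryScenario <- function(spec) {
    set.seed(spec$seed + 2L)
    bs <- spec$binSize
    bin <- function(i) c(i * bs + 1L, (i + 1L) * bs)   # 0-based bin index
    genes <- makeGenes(
        chrom = c("chr1", "chr1", "chr1", "chr1"),
        start = c(400001L, 600001L, 102001L, 800001L),
        end = c(420000L, 615000L, 104000L, 820000L),
        strand = c("+", "-", "+", "+"),
        symbol = c("GENEA", "GENEB", "LNC1", "GENEC"),
        biotype = c("protein_coding", "protein_coding", "lncRNA",
                    "protein_coding"),
        source = "fantom5")
    ## enhancer bins 20 ([100001,105000]) and 30 ([150001,155000]);
    ## promoter bins cover the TSS of GENEA (400001, bin 80) and GENEB
    ## (TSS = end = 615000, bin 122: [610001,615000])
    enh1 <- bin(20L); enh2 <- bin(30L); enh3 <- bin(140L)
    promA <- bin(80L); promB <- bin(122L)
    peaks <- GRanges("chr1", IRanges(c(101001L, 151001L, 701001L),
                                     c(101800L, 151800L, 701800L)))
    mkInter <- function(s1, e1, s2, e2, reads, p,
                        chrom1 = "chr1", chrom2 = "chr1") {
        data.frame(chrom1 = chrom1, start1 = s1, end1 = e1,
                   chrom2 = chrom2, start2 = s2, end2 = e2,
                   read_count = reads, p_value = p)
    }
    epi1 <- mkInter(enh1[1L], enh1[2L], promA[1L], promA[2L], 25L, 1e-4)
    epi2 <- mkInter(enh2[1L], enh2[2L], promB[1L], promB[2L], 30L, 1e-5)
    shared <- mkInter(bin(140L)[1L], bin(140L)[2L], promA[1L], promA[2L],
                      18L, 2e-4)
    distractors <- rbind(
        mkInter(bin(40L)[1L], bin(40L)[2L], promA[1L], promA[2L], 4L, 1e-4),
        mkInter(bin(41L)[1L], bin(41L)[2L], promA[1L], promA[2L], 40L, 0.5),
        mkInter(bin(50L)[1L], bin(50L)[2L], bin(51L)[1L], bin(51L)[2L],
                40L, 1e-4),
        mkInter(bin(10L)[1L], bin(10L)[2L], bin(11L)[1L], bin(11L)[2L],
                40L, 1e-4, chrom2 = "chr2"))
    interactionsCancer <- normalizeInteractions(
        rbind(epi1, epi2, shared, distractors))
    interactionsNormal <- normalizeInteractions(rbind(shared, distractors))
    variants <- GRanges("chr1",
                        IRanges(c(102500L, 151601L, 401000L, 900001L),
                                c(102500L, 153600L, 401000L, 900001L)))
    mcols(variants) <- DataFrame(
        class = c("gwas_snp", "cnvr_dup", "gwas_snp", "gwas_snp"),
        id = c("V1", "V2", "D1", "D2"))
    wgsSnvs <- GRanges("chr1", IRanges(c(102500L, 500000L), width = 1L))
    mcols(wgsSnvs) <- DataFrame(ref = c("A", "G"), alt = c("T", "C"),
                                qual = c(60, 55), dp = c(30L, 25L))
    wgsCnvSegments <- GRanges("chr1", IRanges(700001L, 750000L))
    mcols(wgsCnvSegments) <- DataFrame(direction = "duplication")
    universe <- c(mcols(genes)$symbol, sprintf("BKG%02d", 1:16))
    geneSets <- list(
        PLANTED_TARGETS = structure(c("GENEA", "GENEB"),
                                    description = "planted EPI targets"),
        BACKGROUND_SET = structure(sprintf("BKG%02d", 1:8),
                                   description = "background genes"))
    truth <- data.frame(
        variantId = c("V1", "V2"),
        targetGenes = c("GENEA", "GENEB"),
        replicated = c(TRUE, FALSE))
    list(genes = genes, peaks = peaks,
         interactionsCancer = interactionsCancer,
         interactionsNormal = interactionsNormal,
         variants = variants, wgsSnvs = wgsSnvs,
         wgsCnvSegments = wgsCnvSegments, universe = universe,
         geneSets = geneSets, truth = truth)
}

#' Write a minimal VCF from a record GRanges
#'
#' @param records `GRanges` with `ref`, `alt`, `qual`, `dp` metadata
#'   columns (`dp` may be `NA` to omit the INFO field).
#' @param path output path.
#' @param chromSizes optional named lengths for contig header lines.
#' @return invisibly, the path written.
#' @export
writeVcfMinimal <- function(records, path, chromSizes = NULL) {
    header <- c("##fileformat=VCFv4.2",
                "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">")
    if (!is.null(chromSizes))
        header <- c(header,
                    sprintf("##contig=<ID=%s,length=%d>",
                            names(chromSizes), as.integer(chromSizes)))
    header <- c(header,
                "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    dp <- mcols(records)$dp
    info <- ifelse(is.na(dp), ".", paste0("DP=", dp))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\t%s",
                    as.character(seqnames(records)), start(records),
                    mcols(records)$ref, mcols(records)$alt,
                    format(mcols(records)$qual, trim = TRUE),
                    info)
    writeLines(c(header, body), path)
    invisible(path)
}

#' Write every fixture file for a spec
#'
#' Materializes the synthetic world as the exact text formats the
#' pipeline readers consume (mutation TSV, CNV TSV, interaction tables,
#' peak BED, gene table, chrom.sizes, VCF, GMT) plus a machine-checkable
#' truth manifest (JSON). Output is byte-identical under a fixed seed.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory (created if needed).
#' @return invisibly, named vector of file paths.
#' @export
writeFixtures <- function(spec, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(dir, f)
    mut <- simulateMutations(spec)
    cnv <- simulateCnvs(spec)
    reg <- simulateRegulatoryScenario(spec)

    write.table(data.frame(sample_id = mcols(mut$mutations)$sample_id,
                           chrom = as.character(seqnames(mut$mutations)),
                           pos = start(mut$mutations)),
                p("mutations.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(sample_id = mcols(cnv$cnvs)$sample_id,
                           chrom = as.character(seqnames(cnv$cnvs)),
                           start = start(cnv$cnvs), end = end(cnv$cnvs),
                           direction = mcols(cnv$cnvs)$direction,
                           cohort = mcols(cnv$cnvs)$cohort),
                p("cnvs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeInteractions(reg$interactionsCancer, p("interactions_cancer.tsv"))
    writeInteractions(reg$interactionsNormal, p("interactions_normal.tsv"))
    writeBed(reg$peaks, p("peaks.bed"))
    write.table(data.frame(chrom = as.character(seqnames(reg$genes)),
                           start = start(reg$genes) - 1L,
                           end = end(reg$genes),
                           symbol = mcols(reg$genes)$symbol,
                           score = 0L,
                           strand = as.character(strand(reg$genes)),
                           biotype = mcols(reg$genes)$biotype,
                           source = mcols(reg$genes)$source),
                p("genes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write.table(data.frame(chrom = names(spec$chromSizes),
                           size = as.integer(spec$chromSizes)),
                p("chrom.sizes"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    writeVcfMinimal(reg$wgsSnvs, p("wgs.vcf"), spec$chromSizes)
    writeGmt(reg$geneSets, p("sets.gmt"))
    truth <- list(plantedHotspots = mut$truth,
                  plantedCnvrs = cnv$truth[, c("chrom", "start", "end",
                                               "direction")],
                  cnvrCaseCarriers = cnv$truth$caseCarriers,
                  regulatory = reg$truth)
    jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <- c(mutations = p("mutations.tsv"), cnvs = p("cnvs.tsv"),
               interactionsCancer = p("interactions_cancer.tsv"),
               interactionsNormal = p("interactions_normal.tsv"),
               peaks = p("peaks.bed"), genes = p("genes.tsv"),
               chromSizes = p("chrom.sizes"), vcf = p("wgs.vcf"),
               gmt = p("sets.gmt"), truth = p("truth.json"))
    invisible(files)
}
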