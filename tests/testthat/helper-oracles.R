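## Independent brute-force oracles used to freeze expected values. These
## deliberately avoid the code paths they check.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
    library(IRanges)
})

## Poisson-binomial tail by exhaustive 2^n enumeration.
pbEnumSF <- function(k, probs) {
    n <- length(probs)
    if (k <= 0) return(1)
    if (k > n) return(0)
    outcomes <- as.matrix(expand.grid(rep(list(0:1), n)))
    pr <- exp(outcomes %*% log(probs) + (1 - outcomes) %*% log(1 - probs))
    sum(pr[rowSums(outcomes) >= k])
}

## Hypergeometric upper tail P(X >= x), X ~ HG(N, K, n), by explicit
## choose() summation.
hyperTailOracle <- function(x, N, K, n) {
    lo <- max(0L, n - (N - K))
    hi <- min(K, n)
    if (x > hi) return(0)
    i <- max(x, lo):hi
    sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

## All-pairs interval intersection oracle.
bruteOverlap <- function(a, b, minBp = 1L, fracOfA = 0) {
    out <- NULL
    for (i in seq_along(a)) for (j in seq_along(b)) {
        if (as.character(seqnames(a)[i]) != as.character(seqnames(b)[j]))
            next
        ov <- min(end(a)[i], end(b)[j]) - max(start(a)[i], start(b)[j]) + 1L
        if (ov >= minBp && ov >= fracOfA * width(a)[i])
            out <- rbind(out, c(i, j, ov))
    }
    if (is.null(out))
        return(data.frame(aIndex = integer(), bIndex = integer(),
                          overlapBp = integer()))
    data.frame(aIndex = out[, 1], bIndex = out[, 2], overlapBp = out[, 3])
}

## Random GRanges on a toy genome.
randomRanges <- function(n, chroms = c("chr1", "chr2"), maxPos = 10000L,
                         maxLen = 200L) {
    st <- sample.int(maxPos, n, replace = TRUE)
    GRanges(sample(chroms, n, replace = TRUE),
            IRanges(st, st + sample.int(maxLen, n, replace = TRUE) - 1L))
}

## Minimal mutation cohort builder: one row per (sample, chrom, pos).
mutGR <- function(sample_id, chrom, pos) {
    gr <- GRanges(chrom, IRanges(pos, width = 1L))
    mcols(gr)$sample_id <- sample_id
    gr
}

## Minimal CNV record builder.
cnvGR <- function(sample_id, chrom, start, end,
                  direction = "duplication", cohort = "case") {
    gr <- GRanges(chrom, IRanges(start, end))
    mcols(gr) <- DataFrame(sample_id = sample_id,
                           direction = rep(direction, length.out = length(gr)),
                           cohort = rep(cohort, length.out = length(gr)))
    gr
}

## CNVR span builder with case-sample support sets.
cnvrSpans <- function(chrom, start, end, sampleSets,
                      direction = "duplication", min_p = 1e-4) {
    gr <- GRanges(chrom, IRanges(start, end))
    mcols(gr) <- DataFrame(direction = rep(direction, length(gr)),
                           case_samples = CharacterList(sampleSets),
                           min_p = rep(min_p, length.out = length(gr)))
    gr
}

## Interaction table row(s); handles zero-length input.
interDF <- function(chrom1, start1, chrom2, start2, binSize = 5000L,
                    reads = 20L, p = 1e-4) {
    n <- length(chrom1)
    data.frame(chrom1 = chrom1, start1 = start1,
               end1 = start1 + binSize - 1L,
               chrom2 = chrom2, start2 = start2,
               end2 = start2 + binSize - 1L,
               read_count = rep(reads, length.out = n),
               p_value = rep(p, length.out = n))
}
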