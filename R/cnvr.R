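## Case/control CNV-region association.
##
## Stage order: per-base one-sided Fisher association (computed over
## constant-coverage segments, which is exactly equivalent to literal
## per-base testing), run-merging of significant bases into CNVRs,
## uniqueness computation, DBSCAN clustering on (genomic position,
## uniqueness), and IR-score representative selection per cluster.

## Distinct-sample coverage Rle for one chromosome: per-sample intervals
## are reduced first so a sample never counts twice at one base.
sampleCoverage <- function(gr, chrom, chromLen) {
    gr <- gr[as.character(seqnames(gr)) == chrom]
    if (length(gr) == 0L) return(Rle(0L, chromLen))
    bySample <- split(ranges(gr), mcols(gr)$sample_id)
    red <- unlist(IRanges::reduce(bySample), use.names = FALSE)
    coverage(red, width = chromLen)
}

#' One-sided Fisher exact test for case enrichment
#'
#' Upper-tail p-value of the 2x2 table (a = cases covered, b = cases not,
#' c = controls covered, d = controls not): `P(X >= a)` with
#' `X ~ Hypergeometric(N = a+b+c+d, K = a+b, n = a+c)`. Vectorized.
#'
#' @param a,b,c,d table cell counts.
#' @return one-sided p-value(s) in `(0, 1]`.
#' @export
fisherCaseEnrichment <- function(a, b, c, d) {
    if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
    phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Per-base case/control CNV association
#'
#' For every base of `region`, builds the 2x2 table (a = case samples
#' covered, b = cases not covered, c = controls covered, d = controls not
#' covered) restricted to CNVs of the stated direction, and computes the
#' one-sided Fisher exact p-value for enrichment in cases, i.e. the
#' hypergeometric tail `P(X >= a)` with `X ~ HG(N = nCase + nControl,
#' K = nCase, n = a + c)`. Coverage only changes at interval endpoints, so
#' the computation runs over constant-coverage segments; results are
#' identical to a literal per-base loop.
#'
#' @param case,control `GRanges` of CNV records with `sample_id` and
#'   `direction` metadata columns.
#' @param region single `GRanges` interval to scan.
#' @param direction `"deletion"` or `"duplication"`.
#' @param nCase,nControl cohort sizes; default to the number of distinct
#'   samples in each input (pass explicitly if some samples carry no CNV).
#' @return data.frame of constant-coverage segments with columns `chrom`,
#'   `start`, `end` (1-based inclusive), `a`, `b`, `c`, `d`, `p`.
#' @export
perBaseAssociation <- function(case, control, region, direction,
                               nCase = length(unique(mcols(case)$sample_id)),
                               nControl = length(unique(mcols(control)$sample_id))) {
    stopifnot(length(region) == 1L, nCase >= 1L, nControl >= 1L)
    chrom <- as.character(seqnames(region))
    chromLen <- end(region)
    caseD <- case[mcols(case)$direction == direction]
    ctrlD <- control[mcols(control)$direction == direction]
    covCase <- window(sampleCoverage(caseD, chrom, chromLen),
                      start(region), end(region))
    covCtrl <- window(sampleCoverage(ctrlD, chrom, chromLen),
                      start(region), end(region))
    ## refine the two run-length partitions into common segments
    br <- sort(unique(c(0L, cumsum(runLength(covCase)),
                        cumsum(runLength(covCtrl)))))
    segStart <- br[-length(br)] + 1L
    segEnd <- br[-1L]
    a <- as.integer(covCase[segStart])
    cc <- as.integer(covCtrl[segStart])
    if (any(a > nCase) || any(cc > nControl))
        stop("coverage exceeds cohort size; check nCase/nControl")
    p <- fisherCaseEnrichment(a, nCase - a, cc, nControl - cc)
    data.frame(chrom = chrom,
               start = segStart + start(region) - 1L,
               end = segEnd + start(region) - 1L,
               a = a, b = nCase - a, c = cc, d = nControl - cc, p = p)
}

#' Merge significant bases into CNVR spans
#'
#' Maximal runs of consecutive bases with `p < threshold` become CNVR
#' spans; each span records the case samples whose same-direction CNV
#' overlaps it by at least 1 bp and the smallest per-base p-value inside.
#'
#' @param assoc segment table from [perBaseAssociation()].
#' @param case case `GRanges` (for support assignment).
#' @param direction CNV direction of this scan.
#' @param threshold per-base significance threshold (default 0.05).
#' @return `GRanges` with metadata columns `direction`, `case_samples`
#'   (`CharacterList`), `min_p`.
#' @export
mergeSignificantPositions <- function(assoc, case, direction,
                                      threshold = 0.05) {
    sig <- assoc[assoc$p < threshold, , drop = FALSE]
    if (nrow(sig) == 0L) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(direction = character(),
                               case_samples = CharacterList(),
                               min_p = numeric())
        return(gr)
    }
    segs <- GRanges(sig$chrom, IRanges(sig$start, sig$end), p = sig$p)
    spans <- reduce(segs)                      # merges abutting runs only
    hits <- findOverlaps(spans, segs)
    minP <- vapply(split(mcols(segs)$p[subjectHits(hits)],
                         factor(queryHits(hits),
                                levels = seq_along(spans))), min, 0)
    caseD <- case[mcols(case)$direction == direction]
    supp <- lapply(seq_along(spans), function(i) {
        ov <- suppressWarnings(overlapsAny(caseD, spans[i], minoverlap = 1L))
        sort(unique(mcols(caseD)$sample_id[ov]))
    })
    mcols(spans) <- DataFrame(direction = direction,
                              case_samples = CharacterList(supp),
                              min_p = as.numeric(minP))
    spans
}

#' CNVR uniqueness
#'
#' Uniqueness of candidate i is the number of its supporting case samples
#' not supporting any other candidate in the set:
#' `|S_i \ union_{j != i} S_j|`. Computed within one chromosome/direction
#' candidate set.
#'
#' @param cnvrs `GRanges` with a `case_samples` `CharacterList` column.
#' @return `cnvrs` with an integer `uniqueness` metadata column.
#' @export
cnvrUniqueness <- function(cnvrs) {
    sets <- as.list(mcols(cnvrs)$case_samples)
    uniq <- vapply(seq_along(sets), function(i) {
        others <- unique(unlist(sets[-i], use.names = FALSE))
        sum(!(sets[[i]] %in% others))
    }, 0L)
    mcols(cnvrs)$uniqueness <- if (length(sets)) uniq else integer()
    cnvrs
}

## Textbook DBSCAN on a feature matrix (Euclidean distance). A point is
## core when it has >= minPts points (itself included) within eps;
## clusters are the density-connected components; border points join the
## first core cluster that reaches them. Returns 0 for noise.
dbscanLabels <- function(X, eps, minPts) {
    if (eps <= 0) stop("eps must be > 0")
    n <- nrow(X)
    d <- as.matrix(stats::dist(X))
    nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
    core <- lengths(nb) >= minPts
    labels <- integer(n)
    cl <- 0L
    for (i in seq_len(n)) {
        if (labels[i] != 0L || !core[i]) next
        cl <- cl + 1L
        queue <- i
        labels[i] <- cl
        while (length(queue)) {
            q <- queue[1L]; queue <- queue[-1L]
            for (j in nb[[q]]) {
                if (labels[j] == 0L) {
                    labels[j] <- cl
                    if (core[j]) queue <- c(queue, j)
                }
            }
        }
    }
    labels
}

#' Cluster CNVRs on genomic position and uniqueness
#'
#' DBSCAN on the 2-D feature vector (z-scored genomic midpoint, z-scored
#' uniqueness), run per chromosome and direction by the caller. Noise
#' points receive fresh singleton cluster ids so that every CNVR remains
#' selectable downstream.
#'
#' @param cnvrs `GRanges` with a `uniqueness` metadata column.
#' @param eps DBSCAN neighborhood radius in z-score units (default 0.5).
#' @param minPts minimum neighborhood size for a core point (default 1).
#' @return `cnvrs` with an integer `cluster_id` metadata column.
#' @export
clusterCnvrs <- function(cnvrs, eps = 0.5, minPts = 1L) {
    if (length(cnvrs) == 0L) {
        mcols(cnvrs)$cluster_id <- integer()
        return(cnvrs)
    }
    zscore <- function(x) {
        s <- stats::sd(x)
        if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
    }
    mid <- (start(cnvrs) + end(cnvrs)) / 2
    X <- cbind(zscore(mid), zscore(as.numeric(mcols(cnvrs)$uniqueness)))
    labels <- dbscanLabels(X, eps, minPts)
    noise <- labels == 0L
    if (any(noise))
        labels[noise] <- max(labels) + seq_len(sum(noise))
    mcols(cnvrs)$cluster_id <- labels
    cnvrs
}

#' IR-score computation and representative selection
#'
#' The independence score of candidate i within its cluster is
#' `IR(i) = |S_i| - mean_{j != i} |S_i intersect S_j|`: many supporting
#' cases, little co-occurrence with cluster neighbors. A singleton
#' cluster scores `|S_i|`. The representative is the IR maximizer; ties
#' break toward larger support, then leftmost start.
#'
#' @param cnvrs `GRanges` with `case_samples` and `cluster_id` columns.
#' @return `cnvrs` with numeric `ir_score` and logical
#'   `is_representative` metadata columns.
#' @export
irScoreSelect <- function(cnvrs) {
    n <- length(cnvrs)
    ir <- numeric(n)
    rep_ <- logical(n)
    sets <- as.list(mcols(cnvrs)$case_samples)
    for (cl in unique(mcols(cnvrs)$cluster_id)) {
        idx <- which(mcols(cnvrs)$cluster_id == cl)
        for (i in idx) {
            others <- setdiff(idx, i)
            ir[i] <- if (length(others) == 0L) length(sets[[i]])
                     else length(sets[[i]]) -
                         mean(vapply(others, function(j)
                             length(intersect(sets[[i]], sets[[j]])), 0))
        }
        ord <- order(-ir[idx], -lengths(sets[idx]), start(cnvrs[idx]))
        rep_[idx[ord[1L]]] <- TRUE
    }
    mcols(cnvrs)$ir_score <- ir
    mcols(cnvrs)$is_representative <- rep_
    cnvrs
}

#' Case-enriched CNVR discovery (full scan)
#'
#' Runs the complete association pipeline for one CNV direction:
#' per-base Fisher association per chromosome, run-merging into CNVRs,
#' uniqueness, DBSCAN clustering, and IR-score representative selection.
#' Deletions and duplications are analyzed fully independently; call once
#' per direction.
#'
#' @param case,control `GRanges` of CNV records (`sample_id`,
#'   `direction` metadata columns).
#' @param chromSizes named vector of chromosome lengths.
#' @param direction `"deletion"` or `"duplication"`.
#' @param pThreshold per-base significance threshold (default 0.05).
#' @param eps,minPts DBSCAN parameters (defaults 0.5 / 1).
#' @param nCase,nControl cohort sizes (defaults: distinct samples in each
#'   input).
#' @return a [CnvrSet-class]; see [representatives()] and
#'   [cnvrCandidates()].
#' @export
runPeakCnv <- function(case, control, chromSizes, direction,
                       pThreshold = 0.05, eps = 0.5, minPts = 1L,
                       nCase = length(unique(mcols(case)$sample_id)),
                       nControl = length(unique(mcols(control)$sample_id))) {
    if (length(case) == 0L || length(control) == 0L)
        stop("both cohorts must contain CNV records")
    perChrom <- lapply(names(chromSizes), function(chrom) {
        region <- GRanges(chrom, IRanges(1L, chromSizes[[chrom]]))
        assoc <- perBaseAssociation(case, control, region, direction,
                                    nCase, nControl)
        spans <- mergeSignificantPositions(assoc, case, direction,
                                           pThreshold)
        if (length(spans) == 0L) return(NULL)
        spans <- cnvrUniqueness(spans)
        spans <- clusterCnvrs(spans, eps, minPts)
        irScoreSelect(spans)
    })
    perChrom <- perChrom[!vapply(perChrom, is.null, TRUE)]
    cnvrs <- if (length(perChrom))
        suppressWarnings(do.call(c, perChrom))
    else {
        g <- GRanges()
        mcols(g) <- DataFrame(direction = character(),
                              case_samples = CharacterList(),
                              min_p = numeric(), uniqueness = integer(),
                              cluster_id = integer(), ir_score = numeric(),
                              is_representative = logical())
        g
    }
    ## make cluster ids globally unique across chromosomes
    if (length(cnvrs)) {
        key <- paste(as.character(seqnames(cnvrs)),
                     mcols(cnvrs)$cluster_id)
        mcols(cnvrs)$cluster_id <- as.integer(factor(key, unique(key)))
    }
    new("CnvrSet", cnvrs = cnvrs, nCase = as.integer(nCase),
        nControl = as.integer(nControl), pThreshold = pThreshold)
}
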