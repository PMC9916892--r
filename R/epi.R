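## Enhancer-promoter interaction (EPI) calling from significant Hi-C
## contacts and H3K27ac peaks.
##
## Interactions are plain data.frames with 1-based inclusive anchor
## coordinates (chrom1, start1, end1, chrom2, start2, end2, read_count,
## p_value, optionally cell_line); BEDPE 0-based conventions are converted
## on read/write. Anchors are normalized so anchor1 sorts before anchor2.

interactionCols <- c("chrom1", "start1", "end1", "chrom2", "start2",
                     "end2", "read_count", "p_value")

#' Read a Hi-C interaction table
#'
#' Tab-separated, BEDPE-like, with header `chrom1, start1, end1, chrom2,
#' start2, end2, read_count, p_value` (and optionally `cell_line`);
#' anchor starts are 0-based half-open as in BEDPE.
#'
#' @param path path to the table.
#' @return normalized interaction data.frame (1-based coordinates).
#' @export
readInteractions <- function(path) {
    df <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    if (!all(interactionCols %in% names(df)))
        stop("interaction table must have columns: ",
             paste(interactionCols, collapse = ", "))
    df$chrom1 <- normalizeChrom(df$chrom1)
    df$chrom2 <- normalizeChrom(df$chrom2)
    df$start1 <- df$start1 + 1L
    df$start2 <- df$start2 + 1L
    normalizeInteractions(df)
}

#' Write a Hi-C interaction table (BEDPE-like, 0-based starts)
#'
#' @param df interaction data.frame.
#' @param path output path.
#' @return invisibly, the path written.
#' @export
writeInteractions <- function(df, path) {
    out <- df
    out$start1 <- out$start1 - 1L
    out$start2 <- out$start2 - 1L
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Normalize interaction anchor order
#'
#' Ensures anchor1 sorts before anchor2 (chromosome, then start) and that
#' both anchors share one bin width.
#'
#' @param df interaction data.frame (1-based coordinates).
#' @return normalized data.frame.
#' @export
normalizeInteractions <- function(df) {
    if (nrow(df) == 0L) return(df)
    w1 <- df$end1 - df$start1 + 1L
    w2 <- df$end2 - df$start2 + 1L
    if (length(unique(c(w1, w2))) != 1L)
        stop("all anchors must share one bin width")
    swap <- df$chrom2 < df$chrom1 |
        (df$chrom2 == df$chrom1 & df$start2 < df$start1)
    if (any(swap)) {
        tmp <- df[swap, c("chrom1", "start1", "end1")]
        df[swap, c("chrom1", "start1", "end1")] <-
            df[swap, c("chrom2", "start2", "end2")]
        df[swap, c("chrom2", "start2", "end2")] <- tmp
    }
    rownames(df) <- NULL
    df
}

binWidthOf <- function(df) {
    if (nrow(df) == 0L) return(NA_integer_)
    df$end1[1L] - df$start1[1L] + 1L
}

#' Filter significant Hi-C interactions
#'
#' Keeps cis pairs with `p_value < pMax`, `read_count >= minReads`, and
#' anchor-start distance strictly between `minDist` and `maxDist`. Both
#' distance bounds are strict, so two adjacent 5 kb bins (distance
#' exactly 5000) are dropped. Idempotent.
#'
#' @param df interaction data.frame.
#' @param pMax significance threshold (default 0.01).
#' @param minReads minimum read count (default 10).
#' @param minDist,maxDist strict bounds on `|start2 - start1|` in bp
#'   (defaults 5 kb and 10 Mb).
#' @return filtered data.frame.
#' @export
filterInteractions <- function(df, pMax = 0.01, minReads = 10L,
                               minDist = 5000L, maxDist = 1e7) {
    df <- normalizeInteractions(df)
    if (nrow(df) == 0L) return(df)
    dist <- abs(df$start2 - df$start1)
    keep <- df$chrom1 == df$chrom2 & df$p_value < pMax &
        df$read_count >= minReads & dist > minDist & dist < maxDist
    out <- df[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Merge two Hi-C replicates
#'
#' Union over normalized anchor pairs; read counts are summed and the
#' p-value of a pair present in both replicates is the smaller one
#' (flagged in a `merged` column).
#'
#' @param rep1,rep2 interaction data.frames with equal bin width.
#' @return merged data.frame.
#' @export
mergeReplicates <- function(rep1, rep2) {
    rep1 <- normalizeInteractions(rep1)
    rep2 <- normalizeInteractions(rep2)
    w1 <- binWidthOf(rep1); w2 <- binWidthOf(rep2)
    if (!is.na(w1) && !is.na(w2) && w1 != w2)
        stop("replicate bin widths differ: ", w1, " vs ", w2)
    key <- function(d) paste(d$chrom1, d$start1, d$chrom2, d$start2,
                             sep = ":")
    k1 <- key(rep1); k2 <- key(rep2)
    shared <- intersect(k1, k2)
    out <- rbind(rep1[, intersect(names(rep1), names(rep2))],
                 rep2[!(k2 %in% shared),
                      intersect(names(rep1), names(rep2))])
    ko <- key(out)
    out$merged <- ko %in% shared
    for (s in shared) {
        i <- which(ko == s)
        j <- which(k2 == s)
        out$read_count[i] <- out$read_count[i] + sum(rep2$read_count[j])
        out$p_value[i] <- min(out$p_value[i], rep2$p_value[j])
    }
    out <- out[order(out$chrom1, out$start1, out$chrom2, out$start2), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

anchorRanges <- function(df, side) {
    GRanges(df[[paste0("chrom", side)]],
            IRanges(df[[paste0("start", side)]],
                    df[[paste0("end", side)]]))
}

#' Annotate interaction anchors with genes
#'
#' A gene is assigned to an anchor when their overlap is at least
#' `minFrac` of the smaller of the two widths, so short genes and bins
#' are treated symmetrically (e.g. with 5 kb anchors and `minFrac = 0.1`,
#' a 400 bp overlap fails and a 500 bp overlap passes).
#'
#' @param df interaction data.frame.
#' @param genes gene `GRanges`.
#' @param minFrac minimum overlap fraction of `min(gene width, anchor
#'   width)` (default 0.10).
#' @return data.frame with `row` (interaction row), `side` (1/2),
#'   `anchor` (chrom:start-end, 1-based), `symbol`, `biotype`,
#'   `overlapBp`.
#' @export
annotateAnchorGenes <- function(df, genes, minFrac = 0.10) {
    out <- lapply(1:2, function(side) {
        anc <- anchorRanges(df, side)
        hits <- intersectIntervals(anc, genes)
        if (nrow(hits) == 0L) return(NULL)
        need <- pmin(width(anc)[hits$aIndex],
                     width(genes)[hits$bIndex]) * minFrac
        hits <- hits[hits$overlapBp >= need, , drop = FALSE]
        if (nrow(hits) == 0L) return(NULL)
        data.frame(row = hits$aIndex, side = side,
                   anchor = sprintf("%s:%d-%d",
                                    as.character(seqnames(anc))[hits$aIndex],
                                    start(anc)[hits$aIndex],
                                    end(anc)[hits$aIndex]),
                   symbol = mcols(genes)$symbol[hits$bIndex],
                   biotype = mcols(genes)$biotype[hits$bIndex],
                   overlapBp = hits$overlapBp)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        out <- data.frame(row = integer(), side = integer(),
                          anchor = character(), symbol = character(),
                          biotype = character(), overlapBp = integer())
    out
}

#' Promoter regions of protein-coding genes
#'
#' Strand-aware TSS +/- window (defaults 2 kb each side), clipped to
#' chromosome bounds when sizes are supplied.
#'
#' @param genes gene `GRanges`; only `protein_coding` records are used.
#' @param upstream,downstream window sizes in bp (defaults 2000).
#' @param chromSizes optional named length vector for clipping.
#' @return `GRanges` of promoters with a `symbol` metadata column.
#' @export
promoterRegions <- function(genes, upstream = 2000L, downstream = 2000L,
                            chromSizes = NULL) {
    pc <- genes[mcols(genes)$biotype == "protein_coding"]
    prom <- suppressWarnings(
        promoters(pc, upstream = upstream, downstream = downstream))
    start(prom) <- pmax(start(prom), 1L)
    if (!is.null(chromSizes)) {
        lens <- chromSizes[as.character(seqnames(prom))]
        end(prom) <- pmin(end(prom), as.integer(lens))
    }
    mcols(prom) <- DataFrame(symbol = mcols(pc)$symbol)
    prom
}

#' Call enhancer-promoter interactions
#'
#' For each (already filtered) interaction and each orientation, an EPI
#' is emitted when the enhancer-side anchor overlaps at least one
#' H3K27ac peak (>= 1 bp) and the promoter-side anchor overlaps at least
#' one protein-coding promoter. Both orientations of one interaction may
#' qualify and are then both emitted. Target genes are the union of
#' symbols over all promoters overlapping the promoter anchor.
#'
#' @param df filtered interaction data.frame.
#' @param peaks `GRanges` of H3K27ac peaks.
#' @param proms promoter `GRanges` from [promoterRegions()].
#' @return data.frame: the interaction columns plus `enhancer_side` (1 or
#'   2), `target_genes` (semicolon-joined sorted symbols) and `n_peaks`.
#' @export
callEpis <- function(df, peaks, proms) {
    empty <- cbind(df[0, , drop = FALSE],
                   data.frame(enhancer_side = integer(),
                              target_genes = character(),
                              n_peaks = integer()))
    if (nrow(df) == 0L) return(empty)
    a1 <- anchorRanges(df, 1); a2 <- anchorRanges(df, 2)
    peakHits1 <- countOverlaps(a1, peaks, minoverlap = 1L)
    peakHits2 <- countOverlaps(a2, peaks, minoverlap = 1L)
    promHits <- function(anc) {
        h <- findOverlaps(anc, proms, minoverlap = 1L)
        split(mcols(proms)$symbol[subjectHits(h)],
              factor(queryHits(h), levels = seq_along(anc)))
    }
    genes1 <- promHits(a1); genes2 <- promHits(a2)
    orient <- function(enhSide) {
        pk <- if (enhSide == 1L) peakHits1 else peakHits2
        tg <- if (enhSide == 1L) genes2 else genes1
        ok <- pk >= 1L & lengths(tg) > 0L
        if (!any(ok)) return(NULL)
        cbind(df[ok, , drop = FALSE],
              data.frame(enhancer_side = enhSide,
                         target_genes = vapply(tg[ok], function(g)
                             paste(sort(unique(g)), collapse = ";"), ""),
                         n_peaks = pk[ok]))
    }
    out <- rbind(orient(1L), orient(2L))
    if (is.null(out)) return(empty)
    out <- out[order(out$chrom1, out$start1, out$start2,
                     out$enhancer_side), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Condition-specific EPIs
#'
#' EPIs of the cancer condition whose normalized anchor bin pair does not
#' occur among the normal condition's EPIs. Identity is the exact bin
#' pair; target genes play no role in the comparison.
#'
#' @param cancer,normal EPI data.frames from [callEpis()] with equal bin
#'   width.
#' @return subset of `cancer`.
#' @export
conditionSpecificEpis <- function(cancer, normal) {
    wc <- binWidthOf(cancer); wn <- binWidthOf(normal)
    if (!is.na(wc) && !is.na(wn) && wc != wn)
        stop("bin widths differ between conditions: ", wc, " vs ", wn)
    key <- function(d) paste(d$chrom1, d$start1, d$chrom2, d$start2,
                             sep = ":")
    out <- cancer[!(key(cancer) %in% key(normal)), , drop = FALSE]
    rownames(out) <- NULL
    out
}
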