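## Core coordinate conventions and readers/writers.
##
## Internal convention: everything lives in GRanges, 1-based closed, as is
## standard in Bioconductor. BED/BEDPE (0-based half-open) and 1-based text
## positions are converted at the I/O boundary, never downstream.

#' Normalize chromosome names to the "chr"-prefixed form
#'
#' @param x character vector of chromosome names.
#' @return character vector with a `chr` prefix added where absent.
#' @export
#' @examples
#' normalizeChrom(c("1", "chrX", "MT"))
normalizeChrom <- function(x) {
    x <- as.character(x)
    ifelse(grepl("^chr", x), x, paste0("chr", x))
}

#' Read a two-column chrom.sizes file
#'
#' @param path path to a tab-separated file with chromosome name and length.
#' @return named integer vector of chromosome lengths (all > 0).
#' @export
readChromSizes <- function(path) {
    df <- read.table(path, sep = "\t", header = FALSE,
                     col.names = c("chrom", "size"),
                     colClasses = c("character", "numeric"))
    sizes <- setNames(as.integer(df$size), normalizeChrom(df$chrom))
    if (any(is.na(sizes)) || any(sizes <= 0))
        stop("chrom.sizes: all lengths must be positive integers")
    sizes
}

## Seqinfo from a named chromosome-length vector.
asSeqinfo <- function(chromSizes) {
    Seqinfo(seqnames = names(chromSizes),
            seqlengths = as.integer(chromSizes))
}

#' Read a BED file into GRanges
#'
#' Reads BED3/BED6 with native BED semantics: 0-based half-open input
#' coordinates become 1-based closed GRanges; `track`, `browser` and `#`
#' comment lines are skipped. Zero-width records (`end <= start`) and
#' non-integer coordinates are rejected with the offending line number,
#' which is stricter than lenient importers and intentional: downstream
#' stages assume every interval has positive width.
#'
#' @param path path to a BED file.
#' @return `GRanges`; columns 4-5 (name, score) are kept as metadata
#'   columns when present, column 6 populates the strand.
#' @seealso [writeBed()] for the inverse conversion.
#' @export
readBed <- function(path) {
    if (!file.exists(path)) stop("BED file not found: ", path)
    lines <- readLines(path)
    keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
    idx <- which(keep)
    if (length(idx) == 0L) return(GRanges())
    fields <- strsplit(lines[idx], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("BED parse error at line ", idx[which(nf < 3L)[1L]],
             ": fewer than 3 tab-separated columns")
    chrom <- normalizeChrom(vapply(fields, `[`, "", 1L))
    startRaw <- vapply(fields, `[`, "", 2L)
    endRaw <- vapply(fields, `[`, "", 3L)
    start0 <- suppressWarnings(as.integer(startRaw))
    end0 <- suppressWarnings(as.integer(endRaw))
    bad <- is.na(start0) | is.na(end0) |
        startRaw != as.character(start0) | endRaw != as.character(end0)
    if (any(bad))
        stop("BED parse error at line ", idx[which(bad)[1L]],
             ": non-integer coordinates")
    if (any(start0 < 0L))
        stop("BED parse error at line ", idx[which(start0 < 0L)[1L]],
             ": negative start")
    if (any(end0 <= start0))
        stop("BED parse error at line ", idx[which(end0 <= start0)[1L]],
             ": end must exceed start (zero-width interval)")
    gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
    if (all(nf >= 4L)) mcols(gr)$name <- vapply(fields, `[`, "", 4L)
    if (all(nf >= 5L))
        mcols(gr)$score <- suppressWarnings(
            as.numeric(vapply(fields, `[`, "", 5L)))
    if (all(nf >= 6L)) {
        st <- vapply(fields, `[`, "", 6L)
        st[!st %in% c("+", "-")] <- "*"
        strand(gr) <- st
    }
    gr
}

#' Write GRanges to a BED file
#'
#' Emits BED3, or BED6 when `name`/`score` metadata columns or strand
#' information are present. Coordinates are converted back to the 0-based
#' half-open BED convention so that `writeBed(readBed(f))` reproduces a
#' canonical 3-column file byte-identically.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return invisibly, the path written.
#' @export
writeBed <- function(gr, path) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L,
                     end = end(gr),
                     stringsAsFactors = FALSE)
    hasName <- "name" %in% names(mcols(gr))
    hasScore <- "score" %in% names(mcols(gr))
    hasStrand <- any(strand(gr) != "*")
    if (hasName || hasScore || hasStrand) {
        df$name <- if (hasName) as.character(mcols(gr)$name) else "."
        df$score <- if (hasScore) mcols(gr)$score else 0
        df$strand <- sub("\\*", ".", as.character(strand(gr)))
    }
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Intersect two interval sets with minimum-overlap constraints
#'
#' Returns every same-chromosome pair overlapping by at least
#' `minOverlapBp` base pairs and, additionally, by at least
#' `minOverlapFracOfA` of the width of the first interval. The fractional
#' constraint is asymmetric (computed on `a`), mirroring `bedtools
#' intersect -f`.
#'
#' @param a,b `GRanges` objects.
#' @param minOverlapBp minimum overlap in bp (default 1).
#' @param minOverlapFracOfA minimum overlap as a fraction of `width(a)`,
#'   in `[0, 1]`.
#' @return data.frame with columns `aIndex`, `bIndex`, `overlapBp`.
#' @export
intersectIntervals <- function(a, b, minOverlapBp = 1L,
                               minOverlapFracOfA = 0) {
    stopifnot(minOverlapFracOfA >= 0, minOverlapFracOfA <= 1)
    if (length(a) == 0L || length(b) == 0L)
        return(data.frame(aIndex = integer(), bIndex = integer(),
                          overlapBp = integer()))
    hits <- suppressWarnings(findOverlaps(a, b, minoverlap = 1L))
    if (length(hits) == 0L)
        return(data.frame(aIndex = integer(), bIndex = integer(),
                          overlapBp = integer()))
    ov <- width(pintersect(a[queryHits(hits)], b[subjectHits(hits)]))
    keep <- ov >= minOverlapBp &
        ov >= minOverlapFracOfA * width(a[queryHits(hits)])
    data.frame(aIndex = queryHits(hits)[keep],
               bIndex = subjectHits(hits)[keep],
               overlapBp = ov[keep])
}

#' Load a GWAS SNP table and keep genome-wide significant SNPs
#'
#' The input is a tab-separated table with header columns `rsid`, `chrom`,
#' `pos` (1-based) and `pvalue`. Only SNPs with p-value strictly below
#' `pThreshold` (default the genome-wide significance level 5e-8) are
#' retained.
#'
#' @param path path to the table.
#' @param pThreshold strict upper bound on the association p-value.
#' @return width-1 `GRanges` with metadata columns `rsid` and `p_value`.
#' @export
loadGwasSnps <- function(path, pThreshold = 5e-8) {
    df <- read.table(path, sep = "\t", header = TRUE,
                     colClasses = "character")
    need <- c("rsid", "chrom", "pos", "pvalue")
    if (!all(need %in% names(df)))
        stop("GWAS table must have columns: ", paste(need, collapse = ", "))
    p <- suppressWarnings(as.numeric(df$pvalue))
    if (any(is.na(p)))
        stop("GWAS parse error: non-numeric p-value at row ",
             which(is.na(p))[1L])
    pos <- suppressWarnings(as.integer(df$pos))
    if (any(is.na(pos)))
        stop("GWAS parse error: non-integer position at row ",
             which(is.na(pos))[1L])
    keep <- p < pThreshold
    gr <- GRanges(normalizeChrom(df$chrom[keep]),
                  IRanges(pos[keep], width = 1L))
    mcols(gr)$rsid <- df$rsid[keep]
    mcols(gr)$p_value <- p[keep]
    gr
}

#' Minimal VCF reader for replication checks
#'
#' Wraps `VariantAnnotation::readVcf()` and flattens to one record per ALT
#' allele. Depth (DP) is taken from the INFO field when declared, else
#' from the FORMAT field of the first sample; records without DP carry
#' `NA` (kept, flagged) so that quality filtering can drop them
#' explicitly.
#'
#' @param path path to a VCF 4.x text file.
#' @return `GRanges` with metadata columns `ref`, `alt`, `qual`, `dp`.
#' @export
readVcfMinimal <- function(path) {
    v <- VariantAnnotation::readVcf(path)
    ve <- VariantAnnotation::expand(v)
    gr <- granges(SummarizedExperiment::rowRanges(ve))
    names(gr) <- NULL
    dp <- rep(NA_integer_, length(gr))
    infoDp <- tryCatch(VariantAnnotation::info(ve)$DP, error = function(e) NULL)
    if (!is.null(infoDp)) {
        dp <- as.integer(infoDp)
    } else {
        genoDp <- tryCatch(VariantAnnotation::geno(ve)$DP,
                           error = function(e) NULL)
        if (!is.null(genoDp) && ncol(genoDp) >= 1L)
            dp <- as.integer(genoDp[, 1L])
    }
    mcols(gr) <- DataFrame(
        ref = as.character(VariantAnnotation::ref(ve)),
        alt = as.character(VariantAnnotation::alt(ve)),
        qual = VariantAnnotation::qual(ve),
        dp = dp)
    seqlevels(gr) <- normalizeChrom(seqlevels(gr))
    gr
}

#' Read a GMT gene-set file
#'
#' @param path path to a GMT file (set name, description, then gene
#'   symbols, tab-separated).
#' @return named list of character vectors of upper-cased, de-duplicated
#'   gene symbols; each element carries the set description as attribute
#'   `"description"`.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) return(structure(list(), names = character()))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("GMT parse error at line ", which(nf < 3L)[1L],
             ": fewer than 3 tab-separated fields")
    sets <- lapply(fields, function(f) {
        genes <- unique(toupper(f[-(1:2)]))
        genes <- genes[nzchar(genes)]
        structure(genes, description = f[2L])
    })
    names(sets) <- vapply(fields, `[`, "", 1L)
    sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors (optionally carrying a
#'   `"description"` attribute, as returned by [readGmt()]).
#' @param path output path.
#' @return invisibly, the path written.
#' @export
writeGmt <- function(sets, path) {
    lines <- vapply(seq_along(sets), function(i) {
        desc <- attr(sets[[i]], "description")
        if (is.null(desc)) desc <- "na"
        paste(c(names(sets)[i], desc, sets[[i]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a per-sample somatic mutation table
#'
#' @param path tab-separated table with header `sample_id`, `chrom`,
#'   `pos` (1-based).
#' @return width-1 `GRanges` with a `sample_id` metadata column.
#' @export
readMutationTable <- function(path) {
    df <- read.table(path, sep = "\t", header = TRUE,
                     colClasses = c(sample_id = "character",
                                    chrom = "character", pos = "integer"))
    gr <- GRanges(normalizeChrom(df$chrom), IRanges(df$pos, width = 1L))
    mcols(gr)$sample_id <- df$sample_id
    gr
}

#' Read a per-sample CNV table
#'
#' @param path tab-separated table with header `sample_id`, `chrom`,
#'   `start` (1-based), `end` (inclusive), `direction`
#'   (`deletion`/`duplication`), `cohort` (`case`/`control`).
#' @return `GRanges` with metadata columns `sample_id`, `direction`,
#'   `cohort`.
#' @export
readCnvTable <- function(path) {
    df <- read.table(path, sep = "\t", header = TRUE,
                     colClasses = c(sample_id = "character",
                                    chrom = "character", start = "integer",
                                    end = "integer", direction = "character",
                                    cohort = "character"))
    if (!all(df$direction %in% c("deletion", "duplication")))
        stop("CNV direction must be 'deletion' or 'duplication'")
    if (!all(df$cohort %in% c("case", "control")))
        stop("CNV cohort must be 'case' or 'control'")
    gr <- GRanges(normalizeChrom(df$chrom), IRanges(df$start, df$end))
    mcols(gr) <- DataFrame(sample_id = df$sample_id,
                           direction = df$direction, cohort = df$cohort)
    gr
}
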