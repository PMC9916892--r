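## Reference gene list construction and variant-to-gene annotation.

geneBiotypes <- c("protein_coding", "lncRNA", "miRNA", "snoRNA",
                  "pseudogene", "other_ncRNA")

#' Construct a gene GRanges
#'
#' @param chrom,start,end,strand coordinates (1-based inclusive) and
#'   strand (`+`/`-`).
#' @param symbol gene symbols.
#' @param biotype one of `protein_coding`, `lncRNA`, `miRNA`, `snoRNA`,
#'   `pseudogene`, `other_ncRNA`.
#' @param source annotation source label (e.g. `fantom5`, `ensembl`,
#'   `gencode`).
#' @return `GRanges` with metadata columns `symbol`, `biotype`, `source`.
#' @export
makeGenes <- function(chrom, start, end, strand, symbol, biotype,
                      source = "fantom5") {
    if (!all(biotype %in% geneBiotypes))
        stop("unknown biotype; allowed: ",
             paste(geneBiotypes, collapse = ", "))
    gr <- GRanges(normalizeChrom(chrom), IRanges(start, end),
                  strand = strand)
    mcols(gr) <- DataFrame(symbol = symbol, biotype = biotype,
                           source = rep(source, length.out = length(gr)))
    gr
}

#' Transcription start sites of genes
#'
#' TSS is the start of the span on the plus strand and the end on the
#' minus strand (1-based).
#'
#' @param genes gene `GRanges`.
#' @return integer vector of TSS positions.
#' @export
tssOf <- function(genes) {
    ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
}

#' Read a gene annotation table
#'
#' BED6-plus-biotype TSV: chrom, start (0-based), end, symbol, score,
#' strand, biotype, and optionally source.
#'
#' @param path path to the table (no header).
#' @param source source label used when the table has no 8th column.
#' @return gene `GRanges` as from [makeGenes()].
#' @export
readGeneTable <- function(path, source = "fantom5") {
    df <- read.table(path, sep = "\t", header = FALSE,
                     colClasses = "character")
    if (ncol(df) < 7L)
        stop("gene table needs >= 7 columns (BED6 + biotype)")
    makeGenes(df[[1L]], as.integer(df[[2L]]) + 1L, as.integer(df[[3L]]),
              df[[6L]], df[[4L]], df[[7L]],
              if (ncol(df) >= 8L) df[[8L]] else source)
}

#' Merge gene annotation sources into one reference list
#'
#' The first source is the backbone: all its genes are kept. A gene from
#' the second source is added only when its symbol (case-insensitive) is
#' absent so far; the third source likewise. Provenance is recorded in
#' the `source` metadata column.
#'
#' @param fantom,ensembl,gencode gene `GRanges` in precedence order.
#' @return merged gene `GRanges` with unique symbols.
#' @export
buildReferenceGenes <- function(fantom, ensembl = GRanges(),
                                gencode = GRanges()) {
    merged <- fantom
    for (src in list(ensembl, gencode)) {
        if (length(src) == 0L) next
        seen <- toupper(mcols(merged)$symbol)
        add <- src[!(toupper(mcols(src)$symbol) %in% seen)]
        ## a source may repeat a symbol internally; keep its first record
        add <- add[!duplicated(toupper(mcols(add)$symbol))]
        merged <- suppressWarnings(c(merged, add))
    }
    merged
}

#' Overlap variants with the reference gene list
#'
#' A hit is any overlap of at least 1 bp between a variant span and a
#' gene body (the full annotated span; promoter logic lives in the EPI
#' stage). A variant may hit several genes; variants with no hit are
#' reported as non-annotated by [summarizeAnnotation()].
#'
#' @param variants `GRanges` with metadata columns `class` (e.g.
#'   `gwas_snp`, `hotspot`, `cnvr_dup`, `cnvr_del`) and optionally `id`.
#' @param genes gene `GRanges` from [buildReferenceGenes()].
#' @return data.frame with one row per (variant, gene) hit: `variantIndex`,
#'   `variantId`, `class`, `symbol`, `biotype`, `overlapBp`.
#' @export
annotateVariants <- function(variants, genes) {
    ids <- if ("id" %in% names(mcols(variants))) mcols(variants)$id
           else paste0("v", seq_along(variants))
    hits <- intersectIntervals(variants, genes)
    data.frame(variantIndex = hits$aIndex,
               variantId = ids[hits$aIndex],
               class = mcols(variants)$class[hits$aIndex],
               symbol = mcols(genes)$symbol[hits$bIndex],
               biotype = mcols(genes)$biotype[hits$bIndex],
               overlapBp = hits$overlapBp)
}

#' Summarize variant-gene annotation per variant class
#'
#' For each variant class: the fraction of variants hitting any gene
#' (annotated), the split of annotated variants into protein-coding vs
#' purely non-coding association (a variant counts as protein-coding
#' associated when ANY hit gene is protein-coding), and a biotype
#' histogram over the distinct non-coding genes hit.
#'
#' @param hits hit table from [annotateVariants()].
#' @param variants the variant `GRanges` given to [annotateVariants()].
#' @return named list (per class) of lists with `nVariants`,
#'   `annotatedFraction`, `codingFraction` (of annotated variants),
#'   `ncBiotypeCounts` (table over distinct non-coding genes hit).
#' @export
summarizeAnnotation <- function(hits, variants) {
    classes <- unique(as.character(mcols(variants)$class))
    out <- lapply(classes, function(cl) {
        idx <- which(mcols(variants)$class == cl)
        h <- hits[hits$class == cl, , drop = FALSE]
        annotated <- unique(h$variantIndex)
        codingVar <- unique(h$variantIndex[h$biotype == "protein_coding"])
        nc <- unique(h[h$biotype != "protein_coding",
                       c("symbol", "biotype")])
        list(nVariants = length(idx),
             annotatedFraction = length(annotated) / max(1L, length(idx)),
             codingFraction = if (length(annotated))
                 length(codingVar) / length(annotated) else NA_real_,
             ncBiotypeCounts = table(nc$biotype))
    })
    names(out) <- classes
    out
}
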