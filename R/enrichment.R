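## Hypergeometric over-representation analysis (ORA) of gene lists
## against GMT gene sets.

#' Hypergeometric over-representation test
#'
#' For each gene set, with universe size `N`, set size `K` (after
#' intersection with the universe), query size `n` (after dropping query
#' genes outside the universe, with a warning) and overlap `x`, computes
#' the exact upper-tail p-value `P(X >= x)` for
#' `X ~ Hypergeometric(N, K, n)` and the fold enrichment
#' `(x/n) / (K/N)`. Benjamini-Hochberg q-values are included; the raw
#' p-value with the conventional 0.05 cutoff remains the primary report
#' filter (apply via `pCutoff`).
#'
#' @param query character vector of query gene symbols.
#' @param geneSets named list of character vectors (see [readGmt()]).
#' @param universe character vector of universe gene symbols.
#' @param pCutoff optional raw-p report filter (e.g. 0.05); `NULL`
#'   returns all sets.
#' @return data.frame sorted by p-value: `set`, `description`, `N`, `K`,
#'   `n`, `x`, `fold`, `p_value`, `q_value`, plus `overlapGenes`
#'   (semicolon-joined).
#' @export
hypergeometricOra <- function(query, geneSets, universe,
                              pCutoff = NULL) {
    universe <- unique(toupper(universe))
    N <- length(universe)
    if (N == 0L) stop("empty gene universe")
    query <- unique(toupper(query))
    outside <- setdiff(query, universe)
    if (length(outside))
        warning(length(outside),
                " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
    n <- length(query)
    rows <- lapply(seq_along(geneSets), function(i) {
        set <- intersect(unique(toupper(geneSets[[i]])), universe)
        K <- length(set)
        ov <- intersect(query, set)
        x <- length(ov)
        p <- phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
        fold <- if (x == 0L || n == 0L || K == 0L) 0
                else (x / n) / (K / N)
        desc <- attr(geneSets[[i]], "description")
        data.frame(set = names(geneSets)[i],
                   description = if (is.null(desc)) "" else desc,
                   N = N, K = K, n = n, x = x, fold = fold, p_value = p,
                   overlapGenes = paste(sort(ov), collapse = ";"))
    })
    out <- do.call(rbind, rows)
    out$q_value <- bhAdjust(out$p_value)
    out <- out[order(out$p_value, out$set), , drop = FALSE]
    rownames(out) <- NULL
    if (!is.null(pCutoff)) out <- out[out$p_value < pCutoff, ,
                                      drop = FALSE]
    out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (delegates to `stats::p.adjust`).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}
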