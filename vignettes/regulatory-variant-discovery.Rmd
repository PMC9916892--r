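---
title: "Discovering putative regulatory genomic variants with regvar"
author: "regvar authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering putative regulatory genomic variants with regvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(regvar)
  library(GenomicRanges)
})
```

# The problem

Most genomic variants observed in tumors fall outside protein-coding
sequence, and a variant need not sit inside a gene to change its
expression: it can disrupt an enhancer that contacts the gene's promoter
through chromatin looping. `regvar` implements an integrative pipeline
that nominates such regulatory variants in a case/control cancer cohort
by combining four evidence types:

1. recurrently mutated windows of the genome (somatic hotspots),
2. copy-number regions enriched in cases over controls (CNVRs),
3. genome-wide significant GWAS SNPs, and
4. enhancer–promoter interactions (EPIs) called from significant Hi-C
   contacts supported by H3K27ac peaks.

A variant becomes a candidate only when it overlaps the **enhancer**
side of a cancer-specific EPI; the genes whose promoters sit on the
other side of those contacts are its putative targets. Candidates can be
checked for replication in whole-genome sequencing of the same cell
line, and the target-gene list is tested for pathway over-representation.

All coordinates are carried in `GRanges` (1-based, closed), the native
Bioconductor convention; BED and BEDPE files (0-based, half-open) are
converted at the I/O boundary and nowhere else.

# Somatic hotspot detection

## Model

The genome is tiled into non-overlapping windows of width $w$ (default
21 bp; trailing partial tiles are dropped so every tested window has the
same width). For each window we count $k$, the number of *distinct*
samples with at least one somatic point mutation inside — multiple
mutations from one sample count once.

Under the null, each sample's $m_i$ mutations are placed uniformly and
independently on the usable genome of length $G$ (the total length of
non-excluded chromosomes; chrY is excluded by default). The probability
that sample $i$ hits a fixed window is then

$$p_i = 1 - \left(1 - \frac{w}{G}\right)^{m_i},$$

and the number of mutated samples in the window is Poisson-binomial,
$K = \sum_i \mathrm{Bernoulli}(p_i)$. The window p-value is the exact
upper tail $P(K \ge k)$, computed by dynamic-programming convolution of
the PMF — no normal or Poisson approximation is involved. The published
analysis names the Poisson-binomial model but not the form of $p_i$; the
uniform-placement closed form above is this package's own
operationalization, and it is exactly the assumption the synthetic
generator simulates, so type-I-error checks are well posed.

```{r}
poissonBinomialSF(2, c(0.1, 0.2, 0.3))   # exact tail, cf. 2^3 enumeration
perSampleWindowProb(m = 2, G = 100, w = 21)
```

## Selection and filtering

Windows with $p < \alpha$ (default $\alpha = 0.001$, the threshold used
for the published hotspot list; an optional Bonferroni correction over
the number of $k \ge 1$ windows is off by default to match it) are
reported as hotspots after removing problematic windows: any overlap
with a mappability-masked interval or a repeat interval (both ingested
as BED; the mappability thresholding itself happens upstream) or
location on an excluded chromosome. P-values are computed before
filtering and flagged windows are kept in the candidate table for audit;
the tested-family size is counted after chromosome exclusion but before
the mask/repeat filters, since those tracks arrive as external data of
unknown coverage. The PMF is convolved over the $p_i$ in sorted order so
results are bit-identical under any input ordering or sample relabeling.

Two published thresholds disagree (a figure caption says $p < 0.05$, the
results text $p < 0.001$); the default follows the value behind the
reported hotspot count, and both are configurable.

# CNVR association (PeakCNV-style)

Per base of the genome and per CNV direction (deletions and duplications
are processed fully independently), the pipeline forms the 2×2 table of
case/control samples covering/not covering the base and computes the
one-sided Fisher exact p-value for case enrichment — the hypergeometric
tail $P(X \ge a)$. Coverage only changes at interval endpoints, so the
scan runs over constant-coverage segments; results are identical to a
literal per-base loop at a fraction of the cost.

Maximal runs of significant bases ($p < 0.05$ by default) become CNVRs.
Each CNVR's **uniqueness** is the number of its supporting case samples
that support no other candidate — the stricter, order-independent
reading of "subtracting the common case samples between each pair",
implemented as $|S_i \setminus \bigcup_{j \ne i} S_j|$. CNVRs are then
clustered per chromosome with a textbook DBSCAN (no CRAN DBSCAN package
is assumed) on two z-scored features, genomic midpoint and uniqueness,
so the neighborhood radius has a scale-free default
(`eps = 0.5`, `minPts = 1`); noise points get singleton cluster ids so
every CNVR stays selectable.

One representative per cluster is chosen by the **IR-score**,

$$\mathrm{IR}(i) = |S_i| - \underset{j \ne i \in \text{cluster}}{\mathrm{mean}} |S_i \cap S_j|,$$

favoring CNVRs detected in many cases with little co-occurrence with
their neighbors; a singleton cluster scores $|S_i|$. The published work
names the score but not its formula, so this form is a documented
reconstruction that operationalizes the verbal definition; ties break
toward larger support, then leftmost start.

```{r}
spans <- GRanges("chr1", IRanges(c(100, 300), c(200, 400)))
mcols(spans) <- DataFrame(direction = "duplication",
                          case_samples = CharacterList(
                              list(paste0("s", 1:5), paste0("s", 4:6))),
                          min_p = 1e-4)
spans <- irScoreSelect(clusterCnvrs(cnvrUniqueness(spans), eps = 5))
mcols(spans)[, c("uniqueness", "ir_score", "is_representative")]
```

# Gene annotation

The reference gene list merges up to three sources with strict
precedence: all backbone (FANTOM5-style) genes are kept, and a second or
third source contributes a gene only when its symbol — compared
case-insensitively, since the published merge does not state its key —
is absent so far. Variant–gene hits are any ≥ 1 bp overlap with the full
annotated gene body (promoter logic belongs to the EPI stage). In
per-class summaries a variant hitting both a coding and a non-coding
gene counts as coding-associated; the per-hit table keeps everything.

# EPI calling

Significant Hi-C interactions are filtered to cis pairs with
$p < 0.01$, read count ≥ 10 and anchor distance strictly between 5 kb
and 10 Mb (the methods-section threshold; the results text mentions
$p < 0.001$ once, and the value is configurable). Replicates are merged
by anchor-pair union with read counts summed and the smaller p-value
kept. Genes annotate an anchor when the overlap reaches 10% of the
*smaller* of gene width and anchor width, treating short genes and bins
symmetrically (the published rule names no denominator). Promoters are
strand-aware TSS ± 2 kb windows over protein-coding genes, clipped to
chromosome bounds.

An interaction becomes an EPI when one anchor overlaps an H3K27ac peak
(≥ 1 bp) and the other overlaps a promoter; when both orientations
qualify, both are emitted rather than discarded. Cancer-specific EPIs
are an exact bin-pair set difference against the normal condition —
identity is the coordinate pair, never the target genes.

# Regulatory integration

Candidates are variants overlapping the **enhancer** anchor of at least
one cancer-specific EPI; promoter-side overlaps deliberately do not
qualify. WGS replication is class-specific: position identity for SNPs
(allele-agnostic by default), any in-span SNV for hotspots, and a
same-direction segment overlap for CNVRs (reciprocal-fraction
configurable, default any overlap). The quality filter keeps VCF records
with QUAL > 30 *and* DP > 10, both strict, reading the published removal
expression "QUAL ≤ 30 && DP ≤ 10" as describing the discarded set;
records lacking DP are dropped explicitly. Reports are emitted in a
deterministic order so identical inputs give byte-identical files.

# Enrichment

Target genes are tested against GMT gene sets with the exact
hypergeometric upper tail and fold enrichment $(x/n)/(K/N)$. The
universe defaults to whatever the caller supplies (the synthetic
scenario uses its full toy gene list); the published analysis does not
state its web tool's universe, so it is a required, visible argument.
The raw-p 0.05 cutoff is the default report filter; BH q-values are
included.

# The synthetic world

`fixtureSpec()` fixes the stated test conditions once: 100 samples on
2 × 1 Mb chromosomes with 50 background mutations/sample and one 21 bp
window carried by 30% of samples; 30 case vs 30 control CNV samples with
a planted duplication carried by 20/30 cases and 1/30 controls; and a
deterministic 5 kb-binned regulatory scenario in which two EPIs exist
only in the cancer condition, planted variants sit inside their enhancer
bins, distractors sit in promoter bins and intergenic space, and WGS
calls replicate exactly one of the two planted variants. The CNV
background rate defaults to 2 CNVs/sample (10–50 kb, direction
coin-flip); noise-free runs set it to 0, which is the mode in which
exact boundary recovery is guaranteed. Everything is seeded and
byte-reproducible.

What a green test establishes: correctness of the statistics, the
filtering logic, and the planted-signal recovery under the null model's
own assumptions. What it does not: realistic mutational signatures,
GC/replication-timing covariates, CNV breakpoint noise, population
structure, or the published cohort's headline counts, which depend on
controlled-access data and external database versions.

# Numerical and design notes

* Poisson-binomial tails are exact convolutions; tails are summed from
  the far end to preserve tiny terms, and the convolution order is
  canonicalized by sorting.
* All threshold comparisons follow the documented strictness: GWAS
  $p <$ 5e-8 strict; interaction distance bounds strict at both ends;
  VCF QUAL/DP strict; anchor-gene overlap ≥ (boundary passes).
* A published worked description of the minus-strand promoter window is
  internally inconsistent; the package follows the standard strand-aware
  definition (`GenomicRanges::promoters`), matching the plus-strand
  arithmetic.
* Two published GWAS thresholds conflict (keep $p < 5\times10^{-8}$
  vs exclude $p < 10^{-8}$); the package keeps SNPs below genome-wide
  significance, the standard reading, as a configurable default.
* Zero-width BED records are rejected rather than silently kept, with
  the offending line number, because downstream overlap arithmetic
  assumes positive widths.

# Limitations

Upstream processing (read alignment, variant calling, Hi-C significance
modeling, peak calling) is consumed, not reproduced. Indels and SNVs are
not distinguished in hotspot counting; X-dosage and population structure
are not modeled in the CNVR scan; transcript-level consequences are out
of scope.
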