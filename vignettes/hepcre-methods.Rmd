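---
title: "Methods: hepatocyte subtypes and cis-regulatory elements from single-cell summary tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hepatocyte subtypes and cis-regulatory elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepcre)
```

## Scope and data model

`hepcre` implements the downstream half of a liver single-cell
multi-omics analysis. It deliberately starts *after* the heavy upstream
machinery — integration/clustering, cell-type annotation, peak calling,
fragment processing, network inference — and consumes their summary
tables: per-cluster DEG tables, categorised accessible-chromatin peaks,
histone ChIP-seq peaks, motif occurrences, and two styles of
enhancer–gene link tables (inference-derived and curated-annotation).
Everything genomic lives in `GRanges`; all coordinates are exchanged in
the BED convention (0-based, half-open) and converted once at the I/O
boundary, so file round trips are exact. Overlap queries run on the
`GenomicRanges`/`IRanges` interval trees with `minoverlap = min_bp`;
strand is ignored for all overlap arithmetic (ATAC and histone peaks are
unstranded) and used only for the sign of TSS distances.

## Subtype consolidation

Each cluster is reduced to its top `k = 20` upregulated genes: records
with `avg_log2FC > 0` and `p_val < 0.05`, sorted by `avg_log2FC`
descending. The unadjusted `p_val` column is used as-is, matching the
field's convention for this filter; ties at the cut are broken by gene
symbol ascending so the set is reproducible. Similarity between clusters
is the Jaccard index of these sets; the similarity of two empty sets is
undefined and reported as 0 with a warning.

Clusters whose off-diagonal similarity is exactly 0 everywhere are set
aside as `excluded` before clustering — they share no top genes with any
other cluster and would otherwise distort the tree. The rest are merged
agglomeratively on distance `1 − J` with **complete linkage** — the
default linkage of the standard heatmap clustering stack — and the tree
is cut at exactly `n_subtypes = 2` groups rather than at a height
threshold, because the analysis this package supports reports exactly
two hepatocyte subtypes. Labels are assigned by decreasing group size
(ties by smallest member id), so output labels are deterministic and
order-invariant.

## Condition markers

Marker genes of the disease-skewed subtype are the intersection of the
condition-upregulated genes (same `avg_log2FC`/`p_val` filter, applied
to the disease-vs-normal contrast) with the **union** of the supplied
pathway gene sets. The union reading was chosen over the intersection
because the pairwise Venn presentation of the source analysis treats the
two pathway sets symmetrically against the upregulated set; with the
bundled synthetic pathways both readings recover the same five planted
markers. Pathway sets are inputs (GMT or two-column TSV), never computed
here: ontology enrichment is upstream of this package. Gene matching is
exact and case-sensitive, with an explicit `ignore_case` escape hatch.

## Peak statistics

`category_table()` tallies the four positional categories per condition;
uncategorised peaks are reported under `unassigned` but excluded from
proportions and tests. The between-condition contrast is a Pearson
chi-squared test of independence **without** continuity correction
(`stats::chisq.test(correct = FALSE)`): counts in this setting are large
(the 2×4 table has df = 3), and the uncorrected statistic is the one the
closed form predicts. Degenerate margins raise an error naming the
offending row or column rather than returning NaN.

The "gene region" used by `gene_coverage()` is a TSS ± 50 kb window by
default. The source analysis never defines the extent its upstream tool
used, so the window is an explicit, documented parameter rather than a
hidden constant; 50 kb is a conventional cis-regulatory neighbourhood.
A peak spanning two windows counts for both genes — no unique-assignment
rule is imposed. Venn regions over the four per-category gene sets are
exclusive-membership counts, so they always satisfy inclusion–exclusion.

## Promoter and enhancer calls

The calling rules are deliberately literal:

* **promoter** = Promoter-category peak overlapping ≥ 1 H3K4me3 peak;
* **enhancer** = Distal/Exonic/Intronic peak overlapping ≥ 1 H3K4me1
  peak **and** ≥ 1 H3K27ac peak.

Any-overlap (`min_bp = 1`, the `bedtools intersect` default) is used
rather than a summit or fraction rule; no minimum overlap fraction is
part of the method this implements, and `min_bp` is exposed for
sensitivity analysis. Histone tracks are used as supplied, without
pre-merging overlapping intervals. The two classes are disjoint by the
category rule alone.

Gene assignment: a promoter is assigned to the nearest TSS inside the
peak or within 2,000 bp of it (the classical promoter extent upstream of
the TSS); an enhancer gets a positional *fallback* assignment to the
nearest TSS within 100 kb. The fallback is informational only — the
authoritative enhancer→gene mapping comes from the link tables in the
network stage, which is why the 100 kb default (a conventional distal
regulatory range) is not a sensitive choice. Equidistant TSSs resolve to
the lexicographically smaller symbol; reported distances are signed from
TSS to peak midpoint, negative upstream, strand-aware.

## Networks

Motif enrichment of a CRE set against the full peak background is the
upper-tail hypergeometric probability `P(X ≥ k)` for a motif occurring
in `K` of `N` background peaks and `k` of `n` target peaks, with BH
correction applied **within** each CRE class (promoters and enhancers
are presented side by side, not pooled).

Promoter-network edges TF → promoter → gene require: gene upregulated in
the condition contrast, gene owns a promoter call, the TF motif occurs
in that promoter peak, and the TF belongs to the TF universe (by default
the variable-gene list shipped with the DEG tables). Self-loops are kept
but flagged. Edges are enumerated per (TF, promoter, gene) triple;
multiple promoters per gene are allowed.

Enhancer-network filtering keeps an inferred link only when a curated
link **overlaps its coordinates and names the same gene** (the stricter
of the readings of "supported by annotation"; `require_gene_match =
FALSE` relaxes it to overlap-only) and the link's enhancer overlaps a
histone-supported enhancer call. The three-set Venn is reported both
over enhancer–gene pairs and over unique enhancer regions, since either
could be the unit of the published overlap count.

## The synthetic generator

The generator emulates the *shapes and statistical structure* of the
post-upstream tables, not raw sequencing data. Its defaults are the
study conditions: 12 hepatocyte clusters in two planted blocks
(C0/C3/C8/C11/C12/C13/C15 and C1/C4/C7/C14) plus the outlier C9; 10 of
the top-20 genes shared within a block (within-block Jaccard exactly
10/30 = 1/3, between-block 0, outlier 0 everywhere); disease-cell
fractions 0.853 in the disease-skewed subtype and 0.12 in the
normal-skewed one; Promoter-category shares 16.8 % (disease) vs 8.3 %
(normal) with Intronic the most abundant class. Scale defaults are
1/10th of the study (≈ 2,000 genes, 2,000 peaks, 150 cells per cluster,
a 3 × 10 Mb toy genome), which keeps a full pipeline run under a minute;
these sizes are also what the test suite and the acceptance script use.

Peaks are placed in exclusive 2 kb slots, one peak per slot, with
histone evidence confined to the same slot. This makes planted truth
*exact*: a peak overlaps a mark if and only if the generator gave it
that mark, so promoter/enhancer recovery can be asserted at precision =
recall = 1 rather than approximately. Decoys cover the rejection paths:
Promoter-category peaks carrying both enhancer marks, non-Promoter peaks
carrying exactly one of the two, and unmarked peaks. Planted promoter
rates (half of the eligible category) and enhancer rates (15 % vs 2 % of
non-Promoter peaks in disease vs normal) echo the strong disease skew of
enhancer calls in the source setting. Each planted promoter hosts
exactly one gene TSS at its midpoint; background TSSs are placed in
unused slots more than 2 kb from every peak, so nearest-TSS assignment
recovers the planted promoter→gene map uniquely.

Link tables realise a configured 100/60/40 agreement: 100 inferred
links, 60 with curated support, 40 of those on true enhancer intervals.
The 40 triple-supported links are the planted surviving edges;
curated-but-not-histone decoys live on a reserved chromosome where no
enhancer is ever called, so the three evidence sets cannot leak into
each other. DEG `p_val` values are *generated*, not computed from
counts: differential testing is upstream of this package, and the
generator only needs records that pass or fail the filters by
construction.

One master seed drives everything through a fixed per-stage sub-seed
derivation (`sub_seed()`), so fixture bundles are byte-identical under a
fixed seed and every stage can also be regenerated independently.

### What passing tests do and do not show

The generator plants clean, separable structure: exact block Jaccards,
exclusive histone slots, noiseless link agreement. Passing recovery
tests therefore demonstrates that the *rules* are implemented exactly —
they do not demonstrate robustness to the messiness of real data
(overlapping peaks, ambiguous categories, partial histone coverage,
fuzzy link coordinates), and they cannot reproduce the study's absolute
counts, which depend on the real accession data and upstream tools.

## Numerical and degenerate-input choices

* Jaccard of two empty sets: 0 with a warning (undefined in the method).
* Empty peak sets: match fractions reported as `NA` with a warning, not 0.
* All clusters mutually zero-similar: an error ("no mergeable
  structure") rather than an arbitrary partition.
* Chi-squared on tables with a zero margin: an error naming the
  degenerate row/column.
* The pipeline manifest records checksums but no timestamps, so reruns
  with identical inputs are byte-identical — determinism is a testable
  contract, not an aspiration.

## Known limitations

Cluster consolidation assumes the top-k sets are informative (k, the
fold-change and p thresholds are exposed); the chi-squared contrast
assumes independent peak counts; CRE calling has no notion of signal
strength, only binary overlap; and the positional enhancer–gene fallback
is a heuristic that real analyses should replace with measured or
curated links, as the network stage here does.
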