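#' Peak-category composition by condition
#'
#' Tallies accessible peaks into the four positional categories per
#' condition and row-normalises to proportions. Peaks without a category
#' are counted under an extra `unassigned` column that is excluded from
#' the proportions and from downstream contingency tests.
#'
#' @param peaks_by_condition Named list of `GRanges` (one per condition),
#'   each carrying a `peak_category` metadata column.
#' @return List with `counts` (conditions x categories integer matrix,
#'   plus `unassigned` when needed) and `proportions` (over the four
#'   categories; `NA` for an empty condition, with a warning).
#' @export
category_table <- function(peaks_by_condition) {
  stopifnot(is.list(peaks_by_condition),
            !is.null(names(peaks_by_condition)))
  cats <- PEAK_CATEGORIES
  counts <- t(vapply(peaks_by_condition, function(gr) {
    pc <- S4Vectors::mcols(gr)$peak_category
    c(table(factor(pc, levels = cats)), unassigned = sum(is.na(pc)))
  }, integer(length(cats) + 1L)))
  if (all(counts[, "unassigned"] == 0L))
    counts <- counts[, cats, drop = FALSE]
  core <- counts[, cats, drop = FALSE]
  totals <- rowSums(core)
  if (any(totals == 0L))
    warning("condition(s) with zero categorised peaks: ",
            paste(rownames(core)[totals == 0L], collapse = ", "))
  proportions <- sweep(core, 1L, totals, "/")
  list(counts = counts, proportions = proportions)
}

#' Chi-squared test of independence on a category table
#'
#' Pearson chi-squared without continuity correction: expected counts from
#' the row/column margins, statistic `sum((obs - exp)^2 / exp)`,
#' `df = (rows - 1)(cols - 1)`, p-value from the upper tail. Used to
#' contrast peak-category composition between conditions.
#'
#' @param counts Non-negative integer matrix (e.g. `category_table()$counts`
#'   restricted to the four categories).
#' @return List with `statistic`, `df`, `p_value` and `expected`.
#' @export
chisq_independence <- function(counts) {
  counts <- as.matrix(counts)
  if ("unassigned" %in% colnames(counts))
    counts <- counts[, setdiff(colnames(counts), "unassigned"),
                     drop = FALSE]
  rz <- which(rowSums(counts) == 0)
  cz <- which(colSums(counts) == 0)
  if (length(rz)) stop("degenerate row with zero margin: ",
                       paste(rownames(counts)[rz] %||% rz, collapse = ", "))
  if (length(cz)) stop("degenerate column with zero margin: ",
                       paste(colnames(counts)[cz] %||% cz, collapse = ", "))
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = ht$expected)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fraction of peaks matched by a histone track
#'
#' A peak is matched when at least one track interval overlaps it by
#' `min_bp` bases. Matched and unmatched fractions sum to 1 for a
#' non-empty peak set.
#'
#' @param peaks `GRanges` of accessible peaks.
#' @param track A [histone_track()].
#' @param min_bp Minimum overlap in bp.
#' @return List with `mark`, `n`, `matched`, `matched_fraction`,
#'   `unmatched_fraction`.
#' @export
histone_match_fraction <- function(peaks, track, min_bp = 1L) {
  stopifnot(inherits(track, "histone_track"))
  n <- length(peaks)
  if (n == 0L) {
    warning("empty peak set: match fractions undefined")
    return(list(mark = track$mark, n = 0L, matched = 0L,
                matched_fraction = NA_real_,
                unmatched_fraction = NA_real_))
  }
  matched <- sum(match_any(peaks, track$intervals, min_bp = min_bp)$hit)
  list(mark = track$mark, n = n, matched = matched,
       matched_fraction = matched / n,
       unmatched_fraction = 1 - matched / n)
}

#' Gene coverage by peak category
#'
#' Assigns each peak to every gene whose region (TSS +/- `gene_window_bp`,
#' clipped at the chromosome start) it overlaps, then summarises per
#' category: the gene sets covered by at least one peak, their four-set
#' Venn breakdown, the maximum number of peaks of each category within one
#' gene region, and the genes covered by all four categories. A peak
#' spanning two gene windows counts for both genes.
#'
#' @param peaks `GRanges` with `peak_category`.
#' @param annotation Gene annotation data.frame (`gene`, `chrom`, `tss`,
#'   `strand`).
#' @param gene_window_bp Half-width of the TSS-anchored gene region
#'   (default 50000 bp).
#' @return List with `gene_sets` (per category), `counts` (data frame
#'   gene x category peak counts), `venn`, `max_per_category` and
#'   `genes_all_categories`.
#' @export
gene_coverage <- function(peaks, annotation, gene_window_bp = 50000L) {
  annotation <- validate_gene_annotation(annotation)
  if (nrow(annotation) == 0L) stop("empty gene annotation")
  windows <- genomic_intervals(
    annotation$chrom,
    pmax(annotation$tss - gene_window_bp, 0L),
    annotation$tss + gene_window_bp,
    name = annotation$gene)
  hits <- GenomicRanges::findOverlaps(peaks, windows,
                                      ignore.strand = TRUE)
  cat_of_peak <- S4Vectors::mcols(peaks)$peak_category
  pairs <- data.frame(
    gene = annotation$gene[S4Vectors::subjectHits(hits)],
    category = cat_of_peak[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE)
  pairs <- pairs[!is.na(pairs$category), , drop = FALSE]
  tab <- table(factor(pairs$gene, levels = sort(unique(pairs$gene))),
               factor(pairs$category, levels = PEAK_CATEGORIES))
  counts <- as.data.frame.matrix(tab)
  gene_sets <- lapply(PEAK_CATEGORIES, function(cc)
    rownames(counts)[counts[[cc]] > 0L])
  names(gene_sets) <- PEAK_CATEGORIES
  venn <- if (nrow(counts)) venn_counts(gene_sets) else
    data.frame(region = character(), count = integer())
  max_per_category <- vapply(PEAK_CATEGORIES, function(cc)
    if (nrow(counts)) max(counts[[cc]]) else 0L, numeric(1))
  all_four <- if (nrow(counts))
    rownames(counts)[rowSums(counts > 0L) == length(PEAK_CATEGORIES)]
  else character()
  list(gene_sets = gene_sets, counts = counts, venn = venn,
       max_per_category = max_per_category,
       genes_all_categories = all_four)
}
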