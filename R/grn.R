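#' Motif enrichment over a peak set
#'
#' For each transcription-factor motif, counts its occurrences among the
#' target peaks (k of n) and the background peaks (K of N) and computes
#' the upper-tail hypergeometric probability `P(X >= k)` of drawing at
#' least k motif-bearing peaks in n draws, plus the fold enrichment
#' `(k/n) / (K/N)` and Benjamini-Hochberg adjusted q-values across motifs.
#'
#' @param target_peaks Character vector of target peak ids (must be a
#'   subset of the background).
#' @param background_peaks Character vector of background peak ids.
#' @param occurrences Data frame with columns `peak_id`, `motif`; pairs
#'   are unique and every `peak_id` must be a background peak.
#' @return Data frame (one row per motif) with `motif`, `k`, `n`, `K`,
#'   `N`, `fold`, `p_value`, `q_value`, ordered by increasing p.
#' @export
motif_enrichment <- function(target_peaks, background_peaks, occurrences) {
  target_peaks <- unique(target_peaks)
  background_peaks <- unique(background_peaks)
  if (!all(target_peaks %in% background_peaks))
    stop("target peaks must be a subset of background peaks")
  stopifnot(all(c("peak_id", "motif") %in% names(occurrences)))
  occurrences <- unique(occurrences[, c("peak_id", "motif")])
  if (!all(occurrences$peak_id %in% background_peaks))
    stop("occurrence table references peaks outside the background")
  N <- length(background_peaks)
  n <- length(target_peaks)
  motifs <- sort(unique(occurrences$motif))
  res <- do.call(rbind, lapply(motifs, function(m) {
    with_m <- occurrences$peak_id[occurrences$motif == m]
    K <- length(with_m)
    k <- sum(with_m %in% target_peaks)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    fold <- if (n > 0L && K > 0L) (k / n) / (K / N) else NA_real_
    data.frame(motif = m, k = k, n = n, K = K, N = N, fold = fold,
               p_value = p, stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    return(data.frame(motif = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), fold = numeric(),
                      p_value = numeric(), q_value = numeric()))
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$p_value, res$motif), , drop = FALSE]
}

#' Promoter-anchored regulatory network
#'
#' Emits one edge TF -> promoter -> gene for every combination where the
#' target gene is condition-upregulated, owns a promoter call, the TF's
#' motif occurs in that promoter peak, and the TF belongs to the TF
#' universe (by default the variable-gene list supplied alongside the DEG
#' tables). Self-loops (TF regulating its own promoter) are kept but
#' flagged.
#'
#' @param upregulated Character vector of upregulated gene symbols.
#' @param promoter_calls `GRanges` of promoter calls carrying a `gene`
#'   metadata column (see [assign_gene()]).
#' @param occurrences Motif occurrence data frame (`peak_id`, `motif`).
#' @param tf_universe Character vector of admissible TF symbols.
#' @return Data frame of edges: `tf`, `cre_id`, `cre_class`, `gene`,
#'   `evidence_sources`, `self_loop`.
#' @export
build_promoter_network <- function(upregulated, promoter_calls,
                                   occurrences, tf_universe) {
  m <- S4Vectors::mcols(promoter_calls)
  if (is.null(m$gene))
    stop("promoter calls carry no gene assignment; run assign_gene()")
  keep <- !is.na(m$gene) & m$gene %in% upregulated
  ids <- m$name[keep]
  genes <- m$gene[keep]
  occ <- unique(occurrences[occurrences$peak_id %in% ids &
                              occurrences$motif %in% tf_universe,
                            c("peak_id", "motif"), drop = FALSE])
  if (nrow(occ) == 0L)
    return(data.frame(tf = character(), cre_id = character(),
                      cre_class = character(), gene = character(),
                      evidence_sources = character(),
                      self_loop = logical()))
  gene_of <- stats::setNames(genes, ids)
  edges <- data.frame(tf = occ$motif, cre_id = occ$peak_id,
                      cre_class = "promoter",
                      gene = unname(gene_of[occ$peak_id]),
                      evidence_sources = "motif+histone",
                      stringsAsFactors = FALSE)
  edges$self_loop <- edges$tf == edges$gene
  edges <- edges[order(edges$tf, edges$gene, edges$cre_id), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Read an enhancer-gene link table
#'
#' Tab-separated with header; required columns `chrom`, `start`, `end`
#' (BED convention), `gene`; optional `tf` and `score`.
#'
#' @param path Input TSV.
#' @param source `"inferred"` (network-inference style) or `"curated"`
#'   (annotation-database style).
#' @return Data frame with a `source` column added.
#' @export
read_links <- function(path, source = c("inferred", "curated")) {
  source <- match.arg(source)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene")
  if (!all(need %in% names(tab)))
    stop("link table needs columns: ", paste(need, collapse = ", "))
  if (any(tab$end <= tab$start)) stop("link with end <= start in ", path)
  tab$source <- source
  tab
}

links_to_granges <- function(links) {
  genomic_intervals(links$chrom, links$start, links$end,
                    name = sprintf("link_%05d", seq_len(nrow(links))))
}

#' Triple-evidence enhancer regulatory network
#'
#' Starts from inference-derived enhancer-gene links and keeps a link only
#' when (a) some curated link overlaps its enhancer coordinates by
#' `min_bp` bases AND targets the same gene (set `require_gene_match =
#' FALSE` for overlap-only support), and (b) its enhancer overlaps a
#' histone-supported enhancer call. The three-set Venn breakdown
#' (inferred / curated-supported / histone-supported) is reported over
#' enhancer-gene pairs and over unique enhancer regions.
#'
#' @param inferred Inferred link data frame (see [read_links()]); a `tf`
#'   column is carried through when present.
#' @param curated Curated link data frame.
#' @param enhancer_calls `GRanges` of enhancer calls from
#'   [call_enhancers()].
#' @param min_bp Minimum coordinate overlap in bp.
#' @param require_gene_match Demand gene identity for curated support
#'   (default `TRUE`, the stricter reading).
#' @return List with `edges` (surviving links as a data frame with
#'   `evidence_sources`), `venn_pairs` and `venn_regions`.
#' @export
build_enhancer_network <- function(inferred, curated, enhancer_calls,
                                   min_bp = 1L, require_gene_match = TRUE) {
  stopifnot(nrow(inferred) >= 0L)
  inf_gr <- links_to_granges(inferred)
  cur_gr <- links_to_granges(curated)
  hits <- GenomicRanges::findOverlaps(inf_gr, cur_gr,
                                      minoverlap = min_bp,
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (require_gene_match) {
    good <- inferred$gene[qh] == curated$gene[sh]
    qh <- qh[good]
  }
  curated_ok <- seq_len(nrow(inferred)) %in% qh
  histone_ok <- if (length(enhancer_calls))
    match_any(inf_gr, enhancer_calls, min_bp = min_bp)$hit
  else rep(FALSE, nrow(inferred))
  pair_id <- sprintf("%s:%d-%d|%s", inferred$chrom, inferred$start,
                     inferred$end, inferred$gene)
  region_id <- sprintf("%s:%d-%d", inferred$chrom, inferred$start,
                       inferred$end)
  venn_pairs <- venn_counts(list(
    inferred = pair_id,
    curated = pair_id[curated_ok],
    histone = pair_id[histone_ok]))
  venn_regions <- venn_counts(list(
    inferred = region_id,
    curated = region_id[curated_ok],
    histone = region_id[histone_ok]))
  keep <- curated_ok & histone_ok
  edges <- inferred[keep, , drop = FALSE]
  edges$cre_id <- region_id[keep]
  edges$cre_class <- if (any(keep)) "enhancer" else character(0)
  edges$evidence_sources <- if (any(keep))
    "inferred+curated+histone" else character(0)
  rownames(edges) <- NULL
  list(edges = edges, venn_pairs = venn_pairs,
       venn_regions = venn_regions)
}
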