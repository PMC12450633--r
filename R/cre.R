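#' Call promoters from accessible peaks and H3K4me3
#'
#' A peak is called a promoter exactly when its positional category is
#' `Promoter` and at least one H3K4me3 interval overlaps it by `min_bp`
#' bases. The histone evidence is recorded on each call.
#'
#' @param peaks `GRanges` of accessible peaks with `peak_category`.
#' @param h3k4me3 A [histone_track()] with mark `H3K4me3`.
#' @param min_bp Minimum overlap in bp.
#' @return `GRanges` subset of `peaks` with metadata columns `cre_class`
#'   (`"promoter"`) and `evidence`.
#' @export
call_promoters <- function(peaks, h3k4me3, min_bp = 1L) {
  stopifnot(inherits(h3k4me3, "histone_track"))
  if (h3k4me3$mark != "H3K4me3")
    stop("promoter calling requires an H3K4me3 track, got ", h3k4me3$mark)
  hit <- match_any(peaks, h3k4me3$intervals, min_bp = min_bp)$hit
  sel <- !is.na(S4Vectors::mcols(peaks)$peak_category) &
    S4Vectors::mcols(peaks)$peak_category == "Promoter" & hit
  calls <- peaks[sel]
  S4Vectors::mcols(calls)$cre_class <- rep("promoter", sum(sel))
  S4Vectors::mcols(calls)$evidence <- rep("H3K4me3", sum(sel))
  calls
}

#' Call enhancers from accessible peaks and H3K4me1 + H3K27ac
#'
#' A peak is called an enhancer exactly when its positional category is
#' one of `Distal`, `Exonic`, `Intronic` (i.e. not `Promoter`) and it is
#' overlapped by at least one interval of each of the two marks.
#'
#' @param peaks `GRanges` of accessible peaks with `peak_category`.
#' @param h3k4me1,h3k27ac [histone_track()]s with the matching marks.
#' @param min_bp Minimum overlap in bp.
#' @return `GRanges` subset of `peaks` with `cre_class` (`"enhancer"`)
#'   and `evidence`.
#' @export
call_enhancers <- function(peaks, h3k4me1, h3k27ac, min_bp = 1L) {
  stopifnot(inherits(h3k4me1, "histone_track"),
            inherits(h3k27ac, "histone_track"))
  if (h3k4me1$mark != "H3K4me1")
    stop("first track must be H3K4me1, got ", h3k4me1$mark)
  if (h3k27ac$mark != "H3K27ac")
    stop("second track must be H3K27ac, got ", h3k27ac$mark)
  pc <- S4Vectors::mcols(peaks)$peak_category
  hit1 <- match_any(peaks, h3k4me1$intervals, min_bp = min_bp)$hit
  hit2 <- match_any(peaks, h3k27ac$intervals, min_bp = min_bp)$hit
  sel <- !is.na(pc) & pc %in% c("Distal", "Exonic", "Intronic") &
    hit1 & hit2
  calls <- peaks[sel]
  S4Vectors::mcols(calls)$cre_class <- rep("enhancer", sum(sel))
  S4Vectors::mcols(calls)$evidence <- rep("H3K4me1+H3K27ac", sum(sel))
  calls
}

#' Assign regulatory-element calls to genes by TSS proximity
#'
#' Promoter calls are assigned to the gene whose TSS lies inside the peak
#' or within `promoter_window_bp` of it (nearest such TSS). Enhancer calls
#' get a positional fallback assignment to the nearest TSS within
#' `enhancer_max_distance_bp`, or stay unassigned; authoritative
#' enhancer-gene links come from the evidence tables consumed by the
#' network builder, not from distance. Ties between equidistant TSSs go to
#' the lexicographically smaller gene symbol. The reported distance is
#' signed from the TSS to the peak midpoint, strand-aware: negative when
#' the peak lies upstream of the TSS.
#'
#' @param calls `GRanges` of CRE calls (with `cre_class`).
#' @param annotation Gene annotation data.frame.
#' @param promoter_window_bp Promoter search window around the peak
#'   (default 2000 bp, the classical promoter extent upstream of the TSS).
#' @param enhancer_max_distance_bp Maximum TSS distance for the enhancer
#'   fallback (default 100000 bp).
#' @return `calls` with added metadata columns `gene` (symbol or `NA`)
#'   and `distance_to_tss` (signed bp, `NA` when unassigned).
#' @export
assign_gene <- function(calls, annotation, promoter_window_bp = 2000L,
                        enhancer_max_distance_bp = 100000L) {
  annotation <- validate_gene_annotation(annotation)
  if (nrow(annotation) == 0L) stop("empty gene annotation")
  n <- length(calls)
  gene <- rep(NA_character_, n)
  dist_signed <- rep(NA_real_, n)
  if (n) {
    chrom <- as.character(GenomicRanges::seqnames(calls))
    s0 <- bed_start(calls)
    e0 <- bed_end(calls)
    cls <- S4Vectors::mcols(calls)$cre_class
    for (i in seq_len(n)) {
      cand <- annotation[annotation$chrom == chrom[i], , drop = FALSE]
      if (nrow(cand) == 0L) next
      # gap distance from TSS point to the half-open peak: 0 if inside
      gap <- pmax(s0[i] - cand$tss, cand$tss - (e0[i] - 1L), 0L)
      limit <- if (identical(cls[i], "promoter")) promoter_window_bp
               else enhancer_max_distance_bp
      ok <- which(gap <= limit)
      if (length(ok) == 0L) next
      best <- ok[order(gap[ok], cand$gene[ok])][1L]
      gene[i] <- cand$gene[best]
      mid <- (s0[i] + e0[i]) / 2
      d <- mid - cand$tss[best]
      if (cand$strand[best] == "-") d <- -d
      dist_signed[i] <- d
    }
  }
  S4Vectors::mcols(calls)$gene <- gene
  S4Vectors::mcols(calls)$distance_to_tss <- dist_signed
  calls
}

#' Write CRE calls as extended BED
#'
#' Columns: chrom, start, end, name, score, strand, cre_class, evidence,
#' gene, distance_to_tss.
#'
#' @param calls `GRanges` of annotated CRE calls.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cre_calls <- function(calls, path) {
  m <- S4Vectors::mcols(calls)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(calls)),
                   start = bed_start(calls), end = bed_end(calls),
                   name = m$name,
                   score = ifelse(is.na(m$score), 0, m$score),
                   strand = ".",
                   cre_class = m$cre_class, evidence = m$evidence,
                   gene = ifelse(is.na(m$gene), "unassigned", m$gene),
                   distance_to_tss = ifelse(is.na(m$distance_to_tss), ".",
                                            m$distance_to_tss))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
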