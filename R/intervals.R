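#' @importFrom GenomicRanges GRanges findOverlaps countOverlaps mcols start end seqnames width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqlevels
NULL

PEAK_CATEGORIES <- c("Promoter", "Distal", "Exonic", "Intronic")
HISTONE_MARKS <- c("H3K4me1", "H3K4me3", "H3K27ac")

#' Construct a set of genomic intervals
#'
#' Builds a `GRanges` from BED-convention coordinates (0-based, half-open).
#' This is the unit of all overlap arithmetic in the package: accessible
#' peaks, histone ChIP-seq peaks and regulatory-element calls are all held
#' in this form. Internally coordinates are converted to the 1-based closed
#' convention `GRanges` uses; [write_bed()] converts back, so round trips
#' are exact.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start Integer vector, 0-based inclusive starts (>= 0).
#' @param end Integer vector, 0-based exclusive ends (> start).
#' @param name Optional interval identifiers; auto-generated when `NULL`.
#' @param score Optional numeric scores (`NA` allowed).
#' @param peak_category Optional category per interval, one of
#'   `"Promoter"`, `"Distal"`, `"Exonic"`, `"Intronic"` or `NA`.
#' @param summit_offset Optional integer offset of the point source from
#'   `start` (narrowPeak column 10); `-1` when absent.
#' @return A `GRanges` with metadata columns `name`, `score`,
#'   `peak_category` and `summit_offset`.
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, score = NA_real_,
                              peak_category = NA_character_,
                              summit_offset = -1L) {
  n <- max(length(chrom), length(start), length(end))
  if (n > 0L) {
    chrom <- rep_len(as.character(chrom), n)
    start <- rep_len(start, n)
    end <- rep_len(end, n)
  }
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(!nzchar(chrom)) || any(is.na(chrom)))
    stop("chrom must be non-empty strings")
  if (any(is.na(start)) || any(start < 0L))
    stop("start must be non-negative integers")
  if (any(is.na(end)) || any(end <= start))
    stop("end must exceed start (0-based half-open)")
  if (is.null(name)) name <- sprintf("iv_%05d", seq_len(n))
  peak_category <- rep_len(as.character(peak_category), n)
  bad <- !is.na(peak_category) & !(peak_category %in% PEAK_CATEGORIES)
  if (any(bad))
    stop("unknown peak_category value(s): ",
         paste(unique(peak_category[bad]), collapse = ", "))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  S4Vectors::mcols(gr)$name <- as.character(name)
  S4Vectors::mcols(gr)$score <- rep_len(as.numeric(score), n)
  S4Vectors::mcols(gr)$peak_category <- peak_category
  S4Vectors::mcols(gr)$summit_offset <- rep_len(as.integer(summit_offset), n)
  gr
}

#' BED-convention starts and ends of an interval set
#'
#' @param gr A `GRanges`.
#' @return Integer vector of 0-based starts (`bed_start`) or exclusive
#'   ends (`bed_end`).
#' @export
bed_start <- function(gr) GenomicRanges::start(gr) - 1L

#' @rdname bed_start
#' @export
bed_end <- function(gr) GenomicRanges::end(gr)

#' A histone modification track
#'
#' Bundles a set of ChIP-seq peak intervals with the histone mark they
#' measure, so promoter/enhancer calling can refuse a track of the wrong
#' mark.
#'
#' @param mark One of `"H3K4me1"`, `"H3K4me3"`, `"H3K27ac"`.
#' @param intervals A `GRanges` of peak intervals.
#' @return An object of class `histone_track`.
#' @export
histone_track <- function(mark, intervals) {
  mark <- match.arg(mark, HISTONE_MARKS)
  stopifnot(is(intervals, "GRanges"))
  structure(list(mark = mark, intervals = intervals),
            class = "histone_track")
}

#' @export
print.histone_track <- function(x, ...) {
  cat(sprintf("<histone_track> %s: %d intervals\n",
              x$mark, length(x$intervals)))
  invisible(x)
}

split_bed_lines <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

#' Read intervals from BED or ENCODE narrowPeak
#'
#' Parses a tab-separated BED file (>= 3 columns) into a `GRanges`,
#' keeping coordinates exactly as written (BED is already 0-based
#' half-open). With `format = "narrowPeak"` every data line must carry the
#' 10 ENCODE columns and the summit offset is read from column 10.
#' Accessible-peak files may carry their category (Promoter / Distal /
#' Exonic / Intronic) in an extra column named by `category_column`.
#'
#' @param path Input file path.
#' @param category_column Optional 1-based index of the column holding the
#'   peak category.
#' @param format `"bed"` (default) or `"narrowPeak"`.
#' @return A `GRanges` as built by [genomic_intervals()].
#' @export
read_bed <- function(path, category_column = NULL,
                     format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- split_bed_lines(path)
  fields <- parsed$fields
  if (length(fields) == 0L)
    return(genomic_intervals(character(), integer(), integer()))
  nf <- lengths(fields)
  need <- if (format == "narrowPeak") 10L else 3L
  if (any(nf < need))
    stop(sprintf("malformed line %d in %s: expected >= %d fields, got %d",
                 parsed$lineno[which(nf < need)[1L]], path, need,
                 nf[which(nf < need)[1L]]))
  if (!is.null(category_column) && any(nf < category_column))
    stop(sprintf("malformed line %d in %s: no column %d",
                 parsed$lineno[which(nf < category_column)[1L]], path,
                 category_column))
  col <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[[i]] else NA_character_, character(1))
  start <- suppressWarnings(as.integer(col(2)))
  end <- suppressWarnings(as.integer(col(3)))
  bad <- which(is.na(start) | is.na(end) | start < 0L | end <= start)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: invalid coordinates '%s' '%s'",
                 parsed$lineno[bad[1L]], path,
                 col(2)[bad[1L]], col(3)[bad[1L]]))
  name <- if (all(nf >= 4L)) col(4) else NULL
  score <- if (all(nf >= 5L))
    suppressWarnings(as.numeric(col(5))) else NA_real_
  summit <- if (format == "narrowPeak")
    suppressWarnings(as.integer(col(10))) else -1L
  if (format == "narrowPeak" && any(is.na(summit)))
    stop(sprintf("malformed line %d in %s: non-integer summit column",
                 parsed$lineno[which(is.na(summit))[1L]], path))
  category <- NA_character_
  if (!is.null(category_column)) category <- col(category_column)
  genomic_intervals(col(1), start, end, name = name, score = score,
                    peak_category = category, summit_offset = summit)
}

#' Write intervals to BED or narrowPeak
#'
#' Emits BED6 (name, score, strand `.`) with the peak category appended as
#' a seventh column when any interval carries one; `format = "narrowPeak"`
#' writes the 10-column ENCODE layout with the summit offset in column 10.
#' `read_bed(write_bed(x))` reproduces chrom/start/end/name exactly.
#'
#' @param gr A `GRanges` as built by [genomic_intervals()].
#' @param path Output file path.
#' @param format `"bed"` or `"narrowPeak"`.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  m <- S4Vectors::mcols(gr)
  n <- length(gr)
  score <- ifelse(is.na(m$score), 0, m$score)
  base <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = bed_start(gr), end = bed_end(gr),
                     name = m$name, score = score,
                     strand = rep(".", n))
  if (format == "narrowPeak") {
    base$signalValue <- rep(0, n)
    base$pValue <- rep(-1, n)
    base$qValue <- rep(-1, n)
    base$peak <- ifelse(is.na(m$summit_offset), -1L, m$summit_offset)
  } else if (any(!is.na(m$peak_category))) {
    base$peak_category <- ifelse(is.na(m$peak_category), "NA",
                                 m$peak_category)
  }
  utils::write.table(base, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Do two intervals overlap by at least `min_bp` bases?
#'
#' Overlap length is `min(end) - max(start)` on the shared chromosome;
#' abutting half-open intervals do not overlap. Vectorised over pairs.
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled).
#' @param min_bp Minimum overlap in bp (default 1, the `bedtools
#'   intersect` default).
#' @return Logical vector.
#' @export
overlaps <- function(a, b, min_bp = 1L) {
  if (min_bp < 1L) stop("min_bp must be >= 1")
  n <- max(length(a), length(b))
  a <- rep(a, length.out = n)
  b <- rep(b, length.out = n)
  same <- as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b))
  ov <- pmin(bed_end(a), bed_end(b)) - pmax(bed_start(a), bed_start(b))
  same & ov >= min_bp
}

#' Match queries against a subject interval set
#'
#' For each query interval, reports whether any subject overlaps it by at
#' least `min_bp` bases, and which subjects do. Backed by the interval-tree
#' overlap engine of `GenomicRanges`; strand is ignored.
#'
#' @param queries,subjects `GRanges`.
#' @param min_bp Minimum overlap in bp.
#' @return A list with `hit` (logical, in query order) and `matches`
#'   (list of matched subject names per query).
#' @export
match_any <- function(queries, subjects, min_bp = 1L) {
  if (min_bp < 1L) stop("min_bp must be >= 1")
  hits <- GenomicRanges::findOverlaps(queries, subjects,
                                      minoverlap = min_bp,
                                      ignore.strand = TRUE)
  hit <- rep(FALSE, length(queries))
  hit[unique(S4Vectors::queryHits(hits))] <- TRUE
  snames <- S4Vectors::mcols(subjects)$name
  if (is.null(snames)) snames <- as.character(seq_along(subjects))
  matches <- split(snames[S4Vectors::subjectHits(hits)],
                   factor(S4Vectors::queryHits(hits),
                          levels = seq_along(queries)))
  names(matches) <- S4Vectors::mcols(queries)$name
  list(hit = hit, matches = matches)
}

#' Read a gene annotation table
#'
#' Expects tab-separated columns `gene`, `chrom`, `tss` (0-based bp) and
#' `strand` (`+`/`-`). TSSs anchor promoter windows and all distance
#' calculations.
#'
#' @param path Input TSV path.
#' @return A data.frame with those four columns.
#' @export
read_gene_annotation <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  validate_gene_annotation(ann)
}

validate_gene_annotation <- function(ann) {
  need <- c("gene", "chrom", "tss", "strand")
  if (!all(need %in% names(ann)))
    stop("gene annotation needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(ann$gene))
    stop("duplicate gene symbols in annotation")
  if (any(ann$tss < 0)) stop("tss must be >= 0")
  if (!all(ann$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  ann
}
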