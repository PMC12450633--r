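#' Genes upregulated in a condition contrast
#'
#' Selects genes passing the upregulation filter in one named contrast of
#' a differential-expression table (for example disease vs. normal cells
#' within a subtype).
#'
#' @param degs Data frame with columns `gene`, `avg_log2FC`, `p_val`,
#'   `contrast`.
#' @param contrast Contrast label to select.
#' @param fc_min Lower bound (exclusive) on `avg_log2FC` (default 0).
#' @param p_max Upper bound (exclusive) on `p_val` (default 0.05).
#' @return Character vector of gene symbols (sorted, unique).
#' @export
upregulated_in_condition <- function(degs, contrast, fc_min = 0,
                                     p_max = 0.05) {
  if (!"contrast" %in% names(degs))
    stop("DEG table has no 'contrast' column")
  rows <- degs[degs$contrast == contrast, , drop = FALSE]
  if (nrow(rows) == 0L) stop("contrast not present in table: ", contrast)
  sort(unique(rows$gene[rows$avg_log2FC > fc_min & rows$p_val < p_max]))
}

#' Exclusive-region Venn counts for named sets
#'
#' Enumerates every non-empty combination of the input sets and counts the
#' elements belonging to exactly that combination. Region counts therefore
#' sum to the size of the union (inclusion-exclusion consistency).
#'
#' @param sets Named list of character vectors.
#' @return Data frame with columns `region` (set names joined by `&`) and
#'   `count`.
#' @export
venn_counts <- function(sets) {
  stopifnot(length(sets) >= 1L, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  key <- apply(member, 1L, function(r)
    paste(names(sets)[r], collapse = "&"))
  combos <- unlist(lapply(seq_along(sets), function(m)
    utils::combn(names(sets), m, paste, collapse = "&", simplify = FALSE)))
  counts <- table(factor(key, levels = combos))
  data.frame(region = names(counts), count = as.integer(counts),
             row.names = NULL)
}

#' Condition markers by pathway intersection
#'
#' Marker genes are the intersection of the condition-upregulated gene set
#' with the union of the supplied pathway gene sets; the full Venn
#' breakdown across upregulated-plus-pathway sets is reported alongside.
#'
#' @param upregulated Character vector of upregulated genes.
#' @param pathways Named list of pathway gene sets (character vectors).
#' @param ignore_case Uppercase all symbols before matching (default
#'   `FALSE`; matching is exact and case-sensitive).
#' @return List with `markers` (sorted character vector) and `venn`
#'   (data frame from [venn_counts()] over upregulated + each pathway).
#' @export
intersect_with_pathways <- function(upregulated, pathways,
                                    ignore_case = FALSE) {
  stopifnot(is.list(pathways), !is.null(names(pathways)))
  if (ignore_case) {
    upregulated <- toupper(upregulated)
    pathways <- lapply(pathways, toupper)
  }
  pool <- unique(unlist(pathways, use.names = FALSE))
  markers <- sort(intersect(unique(upregulated), pool))
  venn <- venn_counts(c(list(upregulated = upregulated), pathways))
  list(markers = markers, venn = venn)
}

#' Read pathway gene sets
#'
#' Supports GMT (one pathway per line: id, description, genes...) and
#' two-column TSV (`pathway_id`, `gene`).
#'
#' @param path Input file.
#' @param format `"gmt"` or `"tsv"`.
#' @return Named list of character vectors.
#' @export
read_pathways <- function(path, format = c("gmt", "tsv")) {
  format <- match.arg(format)
  if (format == "gmt") {
    fields <- strsplit(readLines(path), "\t", fixed = TRUE)
    fields <- fields[lengths(fields) >= 3L]
    sets <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(sets) <- vapply(fields, `[[`, character(1), 1L)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    sets <- split(tab$gene, tab$pathway_id)
    sets <- lapply(sets, unique)
  }
  if (any(lengths(sets) == 0L)) stop("empty pathway gene set in ", path)
  sets
}
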