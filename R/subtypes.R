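#' Top upregulated genes of a cluster
#'
#' Applies the upregulation filter (`avg_log2FC > fc_min`, `p_val < p_max`)
#' to one cluster's differential-expression records, sorts the survivors by
#' `avg_log2FC` descending (ties broken by gene symbol ascending) and keeps
#' the first `k`. These per-cluster gene sets feed the Jaccard similarity.
#'
#' @param degs Data frame with columns `gene`, `cluster`, `avg_log2FC`,
#'   `p_val` (and optionally `contrast`).
#' @param cluster Cluster id to extract.
#' @param k Maximum set size (default 20).
#' @param fc_min Lower bound (exclusive) on `avg_log2FC` (default 0).
#' @param p_max Upper bound (exclusive) on `p_val` (default 0.05).
#' @return Character vector of at most `k` gene symbols, in rank order.
#' @export
top_upregulated <- function(degs, cluster, k = 20L, fc_min = 0,
                            p_max = 0.05) {
  validate_degs(degs)
  rows <- degs[degs$cluster == cluster, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("cluster not present in DEG table: ", cluster)
  pass <- rows[rows$avg_log2FC > fc_min & rows$p_val < p_max, , drop = FALSE]
  ord <- order(-pass$avg_log2FC, pass$gene)
  utils::head(pass$gene[ord], k)
}

validate_degs <- function(degs) {
  need <- c("gene", "cluster", "avg_log2FC", "p_val")
  if (!all(need %in% names(degs)))
    stop("DEG table needs columns: ", paste(need, collapse = ", "))
  if (any(degs$p_val < 0 | degs$p_val > 1, na.rm = TRUE))
    stop("p_val must lie in [0, 1]")
  invisible(degs)
}

#' Top gene sets for every cluster in a DEG table
#'
#' @inheritParams top_upregulated
#' @return Named list of character vectors, one per cluster, ordered by
#'   cluster id.
#' @export
cluster_gene_sets <- function(degs, k = 20L, fc_min = 0, p_max = 0.05) {
  validate_degs(degs)
  clusters <- sort(unique(degs$cluster))
  sets <- lapply(clusters, function(cl)
    top_upregulated(degs, cl, k = k, fc_min = fc_min, p_max = p_max))
  names(sets) <- clusters
  sets
}

#' Jaccard similarity of two gene sets
#'
#' `|a intersect b| / |a union b|`. Two empty sets have undefined
#' similarity; it is reported as 0 with a warning.
#'
#' @param a,b Character vectors (treated as sets).
#' @return Similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) {
    warning("Jaccard of two empty sets is undefined; returning 0")
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Pairwise Jaccard matrix over cluster gene sets
#'
#' @param gene_sets Named list of character vectors (>= 2 entries), as
#'   produced by [cluster_gene_sets()].
#' @return Symmetric numeric matrix with cluster ids as dimnames.
#' @export
jaccard_matrix <- function(gene_sets) {
  n <- length(gene_sets)
  if (n < 2L) stop("need at least 2 clusters for a similarity matrix")
  ids <- names(gene_sets)
  J <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n) {
    v <- jaccard(gene_sets[[i]], gene_sets[[j]])
    J[i, j] <- v
    J[j, i] <- v
  }
  J
}

#' Merge clusters into subtypes by similarity
#'
#' Clusters whose similarity to every other cluster is exactly 0 are set
#' aside as `excluded` (they share no top genes with anything, so they are
#' not part of the hepatocyte continuum). The remaining clusters are
#' clustered agglomeratively on distance `1 - J` with complete linkage and
#' the tree is cut into `n_subtypes` groups. Labels `Subtype_1, Subtype_2,
#' ...` are assigned in decreasing group size, ties broken by the smallest
#' member cluster id, so output labels are deterministic.
#'
#' @param J Symmetric Jaccard matrix with cluster ids as dimnames.
#' @param n_subtypes Number of groups to cut (default 2).
#' @return Named character vector mapping each cluster to its subtype
#'   label or `"excluded"`.
#' @export
merge_subtypes <- function(J, n_subtypes = 2L) {
  stopifnot(is.matrix(J), nrow(J) == ncol(J),
            !is.null(rownames(J)), n_subtypes >= 1L)
  if (max(abs(J - t(J))) > 1e-12) stop("similarity matrix not symmetric")
  ids <- rownames(J)
  off <- J
  diag(off) <- 0
  excluded <- ids[apply(off, 1L, max) == 0]
  keep <- setdiff(ids, excluded)
  if (length(keep) == 0L) stop("no mergeable structure: all clusters ",
                               "mutually zero-similar")
  if (length(keep) < n_subtypes)
    stop("fewer mergeable clusters (", length(keep),
         ") than requested subtypes (", n_subtypes, ")")
  Jk <- J[keep, keep, drop = FALSE]
  groups <- if (length(keep) == n_subtypes) {
    stats::setNames(seq_along(keep), keep)
  } else {
    hc <- stats::hclust(stats::as.dist(1 - Jk), method = "complete")
    stats::cutree(hc, k = n_subtypes)
  }
  sizes <- table(groups)
  first_member <- vapply(names(sizes), function(g)
    min(names(groups)[groups == g]), character(1))
  rank <- order(-as.integer(sizes), first_member)
  relabel <- stats::setNames(sprintf("Subtype_%d", seq_along(rank)),
                             names(sizes)[rank])
  out <- stats::setNames(rep("excluded", length(ids)), ids)
  out[names(groups)] <- relabel[as.character(groups)]
  out
}

#' Condition composition of cell groups
#'
#' Counts cells per group and condition and reports within-group
#' condition fractions — the quantity behind statements like "disease
#' cells account for 85.3% of the subtype".
#'
#' @param cells Data frame with columns `cell_id`, `condition` and the
#'   grouping column.
#' @param group Name of the grouping column (default `"cluster"`).
#' @return Data frame: one row per (group, condition) with `n` and
#'   `fraction` (within group).
#' @export
condition_composition <- function(cells, group = "cluster") {
  stopifnot(all(c(group, "condition") %in% names(cells)))
  tab <- as.data.frame(table(cells[[group]], cells$condition),
                       stringsAsFactors = FALSE)
  names(tab) <- c(group, "condition", "n")
  totals <- tapply(tab$n, tab[[group]], sum)
  tab$fraction <- tab$n / as.numeric(totals[tab[[group]]])
  tab[order(tab[[group]], tab$condition), , drop = FALSE]
}

#' Read a DEG table from TSV
#'
#' @param path Tab-separated file with header columns `gene`, `cluster`,
#'   `avg_log2FC`, `p_val` and optionally `contrast`.
#' @return Validated data.frame.
#' @export
read_deg_table <- function(path) {
  degs <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = NA)
  degs$cluster <- as.character(degs$cluster)
  validate_degs(degs)
  degs
}
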