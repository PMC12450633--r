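# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's overlap engine and
# statistics so they can serve as cross-checks.

# All-pairs overlap oracle: per-query hit against every subject,
# computed with plain coordinate arithmetic (0-based half-open).
oracle_match_any <- function(q_chrom, q_start, q_end,
                             s_chrom, s_start, s_end, min_bp = 1L) {
  if (length(s_chrom) == 0L) return(rep(FALSE, length(q_chrom)))
  vapply(seq_along(q_chrom), function(i) {
    same <- s_chrom == q_chrom[i]
    ov <- pmin(s_end, q_end[i]) - pmax(s_start, q_start[i])
    any(same & ov >= min_bp)
  }, logical(1))
}

random_intervals <- function(n, chroms = c("chr1", "chr2", "chr3"),
                             max_pos = 10000L) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(200L, n, replace = TRUE)
  list(chrom = chrom, start = start, end = start + width)
}

# Pearson chi-squared from first principles (margins -> expected -> sum).
oracle_chisq <- function(m) {
  exp <- outer(rowSums(m), colSums(m)) / sum(m)
  list(statistic = sum((m - exp)^2 / exp),
       df = (nrow(m) - 1L) * (ncol(m) - 1L))
}

# Exact hypergeometric upper tail P(X >= k) by combinatorial sum.
oracle_hyper_tail <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Naive complete-linkage agglomeration on distance 1 - J, stopped at
# n_groups clusters; returns the partition as a list of member sets.
oracle_complete_linkage <- function(J, n_groups) {
  D <- 1 - J
  groups <- as.list(rownames(J))
  while (length(groups) > n_groups) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(groups)) for (b in seq_along(groups)) {
      if (a >= b) next
      d <- max(D[groups[[a]], groups[[b]]])
      if (d < best_d) { best_d <- d; best <- c(a, b) }
    }
    groups[[best[1L]]] <- c(groups[[best[1L]]], groups[[best[2L]]])
    groups[[best[2L]]] <- NULL
  }
  lapply(groups, sort)
}

# Canonical form of a cluster->label assignment: the set of groups.
partition_groups <- function(assignment) {
  labs <- setdiff(unique(assignment), "excluded")
  unname(lapply(sort(labs), function(l)
    sort(names(assignment)[assignment == l])))
}

same_partition <- function(a, b) {
  setequal(lapply(a, paste, collapse = ","),
           lapply(b, paste, collapse = ","))
}

# Small DEG table builder: one cluster's records with given stats.
deg_rows <- function(cluster, genes, fc, p,
                     contrast = "cluster_vs_rest") {
  data.frame(gene = genes, cluster = cluster, avg_log2FC = fc,
             p_val = p, contrast = contrast, stringsAsFactors = FALSE)
}

# Shared small fixture config: two-block-plus-outlier structure at the
# scale used throughout the unit tests (fast, same planted properties).
small_config <- function(seed = 1L, ...) {
  defaults <- list(
    seed = seed,
    blocks = list(A = c("C0", "C3", "C8"), B = c("C1", "C4")),
    outlier = "C9",
    condition_fractions = c(A = 0.853, B = 0.12, outlier = 0.5),
    n_genes = 400L,
    cells_per_cluster = 80L,
    n_atac_peaks = 400L,
    category_probs = list(
      HTN = c(Promoter = 0.3, Distal = 0.25, Exonic = 0.15,
              Intronic = 0.3),
      normal = c(Promoter = 0.2, Distal = 0.3, Exonic = 0.2,
                 Intronic = 0.3)),
    planted_promoter_rate = c(HTN = 0.5, normal = 0.5),
    planted_enhancer_rate = c(HTN = 0.2, normal = 0.1),
    n_inferred = 40L, n_curated_supported = 25L, n_triple = 15L)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}
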