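# Region-specific ECM program discovery ("epi-groups"): LRT-significant
# matrisome genes are hierarchically clustered (1 - Spearman distance,
# complete linkage), the dendrogram is cut to K groups, and each group's
# "relatively high expression" regions are labeled by an optimal two-means
# partition of the five per-region mean z-scores.

#' Select differentially expressed ECM genes
#'
#' Matrisome genes with multi-group LRT `padj < alpha` (default 0.001).
#'
#' @param de Result of [de_lrt()] across the epithelial populations.
#' @param catalogue Matrisome catalogue tibble.
#' @param alpha Adjusted-p threshold.
#' @return Character vector of selected symbols.
#' @export
select_de_ecm_genes <- function(de, catalogue, alpha = 0.001) {
  cls <- classify_symbol(catalogue, de$gene)
  sel <- de$gene[de$padj < alpha & cls != "non-matrisome"]
  if (!length(sel)) {
    abort(sprintf(
      "no matrisome gene reached padj < %g; consider a larger alpha", alpha
    ))
  }
  sel
}

#' Hierarchically cluster genes into K groups
#'
#' Agglomerative clustering of gene expression profiles with distance
#' Euclidean distance between gene rows (configurable to `1 - Spearman
#' rho`) and
#' complete linkage; the tree is cut to exactly `k` clusters.
#'
#' @param z Z-scored expression tibble restricted to the selected genes.
#' @param k Number of clusters.
#' @param metric `"euclidean"` (default; stable for few-replicate
#'   designs) or `"spearman"`.
#' @return Tibble with columns `gene` and `group` (1..k).
#' @export
cluster_genes <- function(z, k, metric = c("euclidean", "spearman")) {
  metric <- match.arg(metric)
  m <- as_gene_matrix(z)
  if (nrow(m) < k) {
    abort(sprintf("%d genes cannot be cut into %d clusters", nrow(m), k))
  }
  d <- if (metric == "spearman") {
    as.dist(1 - suppressWarnings(cor(t(m), method = "spearman")))
  } else {
    stats::dist(m)
  }
  if (any(is.na(d))) abort("undefined gene-gene distances (constant profiles)")
  hc <- hclust(d, method = "complete")
  tibble(gene = rownames(m), group = unname(cutree(hc, k = k)))
}

#' Optimal two-means partition of scalars
#'
#' Exhaustively evaluates every threshold split of the sorted values and
#' returns the partition minimizing the within-cluster sum of squares - the
#' global optimum of k-means with k = 2 in one dimension, deterministic and
#' free of initialization effects. Ties in WCSS are broken toward the
#' partition with the smaller high cluster (more region-specific label).
#'
#' @param x Named numeric vector (at least 2 values, not all equal).
#' @return Logical vector (same names/order as `x`): `TRUE` for the
#'   high-mean cluster.
#' @export
split_two_means <- function(x) {
  if (length(x) < 2) abort("need at least 2 values to split")
  if (length(unique(x)) == 1) abort("no region specificity: all values equal")
  ord <- order(x, decreasing = TRUE)
  best <- NULL
  best_wcss <- Inf
  for (s in seq_len(length(x) - 1)) {
    hi <- ord[seq_len(s)]
    lo <- ord[-seq_len(s)]
    wcss <- sum((x[hi] - mean(x[hi]))^2) + sum((x[lo] - mean(x[lo]))^2)
    if (wcss < best_wcss - 1e-12) {
      best_wcss <- wcss
      best <- hi
    }
  }
  out <- seq_along(x) %in% best
  names(out) <- names(x)
  out
}

#' Label the high-expression regions of each gene cluster
#'
#' For each cluster, the per-population mean z-score (replicates averaged,
#' then averaged over cluster genes) is computed and the populations are
#' split by [split_two_means()]; the cluster with the larger mean is the set
#' of regions with relatively high expression.
#'
#' @param z Z-scored expression tibble.
#' @param clusters Tibble from [cluster_genes()].
#' @param samples Sample sheet tibble.
#' @param populations Populations to label over (default the five epithelial
#'   populations present in the data).
#' @return Tibble with columns `group`, `population`, `mean_z`, `high`.
#' @export
label_high_regions <- function(z, clusters, samples,
                               populations = NULL) {
  m <- as_gene_matrix(z)
  check_samples(samples, colnames(m))
  pops <- samples$population[match(colnames(m), samples$sample_id)]
  populations <- populations %||%
    intersect(epithelial_populations(), unique(pops))
  rows <- lapply(sort(unique(clusters$group)), function(g) {
    genes <- clusters$gene[clusters$group == g]
    sub <- m[rownames(m) %in% genes, , drop = FALSE]
    mu <- vapply(populations, function(p) {
      mean(rowMeans(sub[, pops == p, drop = FALSE]))
    }, numeric(1))
    hi <- split_two_means(mu)
    tibble(group = g, population = populations, mean_z = unname(mu),
           high = unname(hi))
  })
  bind_rows(rows)
}

pattern_code <- function(populations, high) {
  paste(sort(populations[high]), collapse = "+")
}

#' Discover epi-groups end to end
#'
#' Convenience wrapper: size-normalize, run the multi-group LRT across the
#' epithelial populations, select matrisome genes at `padj < alpha`, z-score
#' their log2 profiles over the epithelial samples, cluster to `k` groups and
#' label each group's high-expression regions.
#'
#' @param counts Wide counts tibble.
#' @param samples Sample sheet tibble.
#' @param catalogue Matrisome catalogue tibble.
#' @param k Number of epi-groups (default 10).
#' @param alpha LRT adjusted-p selection threshold (default 0.001).
#' @param populations Epithelial populations to analyze.
#' @param metric Gene-gene clustering distance, see [cluster_genes()].
#' @return An `ecm_epigroups` object with components `genes` (gene, group,
#'   pattern), `regions` (group, population, mean_z, high), `de` (the LRT
#'   table) and the call parameters. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
epigroups <- function(counts, samples, catalogue, k = 10, alpha = 0.001,
                      populations = epithelial_populations(),
                      metric = "euclidean") {
  m <- as_gene_matrix(counts)
  check_samples(samples, colnames(m))
  pops <- samples$population[match(colnames(m), samples$sample_id)]
  keep <- pops %in% populations
  sub_counts <- counts[, c("gene", colnames(m)[keep])]
  sub_samples <- samples[samples$sample_id %in% colnames(m)[keep], ]

  de <- de_lrt(sub_counts, sub_samples, populations)
  sel <- select_de_ecm_genes(de, catalogue, alpha = alpha)

  z <- sub_counts |>
    normalize_counts() |>
    log_transform() |>
    zscore_genes()
  zsel <- z[casefold(z$gene) %in% casefold(sel), , drop = FALSE]
  zsel <- set_stage(zsel, "zscore")

  clusters <- cluster_genes(zsel, k = k, metric = metric)
  regions <- label_high_regions(zsel, clusters, sub_samples,
                                populations = populations)
  patterns <- regions |>
    group_by(.data$group) |>
    summarise(pattern = pattern_code(.data$population, .data$high),
              .groups = "drop")
  genes <- clusters |> left_join(patterns, by = "group")

  structure(
    list(genes = genes, regions = regions, de = de, k = k, alpha = alpha,
         populations = populations, metric = metric),
    class = "ecm_epigroups"
  )
}

#' @export
print.ecm_epigroups <- function(x, ...) {
  cat(sprintf("<ecm_epigroups> %d genes in %d groups (padj < %g)\n",
              nrow(x$genes), x$k, x$alpha))
  pat <- x$genes |> dplyr::count(.data$group, .data$pattern)
  print(as.data.frame(pat), row.names = FALSE)
  invisible(x)
}

#' @method tidy ecm_epigroups
#' @export
tidy.ecm_epigroups <- function(x, ...) x$genes

#' @method glance ecm_epigroups
#' @export
glance.ecm_epigroups <- function(x, ...) {
  tibble(k = x$k, n_genes = nrow(x$genes), alpha = x$alpha,
         n_patterns = dplyr::n_distinct(x$genes$pattern))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items
#' (delegates to [mclust::adjustedRandIndex()]).
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in `[-1, 1]`; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("labelings must have equal length")
  mclust::adjustedRandIndex(a, b)
}

#' Score epi-group recovery against planted truth
#'
#' Compares a discovered epi-grouping with the simulator's planted programs:
#' the ARI between gene partitions (over planted genes present in the
#' result) and the fraction of planted genes whose discovered high-region
#' pattern equals the planted epithelial target pattern.
#'
#' @param epi An `ecm_epigroups` object.
#' @param truth Truth tibble from the simulator (columns `gene`, `program`,
#'   `pattern`).
#' @return Tibble with columns `ari`, `label_accuracy`, `n_truth`,
#'   `n_recovered`.
#' @export
recovery_score <- function(epi, truth) {
  joined <- truth |>
    dplyr::inner_join(epi$genes, by = "gene", suffix = c("_true", ""))
  if (!nrow(joined)) {
    return(tibble(ari = NA_real_, label_accuracy = NA_real_,
                  n_truth = nrow(truth), n_recovered = 0L))
  }
  tibble(
    ari = adjusted_rand_index(joined$program, joined$group),
    label_accuracy = mean(joined$pattern == joined$pattern_true),
    n_truth = nrow(truth),
    n_recovered = nrow(joined)
  )
}
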