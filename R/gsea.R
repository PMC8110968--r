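# Weighted running-sum gene-set enrichment with gene-set permutation
# significance. With n = 3 replicates per group only 10 distinct phenotype
# label splits exist, so the null is built by permuting gene sets, the
# standard fallback for small designs.

#' Rank genes by signal-to-noise
#'
#' Per-gene metric `(mean_A - mean_B) / (sd_A + sd_B)` on size-normalized
#' counts, with each SD floored at `0.2 * |mean|` (the usual convention to
#' damp low-variance genes). Genes are sorted by descending metric, ties
#' broken lexicographically by symbol.
#'
#' @param nm Size-normalized matrix tibble.
#' @param samples Sample sheet tibble.
#' @param group_a,group_b Population labels (each with >= 2 replicates).
#' @return Tibble with columns `gene`, `metric`, ordered head-to-tail.
#' @export
rank_signal_to_noise <- function(nm, samples, group_a, group_b) {
  check_stage(nm, "size_normalized", "rank_signal_to_noise")
  m <- as_gene_matrix(nm)
  check_samples(samples, colnames(m))
  pops <- samples$population[match(colnames(m), samples$sample_id)]
  ia <- pops == group_a
  ib <- pops == group_b
  if (sum(ia) < 2 || sum(ib) < 2) {
    abort("signal-to-noise needs at least 2 replicates per group")
  }
  s2n <- apply(m, 1, function(x) {
    ma <- mean(x[ia]); mb <- mean(x[ib])
    sa <- max(sd(x[ia]), 0.2 * abs(ma))
    sb <- max(sd(x[ib]), 0.2 * abs(mb))
    denom <- sa + sb
    if (denom == 0) 0 else (ma - mb) / denom
  })
  tibble(gene = rownames(m), metric = unname(s2n)) |>
    arrange(dplyr::desc(.data$metric), .data$gene)
}

#' Running-sum enrichment score
#'
#' Walks the ranked list top to bottom; set members ("hits") increment the
#' running sum by `|metric|^weight` normalized over all hits, non-members
#' decrement by `1 / (N - n_hits)`. The enrichment score is the running-sum
#' value of maximum absolute deviation from zero (signed); an exact tie
#' between the positive and negative extremes is broken toward the positive
#' deviation.
#'
#' @param ranked Tibble from [rank_signal_to_noise()] (columns `gene`,
#'   `metric`).
#' @param gene_set Character vector of symbols (case-insensitive; must
#'   overlap the list).
#' @param weight Exponent on `|metric|` for hit increments (default 1;
#'   0 gives the unweighted Kolmogorov-Smirnov-like statistic).
#' @return List with elements `es` (scalar in `[-1, 1]`) and `running`
#'   (tibble `gene`, `position`, `hit`, `running_sum`).
#' @export
gsea_es <- function(ranked, gene_set, weight = 1) {
  genes <- ranked$gene
  n <- length(genes)
  hit <- casefold(genes) %in% casefold(gene_set)
  nh <- sum(hit)
  if (nh == 0) abort("gene set has no overlap with the ranked list")
  if (nh == n) abort("gene set covers the whole ranked list")
  w <- abs(ranked$metric)^weight
  denom_hit <- sum(w[hit])
  inc <- numeric(n)
  if (denom_hit > 0) {
    inc[hit] <- w[hit] / denom_hit
  } else {
    inc[hit] <- 1 / nh  # all-zero metrics: fall back to equal hit weights
  }
  inc[!hit] <- -1 / (n - nh)
  running <- cumsum(inc)
  mx <- max(running)
  mn <- min(running)
  es <- if (mx >= -mn - 1e-12) mx else mn
  list(
    es = es,
    running = tibble(gene = genes, position = seq_len(n), hit = hit,
                     running_sum = running)
  )
}

#' Permutation GSEA over one or more gene sets
#'
#' Builds a null from `n_perm` random gene sets of matching size drawn from
#' the ranked list, then reports for each tested set the enrichment score
#' (ES), the normalized ES (ES divided by the mean |null ES| of the same
#' sign), the nominal p (fraction of same-sign null ES at least as extreme)
#' and an FDR q computed from the pooled null NES distribution across all
#' tested sets. A set is significant when FDR < 25% and nominal p < 5%.
#'
#' @param ranked Tibble from [rank_signal_to_noise()].
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param n_perm Number of gene-set permutations (>= 100).
#' @param weight ES weight, see [gsea_es()].
#' @param seed Integer seed; results are deterministic given the seed.
#' @return An `ecm_gsea` object whose `table` is a tibble with columns
#'   `set`, `size`, `es`, `nes`, `p_value`, `fdr_q`, `significant`.
#' @export
run_gsea <- function(ranked, gene_sets, n_perm = 1000, weight = 1,
                     seed = 1L) {
  if (n_perm < 100) abort("n_perm must be at least 100")
  if (is.null(names(gene_sets)) || any(names(gene_sets) == "")) {
    abort("gene_sets must be a named list")
  }
  genes <- ranked$gene
  obs <- lapply(gene_sets, function(s) gsea_es(ranked, s, weight = weight))
  sizes <- vapply(gene_sets, function(s) {
    sum(casefold(genes) %in% casefold(s))
  }, integer(1))

  null_by_size <- withr::with_seed(seed, {
    lapply(unique(sizes), function(sz) {
      vapply(seq_len(n_perm), function(i) {
        gsea_es(ranked, sample(genes, sz), weight = weight)$es
      }, numeric(1))
    }) |> setNames(as.character(unique(sizes)))
  })

  norm_es <- function(es, null) {
    same <- null[sign(null) == sign(es) & null != 0]
    if (!length(same)) return(NA_real_)
    es / mean(abs(same))
  }
  res <- purrr::imap(obs, function(o, nm) {
    null <- null_by_size[[as.character(sizes[[nm]])]]
    same <- null[sign(null) == sign(o$es) & null != 0]
    p <- if (length(same)) mean(abs(same) >= abs(o$es)) else 1 / n_perm
    tibble(set = nm, size = sizes[[nm]], es = o$es,
           nes = norm_es(o$es, null), p_value = p)
  }) |> bind_rows()

  # FDR over the pooled null NES distribution
  null_nes <- unlist(lapply(names(null_by_size), function(sz) {
    null <- null_by_size[[sz]]
    vapply(null, norm_es, numeric(1), null = null)
  }))
  null_nes <- null_nes[is.finite(null_nes)]
  obs_nes <- res$nes
  res$fdr_q <- vapply(obs_nes, function(ns) {
    if (!is.finite(ns)) return(NA_real_)
    if (ns >= 0) {
      num <- mean(null_nes >= ns)
      den <- mean(obs_nes >= ns)
    } else {
      num <- mean(null_nes <= ns)
      den <- mean(obs_nes <= ns)
    }
    if (den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))
  res$significant <- !is.na(res$fdr_q) & res$fdr_q < 0.25 &
    res$p_value < 0.05

  structure(
    list(table = res, ranked = ranked, gene_sets = gene_sets,
         weight = weight, n_perm = n_perm, seed = seed),
    class = "ecm_gsea"
  )
}

#' @export
print.ecm_gsea <- function(x, ...) {
  cat(sprintf("<ecm_gsea> %d set(s), %d permutations (gene-set mode)\n",
              nrow(x$table), x$n_perm))
  print(as.data.frame(x$table), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @method tidy ecm_gsea
#' @export
tidy.ecm_gsea <- function(x, ...) x$table

#' @method glance ecm_gsea
#' @export
glance.ecm_gsea <- function(x, ...) {
  tibble(n_sets = nrow(x$table), n_perm = x$n_perm, weight = x$weight,
         n_significant = sum(x$table$significant, na.rm = TRUE))
}

#' Read / write GMT gene-set files
#'
#' GMT format: one set per line, `name<TAB>description<TAB>symbol...`.
#'
#' @param path File path.
#' @return `read_gmt()`: a named list of symbol vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) abort("malformed GMT line (need name, description, >=1 symbol)")
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  out
}

#' @rdname read_gmt
#' @param gene_sets Named list of symbol vectors.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
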