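# Sample-pairwise Spearman correlation on gene subsets (the correlation
# heatmap panel: all / matrisome / non-matrisome / BM / interstitial genes).

#' Sample-pairwise Spearman correlation on a gene subset
#'
#' Spearman's rank correlation (average ranks for ties) between every pair of
#' samples, computed over the given gene rows. A sample whose restricted
#' expression vector has zero variance yields undefined correlations, which
#' are recorded as `NA` with a warning rather than coerced to 0.
#'
#' @param nm Expression matrix tibble (log2 stage by default in the panel;
#'   any stage is accepted since Spearman is rank-based).
#' @param samples Sample sheet tibble.
#' @param gene_set Optional character vector of symbols to restrict to
#'   (case-insensitive); default all genes. At least 3 genes must overlap the
#'   matrix.
#' @param tag Label stored with the result (e.g. `"matrisome"`).
#' @return An `ecm_cor` object: the rho matrix plus sample metadata and the
#'   gene-set tag. Use [tidy()] for a long tibble and [autoplot()] for a
#'   heatmap.
#' @export
cor_samples <- function(nm, samples, gene_set = NULL, tag = "all") {
  m <- as_gene_matrix(nm)
  check_samples(samples, colnames(m))
  if (!is.null(gene_set)) {
    keep <- casefold(rownames(m)) %in% casefold(gene_set)
    if (sum(keep) < 3) {
      abort(sprintf(
        "gene set '%s' overlaps the matrix in %d gene(s); at least 3 required",
        tag, sum(keep)
      ))
    }
    m <- m[keep, , drop = FALSE]
  } else if (nrow(m) < 3) {
    abort(sprintf("gene set '%s' has fewer than 3 genes", tag))
  }
  zero_var <- apply(m, 2, function(x) length(unique(x)) == 1)
  rho <- suppressWarnings(cor(m, method = "spearman"))
  if (any(zero_var)) {
    warn(sprintf(
      "%d sample(s) have zero variance on gene set '%s'; their correlations are NA",
      sum(zero_var), tag
    ))
    rho[zero_var, ] <- NA_real_
    rho[, zero_var] <- NA_real_
  }
  diag(rho) <- 1
  structure(
    list(rho = rho,
         samples = samples[match(colnames(m), samples$sample_id), ],
         tag = tag, n_genes = nrow(m)),
    class = "ecm_cor"
  )
}

#' @export
print.ecm_cor <- function(x, ...) {
  cat(sprintf("<ecm_cor> gene set '%s' (%d genes), %d samples\n",
              x$tag, x$n_genes, ncol(x$rho)))
  invisible(x)
}

#' @describeIn cor_samples Long-format tibble of pairwise correlations with
#'   population labels.
#' @param x An `ecm_cor` object.
#' @param ... Unused.
#' @method tidy ecm_cor
#' @export
tidy.ecm_cor <- function(x, ...) {
  rho <- x$rho
  out <- as_tibble(as.data.frame.table(rho, responseName = "rho",
                                       stringsAsFactors = FALSE))
  names(out)[1:2] <- c("sample_a", "sample_b")
  out |>
    left_join(x$samples |> select("sample_id", pop_a = "population"),
              by = c(sample_a = "sample_id")) |>
    left_join(x$samples |> select("sample_id", pop_b = "population"),
              by = c(sample_b = "sample_id")) |>
    mutate(gene_set = x$tag)
}

#' Mean and SD of correlations per population pair
#'
#' For every unordered pair of populations (including within-population
#' pairs), summarizes the sample-pair correlations: self-pairs (the diagonal)
#' are excluded, each unordered sample pair is counted once, and the spread
#' is the sample SD (n - 1 denominator), matching the mean +/- SD reporting
#' convention.
#'
#' @param cm An `ecm_cor` object.
#' @return Tibble with columns `group_a`, `group_b`, `mean_rho`, `sd_rho`,
#'   `n_pairs`.
#' @export
summarize_group_pairs <- function(cm) {
  stopifnot(inherits(cm, "ecm_cor"))
  rho <- cm$rho
  pops <- cm$samples$population
  n <- ncol(rho)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pair <- sort(c(pops[i], pops[j]))
      rows[[length(rows) + 1]] <- tibble(
        group_a = pair[1], group_b = pair[2], rho = rho[i, j]
      )
    }
  }
  bind_rows(rows) |>
    group_by(.data$group_a, .data$group_b) |>
    summarise(
      mean_rho = mean(.data$rho),
      sd_rho = if (n() > 1) sd(.data$rho) else 0,
      n_pairs = n(),
      .groups = "drop"
    )
}

#' Gene-set-wise correlation panel
#'
#' Runs [cor_samples()] for the five canonical gene sets: all (expressed)
#' genes, matrisome, non-matrisome, BM and interstitial. The matrisome and
#' non-matrisome sets partition the expressed genes; BM and interstitial
#' partition the matrisome.
#'
#' @param nm Expression matrix tibble (log2 values by default upstream).
#' @param samples Sample sheet tibble.
#' @param catalogue Matrisome catalogue tibble.
#' @return An `ecm_cor_panel`: a named list of `ecm_cor` objects sharing the
#'   sample ordering.
#' @export
correlation_panel <- function(nm, samples, catalogue) {
  catalogue <- validate_matrisome(catalogue)
  genes <- as_gene_matrix(nm) |> rownames()
  cls <- classify_symbol(catalogue, genes)
  sets <- list(
    all = genes,
    matrisome = genes[cls != "non-matrisome"],
    `non-matrisome` = genes[cls == "non-matrisome"],
    BM = genes[cls == "BM"],
    interstitial = genes[cls == "interstitial"]
  )
  out <- purrr::imap(sets, function(g, tag) {
    cor_samples(nm, samples, gene_set = g, tag = tag)
  })
  structure(out, class = "ecm_cor_panel")
}

#' @export
print.ecm_cor_panel <- function(x, ...) {
  cat("<ecm_cor_panel>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-14s %d genes\n", nm, x[[nm]]$n_genes))
  }
  invisible(x)
}

#' @method tidy ecm_cor_panel
#' @export
tidy.ecm_cor_panel <- function(x, ...) {
  bind_rows(lapply(unclass(x), tidy))
}
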