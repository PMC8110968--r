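# Negative-binomial differential expression.
#
# The engine is intentionally simple: group means are fitted in closed form
# on size-normalized counts (the NB mean MLE with fixed dispersion and equal
# size factors), the gene-wise dispersion comes from a method-of-moments
# estimator, and inference uses a Wald z on the log2 fold change (two-group)
# or a likelihood-ratio chi-square (multi-group). No fold-change shrinkage,
# Cook's filtering or independent filtering is performed.

#' Method-of-moments NB dispersion
#'
#' For each gene, within-group mean/variance of size-normalized counts give
#' `alpha = max(0, (s^2 - mu) / mu^2)`, averaged across groups with positive
#' mean. Poisson-like genes (variance equal to the mean) get `alpha = 0`;
#' all-zero genes get `alpha = 0` with flag `all_zero`.
#'
#' @param counts Wide counts tibble.
#' @param samples Sample sheet tibble; `population` defines the groups unless
#'   `groups` is given.
#' @param groups Optional character vector naming, per sample (in count-table
#'   column order), the group each sample belongs to.
#' @param size_factors Optional precomputed size factors.
#' @return Tibble with columns `gene`, `dispersion`, `flag`.
#' @export
estimate_dispersion <- function(counts, samples = NULL, groups = NULL,
                                size_factors = NULL) {
  m <- as_gene_matrix(counts)
  if (is.null(groups)) {
    if (is.null(samples)) abort("either `samples` or `groups` is required")
    check_samples(samples, colnames(m))
    groups <- samples$population[match(colnames(m), samples$sample_id)]
  }
  if (length(groups) != ncol(m)) abort("one group label per sample required")
  if (any(table(groups) < 2)) abort("every group needs at least 2 samples")
  if (is.null(size_factors)) size_factors <- compute_size_factors(counts)
  sf <- size_factors$size_factor[match(colnames(m), size_factors$sample_id)]
  norm <- sweep(m, 2, sf, "/")
  gidx <- split(seq_len(ncol(norm)), groups)
  disp <- apply(norm, 1, function(x) {
    a <- vapply(gidx, function(j) {
      mu <- mean(x[j])
      if (mu <= 0) return(NA_real_)
      max(0, (var(x[j]) - mu) / mu^2)
    }, numeric(1))
    a <- a[!is.na(a)]
    if (!length(a)) NA_real_ else mean(a)
  })
  flag <- unname(ifelse(is.na(disp), "all_zero", ""))
  disp[is.na(disp)] <- 0
  tibble(gene = rownames(m), dispersion = unname(disp), flag = flag)
}

# NB log-likelihood with mean `mu` (per-sample, scaled by size factor) and
# dispersion `alpha`; alpha = 0 falls back to Poisson.
nb_loglik <- function(x, mu, alpha) {
  mu <- pmax(mu, 1e-8)
  if (alpha <= 0) sum(dpois(x, lambda = mu, log = TRUE))
  else sum(dnbinom(x, mu = mu, size = 1 / alpha, log = TRUE))
}

# Moderate per-gene dispersions toward the across-gene pooled mean by taking
# the maximum (conservative; protects n = 3 designs from the severe downward
# bias of per-gene moment estimates).
moderate_dispersions <- function(disp) {
  pooled <- mean(disp, na.rm = TRUE)
  pmax(disp, pooled)
}

#' Two-group NB Wald test
#'
#' Log2 fold changes of `group_a` over `group_b` computed from group means of
#' size-normalized counts, moderated by a pseudocount. The standard error
#' comes from the NB variance `mu + alpha * mu^2` propagated to the log2
#' scale by the delta method; p-values are two-sided normal tails of the Wald
#' z, adjusted by Benjamini-Hochberg within the tested gene family.
#'
#' @param counts Wide counts tibble.
#' @param samples Sample sheet tibble.
#' @param group_a,group_b Population labels to compare (fold change is A over
#'   B).
#' @param genes Optional gene subset defining the multiple-testing family
#'   (e.g. matrisome genes only); default all genes.
#' @param pseudocount Added to both group means before the ratio (default 1).
#' @param moderate_dispersion Moderate gene-wise dispersions toward the
#'   pooled mean (default `TRUE`; see Details in the package vignette).
#' @param dispersion Optional tibble from [estimate_dispersion()]; estimated
#'   from the two groups when omitted.
#' @param size_factors Optional tibble from [compute_size_factors()];
#'   computed from the tested subset when omitted.
#' @return Tibble with columns `gene`, `base_mean`, `log2fc`, `stat`, `df`,
#'   `p`, `padj`, `flag`.
#' @export
de_wald <- function(counts, samples, group_a, group_b, genes = NULL,
                    pseudocount = 1, moderate_dispersion = TRUE,
                    dispersion = NULL, size_factors = NULL) {
  m <- as_gene_matrix(counts)
  check_samples(samples, colnames(m))
  pops <- samples$population[match(colnames(m), samples$sample_id)]
  keep <- pops %in% c(group_a, group_b)
  if (!any(pops == group_a) || !any(pops == group_b)) {
    abort("both comparison groups must be present in the sample sheet")
  }
  sub <- counts[, c("gene", colnames(m)[keep])]
  if (!is.null(genes)) {
    sub <- sub[casefold(sub$gene) %in% casefold(genes), , drop = FALSE]
  }
  msub <- as_gene_matrix(sub)
  gsub <- pops[keep]
  sf_tbl <- size_factors %||% compute_size_factors(sub)
  sf <- sf_tbl$size_factor[match(colnames(msub), sf_tbl$sample_id)]
  norm <- sweep(msub, 2, sf, "/")
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(sub, groups = gsub,
                                      size_factors = sf_tbl)
  }
  disp <- dispersion$dispersion[match(rownames(msub), dispersion$gene)]
  if (moderate_dispersion) disp <- moderate_dispersions(disp)

  ia <- gsub == group_a
  ib <- gsub == group_b
  na <- sum(ia); nb <- sum(ib)
  res <- lapply(seq_len(nrow(msub)), function(i) {
    x <- norm[i, ]
    a <- disp[i]
    ma <- mean(x[ia]); mb <- mean(x[ib])
    base_mean <- mean(x)
    if (ma == 0 && mb == 0) {
      return(tibble(gene = rownames(msub)[i], base_mean = base_mean,
                    log2fc = 0, stat = 0, df = NA_real_, p = 1,
                    flag = "all_zero"))
    }
    l2 <- log2((ma + pseudocount) / (mb + pseudocount))
    # variance of the mean of normalized counts: Var(K/s) = mu/s + alpha*mu^2
    va <- sum(ma / sf[ia] + a * ma^2) / na^2
    vb <- sum(mb / sf[ib] + a * mb^2) / nb^2
    se <- sqrt(va / ((ma + pseudocount) * log(2))^2 +
               vb / ((mb + pseudocount) * log(2))^2)
    z <- if (se > 0) l2 / se else 0
    tibble(gene = rownames(msub)[i], base_mean = base_mean, log2fc = l2,
           stat = z, df = NA_real_, p = 2 * pnorm(-abs(z)), flag = "")
  })
  out <- bind_rows(res)
  out$padj <- bh_adjust(out$p)
  out[, c("gene", "base_mean", "log2fc", "stat", "df", "p", "padj", "flag")]
}

#' Multi-group NB likelihood-ratio test
#'
#' Twice the log-likelihood difference between the per-group-mean and
#' common-mean NB models (dispersion held fixed at its moderated
#' method-of-moments estimate), referred to a chi-square with
#' `n_groups - 1` degrees of freedom.
#'
#' @inheritParams de_wald
#' @param populations Population labels defining the groups (at least 2,
#'   each with at least 2 replicates; typically the five epithelial
#'   populations).
#' @return Tibble with columns `gene`, `base_mean`, `log2fc` (`NA` for the
#'   multi-group test), `stat`, `df`, `p`, `padj`, `flag`.
#' @export
de_lrt <- function(counts, samples, populations, genes = NULL,
                   moderate_dispersion = TRUE, dispersion = NULL,
                   size_factors = NULL) {
  if (length(populations) < 2) abort("the LRT requires at least 2 groups")
  m <- as_gene_matrix(counts)
  check_samples(samples, colnames(m))
  pops <- samples$population[match(colnames(m), samples$sample_id)]
  keep <- pops %in% populations
  sub <- counts[, c("gene", colnames(m)[keep])]
  if (!is.null(genes)) {
    sub <- sub[casefold(sub$gene) %in% casefold(genes), , drop = FALSE]
  }
  msub <- as_gene_matrix(sub)
  gsub <- pops[keep]
  if (any(table(gsub) < 2)) abort("every group needs at least 2 replicates")
  sf_tbl <- size_factors %||% compute_size_factors(sub)
  sf <- sf_tbl$size_factor[match(colnames(msub), sf_tbl$sample_id)]
  norm <- sweep(msub, 2, sf, "/")
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(sub, groups = gsub,
                                      size_factors = sf_tbl)
  }
  disp <- dispersion$dispersion[match(rownames(msub), dispersion$gene)]
  if (moderate_dispersion) disp <- moderate_dispersions(disp)

  gidx <- split(seq_len(ncol(msub)), gsub)
  df <- length(gidx) - 1
  res <- lapply(seq_len(nrow(msub)), function(i) {
    x <- msub[i, ]
    a <- disp[i]
    mu0 <- mean(norm[i, ])
    if (mu0 == 0) {
      return(tibble(gene = rownames(msub)[i], base_mean = 0,
                    log2fc = NA_real_, stat = 0, df = df, p = 1,
                    flag = "all_zero"))
    }
    ll0 <- nb_loglik(x, mu0 * sf, a)
    ll1 <- sum(vapply(gidx, function(j) {
      nb_loglik(x[j], mean(norm[i, j]) * sf[j], a)
    }, numeric(1)))
    stat <- max(0, 2 * (ll1 - ll0))
    tibble(gene = rownames(msub)[i], base_mean = mu0, log2fc = NA_real_,
           stat = stat, df = df,
           p = pchisq(stat, df = df, lower.tail = FALSE), flag = "")
  })
  out <- bind_rows(res)
  out$padj <- bh_adjust(out$p)
  out[, c("gene", "base_mean", "log2fc", "stat", "df", "p", "padj", "flag")]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement, clipped to 1
#' (delegates to [stats::p.adjust()] after validating the input range).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Epithelial-versus-dermal origin calls
#'
#' Applies the published criterion to a Basal versus pan-DF comparison: a
#' gene is `epithelial_enriched` when `padj < padj_threshold` and its fold
#' change toward Basal strictly exceeds `fc_threshold`; `dermal_enriched`
#' symmetrically; otherwise `shared`. The Basal fraction of total normalized
#' counts is attached.
#'
#' @param de Result of [de_wald()] with `group_a = "Basal"`,
#'   `group_b = "panDF"`.
#' @param nm Size-normalized matrix (for the basal fraction).
#' @param samples Sample sheet tibble.
#' @param padj_threshold,fc_threshold Decision thresholds (defaults 0.05 and
#'   4; the fold-change inequality is strict).
#' @return Tibble with columns `gene`, `basal_fraction`, `verdict`.
#' @export
call_origin <- function(de, nm, samples, padj_threshold = 0.05,
                        fc_threshold = 4) {
  check_stage(nm, "size_normalized", "call_origin")
  m <- as_gene_matrix(nm)
  check_samples(samples, colnames(m))
  pops <- samples$population[match(colnames(m), samples$sample_id)]
  bsum <- rowSums(m[, pops == "Basal", drop = FALSE])
  dsum <- rowSums(m[, pops == "panDF", drop = FALSE])
  tot <- bsum + dsum
  frac <- ifelse(tot > 0, bsum / tot, NA_real_)
  frac <- frac[match(de$gene, rownames(m))]
  fc <- 2^de$log2fc
  verdict <- dplyr::case_when(
    de$padj < padj_threshold & fc > fc_threshold ~ "epithelial_enriched",
    de$padj < padj_threshold & 1 / fc > fc_threshold ~ "dermal_enriched",
    TRUE ~ "shared"
  )
  tibble(gene = de$gene, basal_fraction = unname(frac), verdict = verdict)
}
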