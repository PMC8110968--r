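#' Read a gene x sample count table
#'
#' Expects a TSV whose first column is `gene` and whose remaining columns are
#' sample ids holding non-negative integer counts.
#'
#' @param path Counts TSV.
#' @return A wide tibble (`gene` + one column per sample).
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  validate_counts(x)
}

validate_counts <- function(x) {
  m <- as_gene_matrix(x)
  if (any(m < 0)) abort("counts must be non-negative")
  if (any(abs(m - round(m)) > 1e-8)) abort("counts must be integral")
  as_tibble(x)
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `population`, `replicate`. The
#' (population, replicate) pairs must be unique.
#'
#' @param path Sample sheet TSV.
#' @return A tibble of sample metadata.
#' @export
read_samples <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    population = readr::col_character(),
    replicate = readr::col_integer()
  ), progress = FALSE)
  check_samples(x)
  x
}

#' Median-of-ratios size factors
#'
#' Per-sample size factors computed as in the standard RNA-seq
#' median-of-ratios scheme: a per-gene geometric-mean reference is built over
#' genes with all-positive counts, and each sample's factor is the median of
#' its count-to-reference ratios.
#'
#' @param counts Wide counts tibble (`gene` + sample columns).
#' @param pseudo_reference If no gene is positive in every sample the default
#'   is to error; set `TRUE` to fall back to a pseudo-reference built from
#'   positive entries only (geometric mean over samples where the gene is
#'   observed). The fallback changes the estimator, so it must be requested
#'   explicitly.
#' @return A tibble with columns `sample_id` and `size_factor` (all positive).
#' @examples
#' counts <- tibble::tibble(gene = c("g1", "g2", "g3"),
#'                          A = c(10, 20, 30), B = c(20, 40, 60))
#' compute_size_factors(counts)
#' @export
compute_size_factors <- function(counts, pseudo_reference = FALSE) {
  m <- as_gene_matrix(counts)
  if (ncol(m) < 1) abort("no samples in the count table")
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    if (!pseudo_reference) {
      abort(paste0(
        "no gene has positive counts in every sample; rerun with ",
        "pseudo_reference = TRUE to use a positive-entries-only reference"
      ))
    }
    any_pos <- rowSums(m > 0) > 0
    if (!any(any_pos)) abort("all counts are zero; size factors undefined")
    lm <- log(m)
    lm[!is.finite(lm)] <- NA
    ref <- exp(apply(lm[any_pos, , drop = FALSE], 1, mean, na.rm = TRUE))
    sub <- m[any_pos, , drop = FALSE]
  } else {
    sub <- m[all_pos, , drop = FALSE]
    ref <- exp(rowMeans(log(sub)))
  }
  sf <- apply(sub / ref, 2, function(r) median(r[r > 0 & is.finite(r)]))
  if (any(!is.finite(sf) | sf <= 0)) abort("degenerate size factor estimate")
  tibble(sample_id = colnames(m), size_factor = unname(sf))
}

#' Size-normalize a count matrix
#'
#' Divides each sample's counts by its size factor, yielding a matrix at
#' stage `size_normalized`.
#'
#' @param counts Wide counts tibble.
#' @param size_factors Tibble from [compute_size_factors()]; computed from
#'   `counts` when omitted.
#' @return A wide tibble of normalized values carrying stage metadata.
#' @export
normalize_counts <- function(counts, size_factors = NULL) {
  m <- as_gene_matrix(counts)
  if (is.null(size_factors)) size_factors <- compute_size_factors(counts)
  sf <- size_factors$size_factor[match(colnames(m), size_factors$sample_id)]
  if (any(is.na(sf))) abort("size factors missing for some samples")
  if (any(sf <= 0)) abort("size factors must be positive")
  out <- as_gene_tibble(sweep(m, 2, sf, "/"))
  set_stage(out, "size_normalized")
}

#' Log2 transform with pseudocount
#'
#' `log2(value + pseudocount)` on a size-normalized matrix. This is the
#' package's variance-stabilizing stand-in used for clustering and z-scoring;
#' it is monotone in the input, so rank-based statistics are unaffected.
#'
#' @param nm Size-normalized matrix from [normalize_counts()].
#' @param pseudocount Positive offset, default 1.
#' @return A wide tibble at stage `log2`.
#' @export
log_transform <- function(nm, pseudocount = 1) {
  check_stage(nm, "size_normalized", "log_transform")
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    abort("pseudocount must be a positive number")
  }
  m <- as_gene_matrix(nm)
  if (any(m < 0)) abort("negative values cannot be log-transformed")
  set_stage(as_gene_tibble(log2(m + pseudocount)), "log2")
}

#' Per-gene z-scores
#'
#' Centers and scales each gene row of a log2 matrix to mean 0 and
#' population SD 1 (divide-by-n convention, pinned by tests). Constant rows
#' cannot be scaled and map to all zeros with a warning.
#'
#' @param nm Log2 matrix from [log_transform()].
#' @return A wide tibble at stage `zscore`.
#' @export
zscore_genes <- function(nm) {
  check_stage(nm, "log2", "zscore_genes")
  m <- as_gene_matrix(nm)
  mu <- rowMeans(m)
  sdp <- sqrt(rowMeans((m - mu)^2))
  const <- sdp == 0
  if (any(const)) {
    warn(sprintf("%d constant gene row(s) mapped to all-zero z-scores",
                 sum(const)))
    sdp[const] <- 1
  }
  z <- (m - mu) / sdp
  set_stage(as_gene_tibble(z), "zscore")
}

#' Filter to expressed genes
#'
#' Keeps genes whose size-normalized value reaches `min_value` in at least
#' `min_samples` samples. The default (1 normalized count in 1 sample) is
#' deliberately permissive.
#'
#' @param nm Size-normalized matrix.
#' @param min_value,min_samples Expression threshold and support.
#' @return The filtered wide tibble (stage preserved).
#' @export
filter_expressed <- function(nm, min_value = 1, min_samples = 1) {
  check_stage(nm, "size_normalized", "filter_expressed")
  m <- as_gene_matrix(nm)
  keep <- rowSums(m >= min_value) >= min_samples
  set_stage(as_gene_tibble(m[keep, , drop = FALSE]), "size_normalized")
}
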