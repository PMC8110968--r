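#' Path to the packaged matrisome catalogue
#'
#' The package ships a 281-gene mouse matrisome catalogue partitioned into 67
#' basement-membrane (BM) and 214 interstitial ECM genes. Genes named in the
#' primary literature carry provenance `stated`; the remaining membership is
#' reconstructed from the field's mouse core-matrisome annotation so that the
#' published division totals hold (provenance `reconstructed`; the fixture is
#' flagged as synthetic in its filename for this reason).
#'
#' @return Path to the catalogue TSV.
#' @export
matrisome_path <- function() {
  system.file("extdata", "matrisome_mm_synthetic.tsv",
              package = "ecmatlas", mustWork = TRUE)
}

#' Load and validate a matrisome catalogue
#'
#' Reads a tab-separated catalogue with columns `symbol` and `division`
#' (`BM` or `interstitial`); `category` and `provenance` are optional
#' metadata. Symbols are matched case-insensitively throughout the package
#' (mouse symbols are mixed case), so symbols that collide after case folding
#' are rejected as duplicates.
#'
#' @param path Catalogue TSV. Defaults to the packaged catalogue.
#' @return A tibble with one row per gene, columns `symbol`, `division` and
#'   any metadata columns present in the file.
#' @examples
#' cat281 <- read_matrisome()
#' partition_counts(cat281)
#' @export
read_matrisome <- function(path = matrisome_path()) {
  if (!file.exists(path)) abort(paste0("catalogue file not found: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  validate_matrisome(x)
}

validate_matrisome <- function(x) {
  miss <- setdiff(c("symbol", "division"), names(x))
  if (length(miss)) {
    abort(paste0("catalogue is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  x <- as_tibble(x)
  if (nrow(x) == 0) return(x)
  if (any(is.na(x$symbol) | x$symbol == "")) abort("empty gene symbol in catalogue")
  folded <- casefold(x$symbol)
  if (anyDuplicated(folded)) {
    abort(paste0("duplicate catalogue symbol: ",
                 x$symbol[duplicated(folded)][1]))
  }
  bad <- setdiff(unique(x$division), c("BM", "interstitial"))
  if (length(bad)) {
    abort(paste0("unknown division token(s): ", paste(bad, collapse = ", "),
                 " (expected 'BM' or 'interstitial')"))
  }
  x
}

#' Write a matrisome catalogue to TSV
#'
#' @param catalogue A catalogue tibble as returned by [read_matrisome()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrisome <- function(catalogue, path) {
  catalogue <- validate_matrisome(catalogue)
  readr::write_tsv(catalogue, path, progress = FALSE)
  invisible(path)
}

#' Classify gene symbols against the matrisome partition
#'
#' Case-insensitive lookup of each symbol in the catalogue. Symbols absent
#' from the catalogue are classified `non-matrisome` (absence is a valid
#' outcome, not an error).
#'
#' @param catalogue A catalogue tibble.
#' @param symbols Character vector of gene symbols.
#' @return A factor with levels `BM`, `interstitial`, `non-matrisome`,
#'   parallel to `symbols`.
#' @export
classify_symbol <- function(catalogue, symbols) {
  catalogue <- validate_matrisome(catalogue)
  idx <- match(casefold(symbols), casefold(catalogue$symbol))
  out <- ifelse(is.na(idx), "non-matrisome", catalogue$division[idx])
  factor(out, levels = c("BM", "interstitial", "non-matrisome"))
}

#' Count catalogue entries per division
#'
#' @param catalogue A catalogue tibble.
#' @return A tibble with columns `division` and `n`; counts always sum to the
#'   catalogue size.
#' @export
partition_counts <- function(catalogue) {
  catalogue <- validate_matrisome(catalogue)
  tibble(division = c("BM", "interstitial")) |>
    left_join(
      catalogue |> group_by(.data$division) |> summarise(n = n()),
      by = "division"
    ) |>
    mutate(n = ifelse(is.na(.data$n), 0L, as.integer(.data$n)))
}

# Internal: symbols of one division (or all matrisome symbols).
matrisome_symbols <- function(catalogue, division = NULL) {
  if (is.null(division)) return(catalogue$symbol)
  catalogue$symbol[catalogue$division == division]
}
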