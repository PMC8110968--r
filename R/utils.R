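# Internal helpers shared across modules.

# Convert a gene-by-sample tibble (first column `gene`) to a numeric matrix
# with gene rownames, preserving column order.
as_gene_matrix <- function(x) {
  stopifnot(is.data.frame(x))
  if (!"gene" %in% names(x)) {
    abort("expected a `gene` column as the first column of the matrix table")
  }
  genes <- as.character(x$gene)
  if (anyDuplicated(genes)) {
    abort(paste0("duplicate gene id: ", genes[duplicated(genes)][1]))
  }
  m <- as.matrix(x[setdiff(names(x), "gene")])
  if (!is.numeric(m)) abort("non-numeric values in the gene x sample table")
  rownames(m) <- genes
  m
}

as_gene_tibble <- function(m) {
  bind_cols(tibble(gene = rownames(m)), as_tibble(m))
}

# Expression-stage bookkeeping: normalized matrices carry an `ecm_stage`
# attribute so downstream transforms can refuse inputs at the wrong stage.
set_stage <- function(x, stage) {
  attr(x, "ecm_stage") <- stage
  x
}

get_stage <- function(x) attr(x, "ecm_stage")

check_stage <- function(x, expected, caller) {
  st <- get_stage(x)
  if (is.null(st)) {
    abort(sprintf(
      "%s() expects a matrix at stage '%s'; input has no stage (use normalize_counts()/log_transform() first)",
      caller, expected
    ))
  }
  if (!identical(st, expected)) {
    abort(sprintf("%s() expects stage '%s' but input is at stage '%s'",
                  caller, expected, st))
  }
  invisible(TRUE)
}

check_samples <- function(samples, sample_ids = NULL) {
  req <- c("sample_id", "population", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    abort(paste0("sample sheet is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  key <- paste(samples$population, samples$replicate)
  if (anyDuplicated(key)) {
    abort(paste0("duplicated (population, replicate) pair: ",
                 key[duplicated(key)][1]))
  }
  if (!is.null(sample_ids) && !setequal(sample_ids, samples$sample_id)) {
    abort("sample ids in the count table and the sample sheet disagree")
  }
  invisible(TRUE)
}

# The five epithelial populations, in follicle order, plus the dermal ones.
epithelial_populations <- function() c("Basal", "LI", "UB", "MB", "HG")
dermal_populations <- function() c("DP", "panDF")
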