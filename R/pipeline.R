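# End-to-end orchestration with a validated config, deterministic outputs
# and a run manifest.

pipeline_defaults <- function() {
  list(
    simulate = TRUE,
    seed = 1L,
    inputs = list(counts = NULL, samples = NULL, catalogue = NULL,
                  gene_sets = NULL, deposition = NULL),
    de = list(alpha_origin = 0.05, fc_threshold = 4),
    epigroups = list(k = 10, alpha = 0.001, metric = "euclidean"),
    gsea = list(n_perm = 500, weight = 1),
    concordance = list(r_threshold = 0.5),
    sim = list()
  )
}

#' Build and validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list; unknown keys are rejected and
#' every threshold is range-checked before any stage runs.
#'
#' @param config Path to a YAML file, or a named list of overrides.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  for (section in c("inputs", "de", "epigroups", "gsea", "concordance")) {
    bad <- setdiff(names(config[[section]]), names(defaults[[section]]))
    if (length(bad)) {
      abort(paste0("unknown config key(s) in ", section, ": ",
                   paste(bad, collapse = ", ")))
    }
  }
  cfg <- modifyList(defaults, config)
  with(cfg, {
    if (de$alpha_origin <= 0 || de$alpha_origin >= 1) {
      abort("de.alpha_origin must lie in (0, 1)")
    }
    if (de$fc_threshold <= 1) abort("de.fc_threshold must exceed 1")
    if (epigroups$alpha <= 0 || epigroups$alpha >= 1) {
      abort("epigroups.alpha must lie in (0, 1)")
    }
    if (epigroups$k < 2) abort("epigroups.k must be at least 2")
    if (gsea$n_perm < 100) abort("gsea.n_perm must be at least 100")
    if (concordance$r_threshold < -1 || concordance$r_threshold > 1) {
      abort("concordance.r_threshold must lie in [-1, 1]")
    }
  })
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> normalize -> differential expression and
#' origin calling -> gene-set correlation panel -> epi-groups -> GSEA ->
#' deposition / concordance, writing one TSV (or JSON) per stage plus a
#' `manifest.json` recording the config, seed and output checksums.
#' Rerunning with an identical config and seed reproduces byte-identical
#' outputs.
#'
#' @param config A [pipeline_config()] (or anything it accepts).
#' @param out_dir Output directory.
#' @param seed Optional seed override.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL) {
  cfg <- pipeline_config(if (inherits(config, "pipeline_config"))
    unclass(config) else config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  outputs <- character()
  emit <- function(x, f, writer = readr::write_tsv) {
    writer(x, p(f), progress = FALSE)
    outputs[[f]] <<- p(f)
    invisible(x)
  }

  if (isTRUE(cfg$simulate)) {
    sim <- run_stage("simulate", {
      scfg <- do.call(sim_config, modifyList(list(seed = cfg$seed), cfg$sim))
      simulate_deposition_profiles(simulate_counts(scfg))
    })
    counts <- sim$counts; samples <- sim$samples
    catalogue <- sim$catalogue
    gene_sets <- split(sim$truth$gene, paste0("program_", sim$truth$program))
    deposition <- sim$deposition
    emit(sim$truth, "truth.tsv")
  } else {
    run_stage("load", {
      counts <- read_counts(cfg$inputs$counts)
      samples <- read_samples(cfg$inputs$samples)
      catalogue <- read_matrisome(cfg$inputs$catalogue)
      gene_sets <- if (!is.null(cfg$inputs$gene_sets))
        read_gmt(cfg$inputs$gene_sets) else NULL
      deposition <- if (!is.null(cfg$inputs$deposition))
        readr::read_csv(cfg$inputs$deposition, show_col_types = FALSE)
      else NULL
    })
  }

  nm <- run_stage("normalize", normalize_counts(counts))
  lg <- log_transform(nm)
  emit(compute_size_factors(counts), "size_factors.tsv")

  de <- run_stage("diffexp", {
    de_wald(counts, samples, "Basal", "panDF",
            genes = matrisome_symbols(catalogue, "BM"))
  })
  origin <- call_origin(de, nm, samples,
                        padj_threshold = cfg$de$alpha_origin,
                        fc_threshold = cfg$de$fc_threshold)
  emit(de |> left_join(origin, by = "gene"), "origin_calls.tsv")

  run_stage("correlate", {
    panel <- correlation_panel(lg, samples, catalogue)
    emit(tidy(panel), "correlation_panel.tsv")
    emit(bind_rows(lapply(names(panel), function(tag) {
      summarize_group_pairs(panel[[tag]]) |> mutate(gene_set = tag)
    })), "correlation_summaries.tsv")
  })

  epi <- run_stage("epigroups", {
    epigroups(counts, samples, catalogue, k = cfg$epigroups$k,
              alpha = cfg$epigroups$alpha, metric = cfg$epigroups$metric)
  })
  emit(tidy(epi), "epigroups.tsv")
  emit(epi$regions, "epigroup_regions.tsv")

  if (!is.null(gene_sets) && length(gene_sets)) {
    gs <- run_stage("gsea", {
      ranked <- rank_signal_to_noise(nm, samples, "DP", "panDF")
      run_gsea(ranked, gene_sets, n_perm = cfg$gsea$n_perm,
               weight = cfg$gsea$weight, seed = cfg$seed)
    })
    emit(tidy(gs), "gsea.tsv")
  }

  if (!is.null(deposition)) {
    run_stage("concordance", {
      mrna <- population_mean_profiles(nm, samples,
                                       genes = deposition$gene)
      conc <- concordance_table(mrna, deposition,
                                r_threshold = cfg$concordance$r_threshold)
      emit(conc, "concordance.tsv")
      long <- deposition |>
        tidyr::pivot_longer(-"gene", names_to = "zone",
                            values_to = "relative") |>
        rename(protein = "gene")
      fr <- region_enrichment_test(long)
      emit(glance(fr), "deposition_friedman.tsv")
    })
  }

  cfg_file <- p("config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_file)
  manifest <- list(
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    outputs = lapply(outputs, function(f) unname(tools::md5sum(f))),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    package_version = as.character(utils::packageVersion("ecmatlas"))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Per-population mean expression profiles
#'
#' Replicate-averaged size-normalized expression per population for the
#' given genes - the mRNA side of the concordance comparison.
#'
#' @param nm Size-normalized matrix tibble.
#' @param samples Sample sheet tibble.
#' @param genes Genes to keep (default all).
#' @param populations Populations, default the five epithelial ones.
#' @return Tibble: `gene` plus one column per population.
#' @export
population_mean_profiles <- function(nm, samples, genes = NULL,
                                     populations = epithelial_populations()) {
  check_stage(nm, "size_normalized", "population_mean_profiles")
  m <- as_gene_matrix(nm)
  check_samples(samples, colnames(m))
  if (!is.null(genes)) {
    m <- m[casefold(rownames(m)) %in% casefold(genes), , drop = FALSE]
  }
  pops <- samples$population[match(colnames(m), samples$sample_id)]
  prof <- vapply(populations, function(p) {
    rowMeans(m[, pops == p, drop = FALSE])
  }, numeric(nrow(m)))
  bind_cols(tibble(gene = rownames(m)), as_tibble(prof))
}
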