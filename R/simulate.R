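# Ground-truth synthetic data emulating the study design: 5 epithelial
# populations (Basal, LI, UB, MB, HG) plus DP and panDF, 3 replicates each,
# NB-distributed counts with planted region-specific matrisome programs,
# matched six-zone protein deposition with planted discordance, and labeled
# synthetic images. Everything is deterministic given the config seed.

#' Simulation configuration
#'
#' Defaults reproduce the study's design: 7 populations x 3 replicates,
#' negative-binomial counts with dispersion 0.05 and baselines drawn
#' log-uniformly over 20..2000, ten planted 12-gene matrisome programs with
#' log2 effect 3, and one of the ten (program 5) shared between HG and DP -
#' the hair-germ/dermal-papilla coupled interstitial program. The matrisome
#' portion of the gene universe is the packaged 281-gene catalogue; the
#' remaining genes are non-matrisome fillers.
#'
#' @param seed Integer seed (mandatory; every random draw flows through it).
#' @param n_genes Total genes (>= 281 + planted non-matrisome needs).
#' @param n_reps Replicates per population.
#' @param dispersion NB dispersion alpha (Var = mu + alpha mu^2).
#' @param effect_log2 Planted log2 effect size.
#' @param genes_per_program Planted genes per program.
#' @param programs Optional list of character vectors of target populations
#'   (epithelial names, optionally including `"DP"`); default the ten
#'   standard patterns.
#' @param baseline_range Log-uniform range for baseline means.
#' @param libsize_range Uniform range for per-sample library-size factors.
#' @param protein_noise_sd Gaussian noise SD on deposition profiles, as a
#'   fraction of the profile maximum.
#' @param discordant_frac Fraction of deposition-profiled genes planted as
#'   discordant.
#' @param discordance_mode `"peak_shift"` (cyclic one-zone shift) or
#'   `"decorrelate"` (profile replaced by an anti-correlated one).
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(seed,
                       n_genes = 1000,
                       n_reps = 3,
                       dispersion = 0.05,
                       effect_log2 = 3,
                       genes_per_program = 12,
                       programs = NULL,
                       baseline_range = c(20, 2000),
                       libsize_range = c(0.7, 1.3),
                       protein_noise_sd = 0.1,
                       discordant_frac = 0,
                       discordance_mode = c("peak_shift", "decorrelate")) {
  if (missing(seed) || is.null(seed)) abort("a seed is mandatory")
  discordance_mode <- match.arg(discordance_mode)
  programs <- programs %||% default_programs()
  cfg <- list(
    seed = as.integer(seed), n_genes = n_genes, n_reps = n_reps,
    dispersion = dispersion, effect_log2 = effect_log2,
    genes_per_program = genes_per_program, programs = programs,
    baseline_range = baseline_range, libsize_range = libsize_range,
    protein_noise_sd = protein_noise_sd, discordant_frac = discordant_frac,
    discordance_mode = discordance_mode
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Named scenario: the shared HG-DP interstitial program
#'
#' Configuration emulating the coupling between hair-germ and
#' dermal-papilla ECM expression: a single block of interstitial genes is
#' active in both HG and DP, with no other planted structure. On data drawn
#' from this scenario, DP correlates more strongly with HG than with pan-DF
#' on the interstitial gene set.
#'
#' @param seed Integer seed.
#' @param n_shared_genes Size of the shared program (default 60).
#' @param ... Further overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_shared_hgdp <- function(seed, n_shared_genes = 60, ...) {
  sim_config(seed = seed, programs = list(c("HG", "DP")),
             genes_per_program = n_shared_genes, ...)
}

# Ten distinct epithelial expression patterns; program 5 is the HG program
# also active in DP (the shared interstitial program).
default_programs <- function() {
  list(
    c("Basal"), c("LI"), c("UB"), c("MB"), c("HG", "DP"),
    c("Basal", "LI"), c("LI", "UB"), c("UB", "MB"), c("MB", "HG"),
    c("Basal", "MB")
  )
}

validate_sim_config <- function(cfg) {
  if (cfg$n_reps < 2) abort("n_reps must be at least 2")
  if (cfg$dispersion < 0) abort("dispersion must be non-negative")
  if (!is.finite(cfg$effect_log2)) abort("effect_log2 must be finite")
  if (cfg$n_genes < 281) abort("n_genes must cover the 281-gene catalogue")
  if (cfg$discordant_frac < 0 || cfg$discordant_frac > 1) {
    abort("discordant_frac must lie in [0, 1]")
  }
  if (cfg$protein_noise_sd < 0) abort("protein_noise_sd must be non-negative")
  pops <- c(epithelial_populations(), "DP")
  ok <- vapply(cfg$programs, function(p) all(p %in% pops), logical(1))
  if (!all(ok)) abort("program targets must be epithelial populations or DP")
  n_plant <- length(cfg$programs) * cfg$genes_per_program
  if (n_plant > 214) {
    abort("planted programs exceed the interstitial catalogue portion")
  }
  invisible(cfg)
}

#' Simulate a count matrix with planted programs
#'
#' Counts are drawn as `NB(mean = baseline * 2^effect * libsize,
#' dispersion alpha)`, where the effect applies in samples whose population
#' is a target of the gene's planted program. Planted genes are interstitial
#' matrisome genes (programs live in the regionalized interstitial/BM
#' biology); the remaining catalogue genes and the non-matrisome fillers are
#' unplanted background.
#'
#' @param cfg A [sim_config()].
#' @return An `ecm_sim` list: `counts` (wide tibble), `samples`,
#'   `catalogue`, `truth` (tibble `gene`, `program`, `pattern`, `targets`),
#'   `baseline`, `libsize`, `config`.
#' @export
simulate_counts <- function(cfg) {
  validate_sim_config(cfg)
  catalogue <- read_matrisome()
  withr::with_seed(cfg$seed, {
    pops <- c(epithelial_populations(), dermal_populations())
    samples <- tibble(
      population = rep(pops, each = cfg$n_reps),
      replicate = rep(seq_len(cfg$n_reps), times = length(pops))
    ) |>
      mutate(sample_id = paste0(.data$population, "_", .data$replicate)) |>
      select("sample_id", "population", "replicate")

    n_extra <- cfg$n_genes - nrow(catalogue)
    genes <- c(catalogue$symbol,
               if (n_extra > 0) sprintf("NMg%04d", seq_len(n_extra)))
    baseline <- exp(runif(length(genes), log(cfg$baseline_range[1]),
                          log(cfg$baseline_range[2])))
    libsize <- runif(nrow(samples), cfg$libsize_range[1],
                     cfg$libsize_range[2])

    # plant programs into interstitial catalogue genes
    interstitial <- matrisome_symbols(catalogue, "interstitial")
    n_plant <- length(cfg$programs) * cfg$genes_per_program
    planted <- sample(interstitial, n_plant)
    program_of <- rep(seq_along(cfg$programs), each = cfg$genes_per_program)
    truth <- tibble(
      gene = planted,
      program = program_of,
      pattern = vapply(cfg$programs[program_of], function(t) {
        paste(sort(intersect(t, epithelial_populations())), collapse = "+")
      }, character(1)),
      targets = vapply(cfg$programs[program_of], paste, character(1),
                       collapse = "+")
    )

    mu <- outer(baseline, libsize)
    rownames(mu) <- genes
    for (i in seq_len(nrow(truth))) {
      tg <- cfg$programs[[truth$program[i]]]
      in_target <- samples$population %in% tg
      mu[truth$gene[i], in_target] <-
        mu[truth$gene[i], in_target] * 2^cfg$effect_log2
    }
    size <- if (cfg$dispersion > 0) 1 / cfg$dispersion else Inf
    counts <- matrix(
      rnbinom(length(mu), mu = mu, size = size),
      nrow = nrow(mu), dimnames = list(genes, samples$sample_id)
    )
    structure(
      list(counts = as_gene_tibble(counts), samples = samples,
           catalogue = catalogue, truth = truth,
           baseline = setNames(baseline, genes),
           libsize = setNames(libsize, samples$sample_id), config = cfg),
      class = "ecm_sim"
    )
  })
}

#' @export
print.ecm_sim <- function(x, ...) {
  cat(sprintf(
    "<ecm_sim> %d genes x %d samples, %d planted genes in %d programs (seed %d)\n",
    nrow(x$counts), nrow(x$samples), nrow(x$truth),
    length(x$config$programs), x$config$seed
  ))
  invisible(x)
}

#' Expected per-population mean expression of a simulated gene
#'
#' Noise-free generator truth: baseline times the planted effect in target
#' populations, before library-size scaling.
#'
#' @param sim An `ecm_sim`.
#' @param gene Gene symbol.
#' @return Named numeric vector over the seven populations.
#' @export
true_population_means <- function(sim, gene) {
  pops <- c(epithelial_populations(), dermal_populations())
  base <- sim$baseline[[gene]]
  row <- sim$truth[sim$truth$gene == gene, ]
  targets <- if (nrow(row)) sim$config$programs[[row$program]] else character()
  vapply(pops, function(p) {
    base * if (p %in% targets) 2^sim$config$effect_log2 else 1
  }, numeric(1))
}

#' Simulate matched protein deposition profiles
#'
#' For each planted gene, the concordant protein profile is a positive
#' affine transform of its true population-mean mRNA profile mapped onto the
#' six zones (HG feeds both LHG and interface), plus Gaussian noise scaled
#' by the profile maximum. A `discordant_frac` of the genes is made
#' discordant: `peak_shift` rotates the profile one zone so the protein peak
#' moves away from the mRNA peak; `decorrelate` replaces the profile with
#' one built from the negated, re-shifted mRNA profile (low or negative r).
#'
#' @param sim An `ecm_sim` from [simulate_counts()].
#' @param noise_sd,discordant_frac,mode Override the config values.
#' @return `sim` with added `deposition` (tibble `gene` + 6 zone columns of
#'   relative values) and `truth$concordant` (logical).
#' @export
simulate_deposition_profiles <- function(sim, noise_sd = NULL,
                                         discordant_frac = NULL,
                                         mode = NULL) {
  cfg <- sim$config
  noise_sd <- noise_sd %||% cfg$protein_noise_sd
  discordant_frac <- discordant_frac %||% cfg$discordant_frac
  mode <- mode %||% cfg$discordance_mode
  zn <- zone_scheme()
  withr::with_seed(cfg$seed + 1L, {
    genes <- sim$truth$gene
    n_disc <- round(discordant_frac * length(genes))
    disc <- rep(FALSE, length(genes))
    if (n_disc > 0) disc[sample(length(genes), n_disc)] <- TRUE
    rows <- lapply(seq_along(genes), function(i) {
      g <- genes[i]
      mz <- map_mrna_to_zones(true_population_means(sim, g)[
        epithelial_populations()])
      prof <- mz
      if (disc[i]) {
        if (mode == "peak_shift") {
          # cyclic shift by one zone, in whichever direction actually moves
          # the argmax (a plateau starting at the first zone survives a
          # forward shift)
          prof <- mz[c(seq_along(zn)[-1], 1)]
          if (which.max(prof) == which.max(mz)) {
            prof <- mz[c(length(zn), seq_along(zn)[-length(zn)])]
          }
          names(prof) <- zn
        } else {
          prof <- max(mz) - mz + min(mz)  # inverted profile, r <= 0
          names(prof) <- zn
        }
      }
      if (noise_sd > 0) {
        prof <- pmax(0, prof + rnorm(length(prof), 0, noise_sd * max(prof)))
      }
      if (max(prof) <= 0) prof[which.max(mz)] <- 1
      rel <- relative_normalize(unname(prof))
      tibble(gene = g, !!!setNames(as.list(rel), zn))
    })
    sim$deposition <- bind_rows(rows)
    sim$truth$concordant <- !disc
    sim
  })
}

#' Simulate a labeled intensity image
#'
#' Lays out six disjoint rectangular zone stripes with paired background
#' stripes below them, fills each zone with its true mean plus Gaussian
#' noise, and returns the image with both label masks and the ground truth.
#'
#' @param zone_means Numeric length-6: true zone intensities.
#' @param background_means Numeric length-6: true background intensities.
#' @param noise_sd Pixel noise SD.
#' @param zone_height,zone_width Stripe geometry in pixels.
#' @param seed Integer seed.
#' @return List: `image`, `zones`, `background` (matrices), `true_means`
#'   (tibble `zone`, `zone_mean`, `background_mean`).
#' @export
simulate_labeled_image <- function(zone_means, background_means,
                                   noise_sd = 0, zone_height = 20,
                                   zone_width = 30, seed = 1L) {
  if (length(zone_means) != 6 || length(background_means) != 6) {
    abort("six zone means and six background means are required")
  }
  withr::with_seed(seed, {
    h <- zone_height * 2 + 3
    w <- zone_width * 6 + 7
    image <- matrix(0, h, w)
    zones <- matrix(0L, h, w)
    background <- matrix(0L, h, w)
    for (z in 1:6) {
      c0 <- 1 + (z - 1) * (zone_width + 1) + 1
      cols <- c0:(c0 + zone_width - 1)
      zrows <- 2:(zone_height + 1)
      brows <- (zone_height + 3):(2 * zone_height + 2)
      zones[zrows, cols] <- z
      background[brows, cols] <- z
      image[zrows, cols] <- zone_means[z]
      image[brows, cols] <- background_means[z]
    }
    if (noise_sd > 0) {
      image <- image + matrix(rnorm(h * w, 0, noise_sd), h, w)
    }
    image <- pmax(image, 0)
    stopifnot(!any(zones > 0 & background > 0))
    list(
      image = image, zones = zones, background = background,
      true_means = tibble(zone = factor(zone_scheme(),
                                        levels = zone_scheme()),
                          zone_mean = zone_means,
                          background_mean = background_means)
    )
  })
}

#' Write a complete fixture bundle
#'
#' Emits every file the pipeline stages consume: counts and sample-sheet
#' TSVs, the catalogue TSV, planted-program gene sets (GMT), the deposition
#' CSV, the labeled image TIFFs, and a machine-readable truth JSON.
#' Rerunning with the same config is byte-identical.
#'
#' @param sim An `ecm_sim`, ideally after
#'   [simulate_deposition_profiles()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  paths <- c(
    counts = p("counts.tsv"), samples = p("samples.tsv"),
    catalogue = p("catalogue.tsv"), gene_sets = p("gene_sets.gmt"),
    deposition = p("deposition.csv"), truth = p("truth.json"),
    image = p("image.tif"), zones = p("zones.tif"),
    background = p("background.tif")
  )
  readr::write_tsv(sim$counts, paths["counts"], progress = FALSE)
  readr::write_tsv(sim$samples, paths["samples"], progress = FALSE)
  write_matrisome(sim$catalogue, paths["catalogue"])

  sets <- split(sim$truth$gene, sim$truth$program)
  names(sets) <- paste0("program_", names(sets))
  sets$BM <- matrisome_symbols(sim$catalogue, "BM")
  write_gmt(sets, paths["gene_sets"])

  if (is.null(sim$deposition)) {
    sim <- simulate_deposition_profiles(sim)
  }
  readr::write_csv(sim$deposition, paths["deposition"], progress = FALSE)

  img <- simulate_labeled_image(
    zone_means = c(120, 80, 60, 40, 150, 200),
    background_means = rep(20, 6),
    noise_sd = 5, seed = sim$config$seed + 2L
  )
  write_intensity_tiff(round(img$image), paths["image"])
  write_intensity_tiff(img$zones, paths["zones"])
  write_intensity_tiff(img$background, paths["background"])

  truth <- list(
    seed = sim$config$seed,
    n_genes = nrow(sim$counts),
    programs = lapply(sim$config$programs, as.list),
    genes = sim$truth,
    image_true_means = img$true_means
  )
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
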