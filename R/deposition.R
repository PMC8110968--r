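# Regional protein deposition: six BM zones, background-subtracted mean
# intensities, percent-of-max normalization, region enrichment statistics,
# mRNA-protein concordance and the morphometry helpers.

#' The six basement-membrane zones
#'
#' Fixed zone order used throughout: interfollicular epidermis (IFE), lower
#' isthmus (LI), upper bulge (UB), mid-bulge (MB), lateral hair germ (LHG)
#' and the hair germ-dermal papilla interface.
#'
#' @return Character vector of the six zone names, in order.
#' @export
zone_scheme <- function() c("IFE", "LI", "UB", "MB", "LHG", "interface")

#' Background-subtracted mean zone intensities
#'
#' For each zone label `z` in 1..6, the mean image intensity over the zone
#' mask minus the mean over the paired background region (the adjoining
#' epithelium, label `z` of the background mask), clipped at 0 - deposition
#' cannot be negative.
#'
#' @param image Numeric matrix of intensities.
#' @param zones Integer matrix, same shape: zone labels 1..6, 0 outside.
#' @param background Integer matrix, same shape: background labels 1..6
#'   paired with the zones, 0 outside.
#' @return Tibble with columns `zone` (ordered factor) and `raw_mean`.
#' @export
measure_region_intensities <- function(image, zones, background) {
  if (!all(dim(image) == dim(zones)) || !all(dim(image) == dim(background))) {
    abort("image, zone mask and background mask must share dimensions")
  }
  zn <- zone_scheme()
  raw <- vapply(seq_along(zn), function(z) {
    in_zone <- zones == z
    in_bg <- background == z
    if (!any(in_zone)) abort(paste0("zone has no pixels: ", zn[z]))
    if (!any(in_bg)) abort(paste0("background region has no pixels: ", zn[z]))
    max(0, mean(image[in_zone]) - mean(image[in_bg]))
  }, numeric(1))
  tibble(zone = factor(zn, levels = zn), raw_mean = raw)
}

#' Percent-of-max relative normalization
#'
#' Scales a raw per-zone profile so the maximum-intensity zone is 100 and
#' every other zone is proportional.
#'
#' @param raw Numeric vector of non-negative zone means (>= 1 positive), or
#'   a tibble from [measure_region_intensities()].
#' @return Same shape as the input with values in `[0, 100]` (column
#'   `relative` when a tibble is given).
#' @export
relative_normalize <- function(raw) {
  if (is.data.frame(raw)) {
    raw$relative <- relative_normalize(raw$raw_mean)
    return(raw)
  }
  if (any(raw < 0)) abort("raw intensities must be non-negative")
  mx <- max(raw)
  if (mx <= 0) abort("no deposition detected: all zones are zero")
  100 * raw / mx
}

#' Friedman test with pairwise Wilcoxon follow-up
#'
#' Tests whether relative deposition differs across zones, treating proteins
#' as blocks: Friedman chi-square with `zones - 1` degrees of freedom,
#' followed (only when the Friedman p < 0.05) by two-sided paired Wilcoxon
#' signed-rank tests for every zone pair with Bonferroni correction over the
#' number of comparisons performed. Zero differences are dropped; the exact
#' distribution is used for small samples without ties, the
#' continuity-corrected normal approximation otherwise.
#'
#' @param profiles Long tibble with columns `protein`, `zone`, `relative`
#'   (>= 3 proteins, every protein measured in every zone).
#' @return An `ecm_friedman` list: `statistic`, `df`, `p_value`, `pairwise`
#'   (tibble `zone_a`, `zone_b`, `p`, `p_bonferroni`; empty when the global
#'   test is not significant).
#' @export
region_enrichment_test <- function(profiles) {
  req <- c("protein", "zone", "relative")
  if (!all(req %in% names(profiles))) {
    abort("profiles needs columns protein, zone, relative")
  }
  nb <- dplyr::n_distinct(profiles$protein)
  if (nb < 3) abort("need at least 3 proteins (blocks)")
  wide <- profiles |>
    tidyr::pivot_wider(id_cols = "protein", names_from = "zone",
                       values_from = "relative")
  m <- as.matrix(wide[-1])
  if (anyNA(m)) abort("every protein must be measured in every zone")
  ft <- friedman.test(m)
  pairwise <- tibble(zone_a = character(), zone_b = character(),
                     p = numeric(), p_bonferroni = numeric())
  if (is.finite(ft$p.value) && ft$p.value < 0.05) {
    zs <- colnames(m)
    combos <- utils::combn(seq_along(zs), 2)
    ps <- apply(combos, 2, function(ij) {
      suppressWarnings(
        wilcox.test(m[, ij[1]], m[, ij[2]], paired = TRUE)$p.value
      )
    })
    nc <- ncol(combos)
    pairwise <- tibble(
      zone_a = zs[combos[1, ]], zone_b = zs[combos[2, ]],
      p = ps, p_bonferroni = pmin(1, ps * nc)
    )
  }
  structure(
    list(statistic = unname(ft$statistic), df = unname(ft$parameter),
         p_value = ft$p.value, n_blocks = nb, pairwise = pairwise),
    class = "ecm_friedman"
  )
}

#' @export
print.ecm_friedman <- function(x, ...) {
  cat(sprintf("<ecm_friedman> chi-square = %.4g, df = %d, p = %.3g (%d blocks)\n",
              x$statistic, x$df, x$p_value, x$n_blocks))
  if (nrow(x$pairwise)) {
    print(as.data.frame(x$pairwise), row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @method glance ecm_friedman
#' @export
glance.ecm_friedman <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         n_blocks = x$n_blocks, n_pairwise = nrow(x$pairwise))
}

#' @method tidy ecm_friedman
#' @export
tidy.ecm_friedman <- function(x, ...) x$pairwise

#' Map epithelial mRNA populations onto the six BM zones
#'
#' The five expression populations map as Basal -> IFE, LI -> LI, UB -> UB,
#' MB -> MB and HG -> both LHG and interface (protein was measured in the
#' two hair-germ zones separately, but there is a single HG expression
#' population, so its value is compared against both).
#'
#' @param mrna Named numeric vector over the populations `Basal`, `LI`,
#'   `UB`, `MB`, `HG`.
#' @param mapping Named list: zone -> population providing its mRNA value.
#' @return Named numeric vector over [zone_scheme()].
#' @export
map_mrna_to_zones <- function(mrna,
                              mapping = list(IFE = "Basal", LI = "LI",
                                             UB = "UB", MB = "MB",
                                             LHG = "HG", interface = "HG")) {
  miss <- setdiff(unlist(mapping), names(mrna))
  if (length(miss)) {
    abort(paste0("mRNA profile is missing population(s): ",
                 paste(unique(miss), collapse = ", ")))
  }
  out <- vapply(zone_scheme(), function(z) mrna[[mapping[[z]]]], numeric(1))
  names(out) <- zone_scheme()
  out
}

#' mRNA-protein concordance call
#'
#' Classifies one ECM component as `consistent` when the mRNA and protein
#' profiles peak in the same zone AND their Pearson r strictly exceeds
#' `r_threshold` (default 0.5); otherwise `discrepant`. The five-population
#' mRNA profile is first mapped to the six zones (HG covers both LHG and
#' interface, so an HG mRNA peak matches a protein peak in either); peak
#' ties are compared as sets (non-empty intersection required). Because
#' measured profiles never tie exactly, a zone counts as a co-peak when it
#' lies within `peak_tol` of the maximum (as a fraction of the maximum);
#' zones that are genuinely distinct in this regionalized biology sit far
#' below that band. A zero-variance profile has undefined r and is called
#' `discrepant` with a flag.
#'
#' @param mrna Named numeric vector over the 5 populations, or over the 6
#'   zones directly.
#' @param protein Named numeric vector of relative deposition over the 6
#'   zones.
#' @param r_threshold Pearson threshold (strict inequality).
#' @param peak_tol Co-peak tolerance: zones with value `>= (1 - peak_tol) *
#'   max` belong to the peak set. 0 gives the strict argmax.
#' @return One-row tibble: `pearson_r`, `mrna_peak`, `protein_peak`,
#'   `verdict`, `flag`.
#' @export
concordance_call <- function(mrna, protein, r_threshold = 0.5,
                             peak_tol = 1 / 3) {
  zn <- zone_scheme()
  if (!all(zn %in% names(protein))) {
    abort("protein profile must be named by the six zones")
  }
  protein <- protein[zn]
  peak_set <- function(x) names(x)[x >= (1 - peak_tol) * max(x)]
  if (all(zn %in% names(mrna))) {
    mz <- mrna[zn]
    mrna_peaks <- peak_set(mz)
  } else {
    mz <- map_mrna_to_zones(mrna)
    pops <- c("Basal", "LI", "UB", "MB", "HG")
    pk <- peak_set(mrna[pops])
    # HG expression peak matches either hair-germ protein zone
    mrna_peaks <- unique(unlist(lapply(pk, function(p) {
      if (p == "HG") c("LHG", "interface") else zn[match(p, c("Basal", "LI", "UB", "MB"))]
    })))
  }
  if (anyNA(mz) || anyNA(protein)) abort("profiles must not contain missing values")
  prot_peaks <- peak_set(protein)
  flag <- ""
  if (sd(mz) == 0 || sd(protein) == 0) {
    r <- NA_real_
    flag <- "zero_variance"
  } else {
    r <- cor(mz, protein)
  }
  consistent <- length(intersect(mrna_peaks, prot_peaks)) > 0 &&
    !is.na(r) && r > r_threshold
  tibble(
    pearson_r = r,
    mrna_peak = paste(mrna_peaks, collapse = "|"),
    protein_peak = paste(prot_peaks, collapse = "|"),
    verdict = ifelse(consistent, "consistent", "discrepant"),
    flag = flag
  )
}

#' Concordance calls for many genes
#'
#' @param mrna_profiles Tibble: `gene` plus one column per population (or
#'   per zone).
#' @param protein_profiles Tibble: `gene` plus one column per zone
#'   (relative deposition).
#' @param r_threshold,peak_tol See [concordance_call()].
#' @return Tibble with one row per gene present in both tables.
#' @export
concordance_table <- function(mrna_profiles, protein_profiles,
                              r_threshold = 0.5, peak_tol = 1 / 3) {
  shared <- intersect(mrna_profiles$gene, protein_profiles$gene)
  rows <- lapply(shared, function(g) {
    mr <- unlist(mrna_profiles[mrna_profiles$gene == g, -1])
    pr <- unlist(protein_profiles[protein_profiles$gene == g, -1])
    bind_cols(tibble(gene = g),
              concordance_call(mr, pr, r_threshold = r_threshold,
                               peak_tol = peak_tol))
  })
  bind_rows(rows)
}

#' Hemidesmosome density
#'
#' Structures per micrometre of traced cellular perimeter.
#'
#' @param count Non-negative integer count of structures.
#' @param length_um Perimeter length in micrometres (> 0).
#' @return Density in structures per micrometre.
#' @export
hemidesmosome_density <- function(count, length_um) {
  if (any(length_um <= 0)) abort("perimeter length must be positive")
  if (any(count < 0)) abort("structure count must be non-negative")
  count / length_um
}

#' Volume per label of a 3D segmentation
#'
#' @param labels Integer 3D array of object labels (0 = background).
#' @param voxel_size_um Numeric length-3 vector `(dx, dy, dz)` in
#'   micrometres; anisotropic voxels are supported.
#' @return Tibble with columns `label`, `n_voxels`, `volume_um3`.
#' @export
dp_volume <- function(labels, voxel_size_um) {
  if (length(voxel_size_um) != 3 || any(voxel_size_um <= 0)) {
    abort("voxel_size_um must be 3 positive dimensions")
  }
  tab <- table(labels[labels > 0])
  vox <- prod(voxel_size_um)
  tibble(
    label = as.integer(names(tab)),
    n_voxels = as.integer(tab),
    volume_um3 = as.numeric(tab) * vox
  )
}

#' Pigmented-area fraction
#'
#' Fraction of pixels on the pigmented side of a threshold. Pigmented skin
#' is dark on bright-field photographs, so pigmented means below the
#' threshold by default.
#'
#' @param image Numeric matrix (greyscale).
#' @param threshold Intensity cut.
#' @param dark_is_pigmented Count pixels `< threshold` (default) or
#'   `> threshold`.
#' @return List: `fraction` in `[0, 1]` and `binary` (logical matrix of
#'   pigmented pixels).
#' @export
pigmented_fraction <- function(image, threshold, dark_is_pigmented = TRUE) {
  if (length(image) == 0) abort("empty image")
  binary <- if (dark_is_pigmented) image < threshold else image > threshold
  list(fraction = mean(binary), binary = binary)
}

#' Read a single-channel TIFF as a numeric matrix
#'
#' @param path TIFF file.
#' @param as_integer Round to integers (for label masks).
#' @return Numeric (or integer) matrix.
#' @export
read_intensity_tiff <- function(path, as_integer = FALSE) {
  x <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(x)) == 3) x <- x[, , 1]
  if (as_integer) x <- round(x)
  x
}

#' Write a numeric matrix as a 16-bit TIFF
#'
#' Values are stored as `value / 65535` in the TIFF's unit range, so integer
#' intensities up to 65535 round-trip through [read_intensity_tiff()].
#'
#' @param x Numeric matrix with values in `[0, 65535]`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_intensity_tiff <- function(x, path) {
  if (any(x < 0) || any(x > 65535)) abort("values must lie in [0, 65535]")
  tiff::writeTIFF(x / 65535, path, bits.per.sample = 16)
  invisible(path)
}
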