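test_that("zone intensities are background-subtracted and clipped", {
  img <- simulate_labeled_image(zone_means = rep(120, 6),
                                background_means = rep(20, 6),
                                noise_sd = 0, seed = 1)
  got <- measure_region_intensities(img$image, img$zones, img$background)
  expect_equal(got$raw_mean, rep(100, 6))

  # background above signal clips to zero
  img2 <- simulate_labeled_image(zone_means = rep(10, 6),
                                 background_means = rep(50, 6),
                                 noise_sd = 0, seed = 1)
  got2 <- measure_region_intensities(img2$image, img2$zones, img2$background)
  expect_equal(got2$raw_mean, rep(0, 6))

  # pixels outside every mask are irrelevant
  img3 <- img
  img3$image[img3$zones == 0 & img3$background == 0] <- 1e6
  got3 <- measure_region_intensities(img3$image, img3$zones, img3$background)
  expect_equal(got3, got)

  # shape mismatch and missing zones are errors
  expect_error(measure_region_intensities(img$image[-1, ], img$zones,
                                          img$background), "dimensions")
  z <- img$zones
  z[z == 3] <- 0
  expect_error(measure_region_intensities(img$image, z, img$background),
               "UB")
})

test_that("noisy synthetic images are recovered within sampling error", {
  zm <- c(120, 80, 60, 40, 150, 200)
  img <- simulate_labeled_image(zone_means = zm,
                                background_means = rep(20, 6),
                                noise_sd = 5, seed = 7)
  got <- measure_region_intensities(img$image, img$zones, img$background)
  n_pix <- sum(img$zones == 1)
  se <- 5 * sqrt(2 / n_pix)  # difference of two means of n_pix pixels
  expect_true(all(abs(got$raw_mean - (zm - 20)) < 3 * se))
  # masks are disjoint labels
  expect_true(!any(img$zones > 0 & img$background > 0))
})

test_that("relative normalization is percent-of-max", {
  expect_equal(relative_normalize(c(2, 8, 4, 0, 0, 0)),
               c(25, 100, 50, 0, 0, 0))
  withr::with_seed(2, {
    for (i in 1:20) {
      raw <- runif(6, 0, 500)
      rel <- relative_normalize(raw)
      expect_equal(max(rel), 100)
      expect_equal(relative_normalize(raw * runif(1, 0.1, 9)), rel,
                   tolerance = 1e-12)
    }
  })
  expect_error(relative_normalize(rep(0, 6)), "no deposition")
})

test_that("Friedman worked example gives chi-square 6 on 2 df", {
  profiles <- tibble::tibble(
    protein = rep(c("p1", "p2", "p3"), each = 3),
    zone = rep(c("z1", "z2", "z3"), 3),
    relative = rep(c(10, 20, 30), 3)  # every block ranks (1, 2, 3)
  )
  fr <- region_enrichment_test(profiles)
  expect_equal(fr$statistic, 6, tolerance = 1e-12)
  expect_equal(fr$df, 2)
  expect_equal(fr$statistic, oracle_friedman(matrix(rep(c(10, 20, 30), 3),
                                                    3, byrow = TRUE)))
  # wilcoxon follow-up ran (p < 0.05) with Bonferroni = min(1, p * m)
  expect_equal(fr$pairwise$p_bonferroni,
               pmin(1, fr$pairwise$p * nrow(fr$pairwise)))
})

test_that("identical deposition across zones is a Friedman null", {
  profiles <- tibble::tibble(
    protein = rep(c("p1", "p2", "p3"), each = 3),
    zone = rep(c("z1", "z2", "z3"), 3),
    relative = rep(5, 9)
  )
  fr <- suppressWarnings(region_enrichment_test(profiles))
  expect_true(is.na(fr$p_value) || fr$p_value >= 0.05)
  expect_equal(nrow(fr$pairwise), 0)
  expect_error(region_enrichment_test(profiles[1:6, ]), "3 proteins")
})

test_that("Friedman statistic equals the rank-sum formula on random data", {
  withr::with_seed(23, {
    for (i in 1:20) {
      m <- t(replicate(5, sample(seq_len(6))))  # tie-free blocks
      colnames(m) <- zone_scheme()
      profiles <- tibble::tibble(
        protein = rep(paste0("p", 1:5), each = 6),
        zone = rep(zone_scheme(), 5),
        relative = as.numeric(t(m))
      )
      fr <- region_enrichment_test(profiles)
      expect_equal(fr$statistic, oracle_friedman(m), tolerance = 1e-12)
    }
  })
})

test_that("concordance follows the shared-peak-and-correlation rule", {
  zn <- zone_scheme()
  prof <- function(x) stats::setNames(x, zn)

  # perfect colocalization
  cc <- concordance_call(prof(c(0, 0, 0, 10, 0, 0)),
                         prof(c(0, 0, 0, 8, 0, 0)))
  expect_equal(cc$verdict, "consistent")
  expect_equal(cc$pearson_r, 1)

  # high r but distinct peaks -> discrepant
  cc2 <- concordance_call(prof(c(0, 0, 0, 0, 6, 10)),
                          prof(c(0, 0, 0, 0, 10, 6)))
  expect_gt(cc2$pearson_r, 0.5)
  expect_equal(cc2$verdict, "discrepant")

  # same peak but weak correlation -> discrepant
  m3 <- prof(c(0, 0, 0, 10, 0, 0))
  p3 <- prof(c(9.9, 0, 0, 10, 0, 9.9))
  expect_lt(cor(m3, p3), 0.5)
  expect_equal(concordance_call(m3, p3)$verdict, "discrepant")

  # r exactly at the 0.5 boundary -> discrepant (strict inequality)
  m4 <- prof(c(4, 0, 0, 0, 0, 0))
  p4 <- prof(c(4 + 4 * sqrt(2), 5 * sqrt(2), 5 * sqrt(2), 5 * sqrt(2),
               5 * sqrt(2), 0))
  expect_equal(cor(m4, p4), 0.5, tolerance = 1e-12)
  expect_equal(concordance_call(m4, p4)$verdict, "discrepant")

  # zero-variance protein -> undefined r, flagged discrepant
  cc5 <- concordance_call(m4, prof(rep(3, 6)))
  expect_equal(cc5$verdict, "discrepant")
  expect_equal(cc5$flag, "zero_variance")
})

test_that("population profiles map onto zones with HG covering both HG zones", {
  mrna <- c(Basal = 1, LI = 2, UB = 3, MB = 4, HG = 9)
  mz <- map_mrna_to_zones(mrna)
  expect_equal(unname(mz), c(1, 2, 3, 4, 9, 9))
  cc <- concordance_call(mrna,
                         stats::setNames(c(0, 0, 0, 0, 0, 9), zone_scheme()))
  # protein peaks at the interface; HG mRNA matches either HG zone
  expect_equal(cc$verdict, "consistent")
  expect_error(map_mrna_to_zones(c(Basal = 1)), "missing population")
})

test_that("Pearson on six-zone vectors matches the sum-formula oracle", {
  withr::with_seed(41, {
    for (i in 1:100) {
      x <- runif(6)
      y <- runif(6)
      expect_equal(cor(x, y), oracle_pearson(x, y), tolerance = 1e-12)
    }
  })
})

test_that("morphometry helpers apply their formulas", {
  expect_equal(hemidesmosome_density(6, 3), 2)
  expect_equal(hemidesmosome_density(0, 5), 0)
  expect_equal(hemidesmosome_density(12, 6), hemidesmosome_density(6, 3))
  expect_error(hemidesmosome_density(3, 0), "positive")

  labels <- array(0L, c(10, 10, 4))
  labels[1:5, 1:5, 1:4] <- 1L   # 100 voxels
  labels[6:9, 6:9, 1:2] <- 2L   # 32 voxels
  vol <- dp_volume(labels, c(0.5, 0.5, 0.5))
  expect_equal(vol$volume_um3[vol$label == 1], 12.5)
  expect_equal(sum(vol$volume_um3), sum(labels > 0) * 0.125)
  expect_error(dp_volume(labels, c(0.5, 0.5)), "3 positive")
  expect_equal(nrow(dp_volume(array(0L, c(2, 2, 2)), c(1, 1, 1))), 0)

  img <- matrix(seq(0, 999), 40, 25)
  pf <- pigmented_fraction(img, 250)
  expect_equal(pf$fraction, 0.25)
  expect_equal(pigmented_fraction(img, -1)$fraction, 0)
  fr <- vapply(c(100, 400, 900), function(th) {
    pigmented_fraction(img, th)$fraction
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("TIFF round-trip preserves intensities and labels", {
  f <- withr::local_tempfile(fileext = ".tif")
  m <- matrix(sample(0:65535, 200), 20, 10)
  write_intensity_tiff(m, f)
  expect_equal(read_intensity_tiff(f), m)
})
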