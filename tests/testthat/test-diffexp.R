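test_that("method-of-moments dispersion matches hand computations", {
  # group with mean 100 and variance 1100 -> alpha = 0.1
  a <- sqrt(1100)  # sample variance of (100-a, 100, 100+a) is a^2
  cm <- tibble::tibble(gene = "g1",
                       A_1 = 100 - a, A_2 = 100, A_3 = 100 + a,
                       B_1 = 100 - a, B_2 = 100, B_3 = 100 + a)
  groups <- rep(c("A", "B"), each = 3)
  sf <- tibble::tibble(sample_id = names(cm)[-1], size_factor = rep(1, 6))
  d <- estimate_dispersion(cm, groups = groups, size_factors = sf)
  expect_equal(d$dispersion, 0.1, tolerance = 1e-12)

  # Poisson-like gene (variance = mean) -> 0; all-zero gene flagged
  b <- sqrt(50)
  cm2 <- tibble::tibble(gene = c("pois", "zero"),
                        A_1 = c(50 - b, 0), A_2 = c(50, 0), A_3 = c(50 + b, 0),
                        B_1 = c(50 - b, 0), B_2 = c(50, 0), B_3 = c(50 + b, 0))
  d2 <- estimate_dispersion(cm2, groups = groups, size_factors = sf)
  expect_equal(d2$dispersion, c(0, 0), tolerance = 1e-12)
  expect_equal(d2$flag, c("", "all_zero"))

  # never negative, under any data
  set.seed(4)
  cmr <- tibble::tibble(gene = paste0("g", 1:50))
  for (s in names(cm)[-1]) cmr[[s]] <- rpois(50, 30)
  dr <- estimate_dispersion(cmr, groups = groups, size_factors = sf)
  expect_true(all(dr$dispersion >= 0))
})

test_that("Wald test returns the moderated fold change and null behaviour", {
  samples <- tibble::tibble(
    sample_id = c(paste0("a", 1:3), paste0("b", 1:3)),
    population = rep(c("A", "B"), each = 3), replicate = rep(1:3, 2)
  )
  cm <- tibble::tibble(gene = c("up", "flat", "zero"),
                       a1 = c(80L, 30L, 0L), a2 = c(80L, 30L, 0L),
                       a3 = c(80L, 30L, 0L),
                       b1 = c(5L, 30L, 0L), b2 = c(5L, 30L, 0L),
                       b3 = c(5L, 30L, 0L))
  unit_sf <- tibble::tibble(sample_id = names(cm)[-1],
                            size_factor = rep(1, 6))
  de <- de_wald(cm, samples, "A", "B", size_factors = unit_sf)
  up <- de[de$gene == "up", ]
  expect_equal(up$log2fc, log2(81 / 6), tolerance = 1e-9)
  flat <- de[de$gene == "flat", ]
  expect_equal(flat$log2fc, 0)
  expect_equal(flat$p, 1, tolerance = 1e-9)
  zero <- de[de$gene == "zero", ]
  expect_equal(zero$p, 1)
  expect_equal(zero$flag, "all_zero")
})

test_that("LRT statistic is non-negative and separates strong effects", {
  samples <- tibble::tibble(
    sample_id = paste0("s", 1:9),
    population = rep(c("A", "B", "C"), each = 3), replicate = rep(1:3, 3)
  )
  withr::with_seed(11, {
    cm <- tibble::tibble(gene = paste0("g", 1:30))
    mu <- matrix(100, 30, 9)
    mu[1, 1:3] <- 1000  # one group 10x the others for gene 1
    for (s in 1:9) cm[[paste0("s", s)]] <- rnbinom(30, mu = mu[, s], size = 100)
  })
  de <- de_lrt(cm, samples, c("A", "B", "C"))
  expect_true(all(de$stat >= 0))
  expect_true(all(de$df == 2))
  expect_lt(de$p[de$gene == "g1"], 1e-4)
})

test_that("Wald and LRT p-values agree in rank order for strong effects", {
  samples <- tibble::tibble(
    sample_id = c(paste0("a", 1:3), paste0("b", 1:3)),
    population = rep(c("A", "B"), each = 3), replicate = rep(1:3, 2)
  )
  withr::with_seed(7, {
    ng <- 200
    lfc <- rnorm(ng, 0, 2)
    cm <- tibble::tibble(gene = sprintf("g%03d", seq_len(ng)))
    for (s in 1:3) cm[[paste0("a", s)]] <- rnbinom(ng, mu = 200 * 2^lfc, size = 20)
    for (s in 1:3) cm[[paste0("b", s)]] <- rnbinom(ng, mu = 200, size = 20)
  })
  w <- de_wald(cm, samples, "A", "B")
  l <- de_lrt(cm, samples, c("A", "B"))
  rho <- cor(w$p, l$p[match(w$gene, l$gene)], method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("planted log2 = 3 effects are recovered with high sensitivity", {
  samples <- tibble::tibble(
    sample_id = c(paste0("a", 1:3), paste0("b", 1:3)),
    population = rep(c("A", "B"), each = 3), replicate = rep(1:3, 2)
  )
  withr::with_seed(21, {
    ng <- 300
    planted <- seq_len(50)
    mu_a <- rep(200, ng); mu_a[planted] <- 200 * 8
    cm <- tibble::tibble(gene = sprintf("g%03d", seq_len(ng)))
    for (s in 1:3) cm[[paste0("a", s)]] <- rnbinom(ng, mu = mu_a, size = 20)
    for (s in 1:3) cm[[paste0("b", s)]] <- rnbinom(ng, mu = 200, size = 20)
  })
  de <- de_wald(cm, samples, "A", "B")
  sens <- mean(de$padj[match(sprintf("g%03d", planted), de$gene)] < 0.05)
  expect_gte(sens, 0.9)
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
  withr::with_seed(3, {
    for (i in 1:50) {
      p <- runif(sample(2:40, 1))
      expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    }
  })
})

test_that("origin calls apply the strict padj and fold-change criterion", {
  nm <- normalize_counts(
    tibble::tibble(gene = c("e", "s1", "s2"),
                   Basal_1 = c(80L, 80L, 40L), panDF_1 = c(5L, 5L, 10L)),
    tibble::tibble(sample_id = c("Basal_1", "panDF_1"),
                   size_factor = c(1, 1))
  )
  samples <- tibble::tibble(sample_id = c("Basal_1", "panDF_1"),
                            population = c("Basal", "panDF"),
                            replicate = c(1L, 1L))
  de <- tibble::tibble(
    gene = c("e", "s1", "s2"),
    log2fc = c(log2(8), log2(8), log2(4)),  # FC 8, 8, exactly 4
    padj = c(0.01, 0.20, 0.01)
  )
  oc <- call_origin(de, nm, samples)
  expect_equal(oc$verdict, c("epithelial_enriched", "shared", "shared"))
  expect_true(all(oc$basal_fraction >= 0 & oc$basal_fraction <= 1))

  # dermal side is symmetric
  de$log2fc <- -de$log2fc
  oc2 <- call_origin(de, nm, samples)
  expect_equal(oc2$verdict[1], "dermal_enriched")
})
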