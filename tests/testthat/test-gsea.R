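snr_fixture <- function(values_a, values_b) {
  ng <- nrow(values_a)
  cm <- tibble::tibble(gene = sprintf("g%03d", seq_len(ng)))
  for (j in seq_len(ncol(values_a))) cm[[paste0("a", j)]] <- values_a[, j]
  for (j in seq_len(ncol(values_b))) cm[[paste0("b", j)]] <- values_b[, j]
  nm <- normalize_counts(
    cm, tibble::tibble(sample_id = names(cm)[-1],
                       size_factor = rep(1, ncol(values_a) + ncol(values_b))))
  samples <- tibble::tibble(
    sample_id = names(cm)[-1],
    population = rep(c("A", "B"), c(ncol(values_a), ncol(values_b))),
    replicate = c(seq_len(ncol(values_a)), seq_len(ncol(values_b)))
  )
  list(nm = nm, samples = samples)
}

test_that("signal-to-noise metric follows the floored-SD convention", {
  # identical groups -> all zero
  f <- snr_fixture(matrix(5L, 3, 2), matrix(5L, 3, 2))
  rl <- rank_signal_to_noise(f$nm, f$samples, "A", "B")
  expect_equal(rl$metric, rep(0, 3))

  # means 10 and 2 with sd 1 each: the 0.2*|mean| floor binds on group A,
  # giving (10 - 2) / (2 + 1) after flooring sd_A to 2 (sd_B = 1 > 0.4)
  a <- matrix(c(9, 10, 11), 1)
  b <- matrix(c(1, 2, 3), 1)
  f2 <- snr_fixture(a, b)
  rl2 <- rank_signal_to_noise(f2$nm, f2$samples, "A", "B")
  expect_equal(rl2$metric, (10 - 2) / (2 + 1), tolerance = 1e-12)

  # antisymmetry
  rl2r <- rank_signal_to_noise(f2$nm, f2$samples, "B", "A")
  expect_equal(rl2r$metric, -rl2$metric)

  few <- f2$samples
  few$population[1:2] <- "C"  # leaves a single A replicate
  expect_error(rank_signal_to_noise(f2$nm, few, "A", "B"), "2 replicates")
})

test_that("ranking breaks metric ties lexicographically by symbol", {
  cm <- tibble::tibble(gene = c("b", "a", "c"),
                       a1 = c(5L, 5L, 9L), a2 = c(5L, 5L, 9L),
                       b1 = c(5L, 5L, 1L), b2 = c(5L, 5L, 1L))
  nm <- normalize_counts(cm, tibble::tibble(sample_id = names(cm)[-1],
                                            size_factor = rep(1, 4)))
  samples <- tibble::tibble(sample_id = names(cm)[-1],
                            population = rep(c("A", "B"), each = 2),
                            replicate = rep(1:2, 2))
  rl <- rank_signal_to_noise(nm, samples, "A", "B")
  expect_equal(rl$gene, c("c", "a", "b"))
})

test_that("running-sum ES matches enumeration on the 4-gene example", {
  rl <- tibble::tibble(gene = c("g1", "g2", "g3", "g4"),
                       metric = c(3, 2, 1, 0.5))
  top <- gsea_es(rl, "g1", weight = 0)
  expect_equal(top$running$running_sum, c(1, 2 / 3, 1 / 3, 0),
               tolerance = 1e-12)
  expect_equal(top$es, 1)
  bottom <- gsea_es(rl, "g4", weight = 0)
  expect_equal(bottom$es, -1)
  expect_error(gsea_es(rl, "absent"), "no overlap")
})

test_that("ES equals the brute-force oracle and stays in [-1, 1]", {
  withr::with_seed(19, {
    for (i in 1:80) {
      n <- sample(5:50, 1)
      rl <- tibble::tibble(gene = sprintf("g%02d", seq_len(n)),
                           metric = sort(rnorm(n), decreasing = TRUE))
      set <- sample(rl$gene, sample(1:(n - 1), 1))
      w <- sample(c(0, 1), 1)
      got <- gsea_es(rl, set, weight = w)
      expect_equal(got$es, oracle_es(rl$gene, rl$metric, set, w),
                   tolerance = 1e-12)
      expect_true(abs(got$es) <= 1 + 1e-12)
      # running sum returns to zero at the list end when weight = 0
      if (w == 0) {
        expect_equal(got$running$running_sum[n], 0, tolerance = 1e-12)
      }
    }
  })
})

test_that("permutation significance is deterministic and finds planted sets", {
  sim <- simulate_counts(sim_config(seed = 3))
  nm <- normalize_counts(sim$counts)
  rl <- rank_signal_to_noise(nm, sim$samples, "DP", "panDF")
  planted_dp <- sim$truth$gene[sim$truth$program == 5]  # HG+DP program
  random_set <- withr::with_seed(99, sample(rl$gene, 20))
  gs <- run_gsea(rl, list(dp_program = planted_dp, random = random_set),
                 n_perm = 200, seed = 10)
  tab <- tidy(gs)
  expect_true(tab$significant[tab$set == "dp_program"])
  expect_lt(tab$p_value[tab$set == "dp_program"], 0.05)
  expect_lt(tab$fdr_q[tab$set == "dp_program"], 0.25)
  expect_false(tab$significant[tab$set == "random"])

  gs2 <- run_gsea(rl, list(dp_program = planted_dp, random = random_set),
                  n_perm = 200, seed = 10)
  expect_identical(tidy(gs), tidy(gs2))
  expect_error(run_gsea(rl, list(x = planted_dp), n_perm = 10), "100")
})

test_that("permutation p-values are calibrated for random sets", {
  # many random sets against one ranked list: nominal p approximately
  # uniform, so the p < 0.05 fraction stays near 0.05
  sim <- simulate_counts(sim_config(seed = 13, n_genes = 300,
                                    programs = list()))
  nm <- normalize_counts(sim$counts)
  rl <- rank_signal_to_noise(nm, sim$samples, "DP", "panDF")
  sets <- withr::with_seed(55, {
    lapply(1:300, function(i) sample(rl$gene, 15))
  })
  names(sets) <- paste0("s", 1:300)
  gs <- run_gsea(rl, sets, n_perm = 200, seed = 5)
  frac <- mean(tidy(gs)$p_value < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.10)
})

test_that("permutation p is invariant to metric rescaling when weight = 0", {
  rl <- tibble::tibble(gene = sprintf("g%02d", 1:40),
                       metric = sort(rnorm(40), decreasing = TRUE))
  set <- rl$gene[c(2, 5, 9)]
  g1 <- run_gsea(rl, list(s = set), n_perm = 150, weight = 0, seed = 4)
  rl2 <- rl
  rl2$metric <- rl2$metric * 17
  g2 <- run_gsea(rl2, list(s = set), n_perm = 150, weight = 0, seed = 4)
  expect_equal(tidy(g1)$p_value, tidy(g2)$p_value)
  expect_equal(tidy(g1)$es, tidy(g2)$es)
})

test_that("GMT files round-trip", {
  sets <- list(alpha = c("Lama5", "Npnt"), beta = c("Col1a1", "Bgn", "Dcn"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  expect_equal(read_gmt(f), sets)
})
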