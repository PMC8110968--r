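# Independent brute-force oracles, written from the definitions and kept
# free of the code paths they check.

# Average ranks computed from first principles (no rank()).
oracle_ranks <- function(x) {
  vapply(seq_along(x), function(i) {
    smaller <- sum(x < x[i])
    ties <- sum(x == x[i])
    smaller + (ties + 1) / 2
  }, numeric(1))
}

# Pearson correlation from the sum formulas.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_ranks(x), oracle_ranks(y))
}

# Step-up Benjamini-Hochberg from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Running-sum enrichment score by direct enumeration.
oracle_es <- function(genes, metric, set, weight) {
  n <- length(genes)
  hit <- genes %in% set
  nh <- sum(hit)
  w <- abs(metric)^weight
  denom <- sum(w[hit])
  run <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- cur + if (hit[i]) {
      if (denom > 0) w[i] / denom else 1 / nh
    } else {
      -1 / (n - nh)
    }
    run[i] <- cur
  }
  mx <- max(run)
  mn <- min(run)
  if (mx >= -mn - 1e-12) mx else mn
}

# Best 2-partition of scalars by enumerating every nonempty bipartition.
oracle_two_means_wcss <- function(x) {
  n <- length(x)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    grp <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    w <- sum((x[grp] - mean(x[grp]))^2) + sum((x[!grp] - mean(x[!grp]))^2)
    best <- min(best, w)
  }
  best
}

wcss_of_split <- function(x, high) {
  sum((x[high] - mean(x[high]))^2) + sum((x[!high] - mean(x[!high]))^2)
}

# Friedman chi-square from rank sums (tie-free inputs only).
oracle_friedman <- function(m) {
  ranks <- t(apply(m, 1, oracle_ranks))
  n <- nrow(m); k <- ncol(m)
  rj <- colSums(ranks)
  12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
}

# Tiny expression fixture shared across tests: 2 populations x 2 replicates.
tiny_counts <- function() {
  tibble::tibble(
    gene = c("Lama5", "Col1a1", "NMx1", "NMx2"),
    A_1 = c(10L, 5L, 100L, 7L),
    A_2 = c(12L, 4L, 90L, 8L),
    B_1 = c(40L, 50L, 10L, 70L),
    B_2 = c(44L, 55L, 12L, 77L)
  )
}

tiny_samples <- function() {
  tibble::tibble(
    sample_id = c("A_1", "A_2", "B_1", "B_2"),
    population = c("A", "A", "B", "B"),
    replicate = c(1L, 2L, 1L, 2L)
  )
}
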