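# Shared fixtures, all generated in code.

# Count tibble -> numeric matrix with gene rownames.
counts_matrix_for_tests <- function(counts) {
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

bic_series_conditions_for_tests <- function() {
  c("untreated", "bic_0.5h", "bic_1h", "bic_2h")
}

# Small default-structure experiment for fast end-to-end tests.
small_sim <- function(n_genes = 150, n_replicates = 3, seed = 7, ...) {
  cfg <- sim_config(n_genes = n_genes, n_replicates = n_replicates,
                    seed = seed, ...)
  simulate_experiment(cfg)
}

# A two-condition count matrix with given per-condition means (vectors over
# genes), NB dispersion alpha, n replicates per group; library factors 1.
two_group_counts <- function(mean_a, mean_b, alpha, n_per_group, seed = 1) {
  stopifnot(length(mean_a) == length(mean_b))
  set.seed(seed)
  draw <- function(mu) {
    if (alpha <= 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / alpha)
  }
  n_genes <- length(mean_a)
  m <- matrix(0L, n_genes, 2 * n_per_group)
  for (j in seq_len(n_per_group)) m[, j] <- draw(mean_a)
  for (j in seq_len(n_per_group)) m[, n_per_group + j] <- draw(mean_b)
  rownames(m) <- sprintf("g%05d", seq_len(n_genes))
  colnames(m) <- c(paste0("untreated_r", seq_len(n_per_group)),
                   paste0("bic_2h_r", seq_len(n_per_group)))
  m
}

# Design matching two_group_counts (untreated vs 2 h Bic).
two_group_design <- function(n_per_group) {
  d <- study_design(n_per_group, conditions = c("untreated", "bic_2h"))
  d[order(match(d$condition, c("untreated", "bic_2h"))), ]
}

# Independently written Benjamini-Hochberg oracle: for each p-value, the
# minimum over larger-or-equal p-values of m * p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  cand <- m * ps / seq_len(m)
  adj <- vapply(seq_len(m), function(i) min(1, min(cand[i:m])), numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force complete-linkage agglomeration: returns merge heights and the
# cluster memberships after each merge, computed greedily from the raw
# distance matrix with max-linkage between clusters.
complete_linkage_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_h)
    partitions <- c(partitions, list(lapply(clusters, sort)))
  }
  list(heights = heights, partitions = partitions)
}

# All permutations of seq_len(n) as a matrix (one permutation per row).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-i]
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1
    }
  }
  out
}

# Mean silhouette width of labels on 2-D coordinates (Euclidean).
mean_silhouette <- function(coords, labels) {
  d <- as.matrix(stats::dist(coords))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
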