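test_that("size factors recover known sample scalings", {
  set.seed(1)
  base <- rpois(80, 200) + 1
  m <- cbind(s1 = base, s2 = base)
  rownames(m) <- sprintf("g%03d", seq_len(80))
  norm <- estimate_size_factors(m)
  expect_equal(norm$size_factors$size_factor, c(1, 1))

  # sample B three times sample A: centered factors (3^-1/2, 3^1/2)
  m2 <- cbind(s1 = base, s2 = 3L * base)
  rownames(m2) <- rownames(m)
  norm2 <- estimate_size_factors(m2)
  expect_equal(norm2$size_factors$size_factor, c(3^(-0.5), 3^(0.5)),
               tolerance = 1e-12)
  expect_equal(prod(norm2$size_factors$size_factor), 1, tolerance = 1e-12)

  expect_error(estimate_size_factors(matrix(0, 3, 2,
                                            dimnames = list(letters[1:3],
                                                            c("a", "b")))),
               "normalization error")
})

test_that("dispersion estimation recovers simulated values", {
  # Poisson data: median estimate collapses to (near) zero
  m <- two_group_counts(rep(100, 300), rep(100, 300), alpha = 0,
                        n_per_group = 50, seed = 4)
  d <- two_group_design(50)
  norm <- estimate_size_factors(m, d)
  disp <- estimate_dispersions(m, norm)
  expect_lte(median(disp$dispersion), 0.01)

  # NB alpha = 0.5 at mean 100: mean estimate within 20 percent
  m2 <- two_group_counts(rep(100, 400), rep(100, 400), alpha = 0.5,
                         n_per_group = 50, seed = 5)
  disp2 <- estimate_dispersions(m2, estimate_size_factors(m2, d))
  expect_lt(abs(mean(disp2$dispersion) - 0.5), 0.1)

  # constant replicate counts hit the floor and are flagged
  m3 <- matrix(50L, 5, 4,
               dimnames = list(paste0("g", 1:5),
                               c("untreated_r1", "untreated_r2",
                                 "bic_2h_r1", "bic_2h_r2")))
  d3 <- two_group_design(2)
  disp3 <- estimate_dispersions(m3, estimate_size_factors(m3, d3))
  expect_true(all(disp3$clamped))
  expect_true(all(disp3$dispersion == 1e-8))
})

test_that("Wald contrast recovers a known fold change and flags zeros", {
  # mostly null genes anchor the normalization; balanced up/down DE genes
  n <- 400
  mean_a <- rep(200, n)
  mean_b <- mean_a
  doubled <- 101:140
  halved <- 141:180
  mean_b[doubled] <- 400
  mean_b[halved] <- 100
  m <- two_group_counts(mean_a, mean_b, alpha = 0.02, n_per_group = 5,
                        seed = 6)
  m[1, ] <- 0L                              # undetectable gene
  m[2, 1:5] <- 0L                           # zero in denominator group only
  d <- two_group_design(5)
  norm <- estimate_size_factors(m, d)
  disp <- estimate_dispersions(m, norm)
  res <- test_contrast(m, norm, disp, "bic_2h", "untreated")
  expect_equal(res$status[1], "NA")
  expect_true(is.na(res$l2fc_mle[1]))
  expect_true(res$boundary[2])
  expect_equal(median(res$l2fc_mle[doubled]), 1, tolerance = 0.1)
  expect_gte(mean(res$fdr[doubled] < 0.05), 0.95)
})

test_that("the NB IRLS fit matches an independent GLM fit per gene", {
  skip_if_not_installed("MASS")
  set.seed(8)
  base <- rpois(40, 150) + 20
  shift <- base
  shift[1:10] <- 2 * shift[1:10]
  m <- two_group_counts(base, shift, alpha = 0.05, n_per_group = 5,
                        seed = 8)
  d <- two_group_design(5)
  norm <- estimate_size_factors(m, d)
  disp <- estimate_dispersions(m, norm)
  res <- test_contrast(m, norm, disp, "bic_2h", "untreated")
  sf <- norm$size_factors$size_factor
  group <- factor(rep(c("a", "b"), each = 5), levels = c("a", "b"))
  for (g in c(1, 7, 23)) {
    alpha_g <- disp$dispersion[g]
    fit <- stats::glm(m[g, ] ~ group + offset(log(sf)),
                      family = MASS::negative.binomial(theta = 1 / alpha_g))
    co <- summary(fit, dispersion = 1)$coefficients
    expect_equal(res$l2fc_mle[g], co[2, 1] / log(2), tolerance = 1e-5)
    expect_equal(res$se[g], co[2, 2] / log(2), tolerance = 1e-4)
  }
})

test_that("null p-values are near-uniform and BH controls selections", {
  cfg <- sim_config(n_genes = 2000,
                    archetype_fractions = c(unresponsive = 1), seed = 9)
  sim <- simulate_experiment(cfg)
  norm <- estimate_size_factors(sim$counts, sim$design)
  disp <- estimate_dispersions(sim$counts, norm)
  res <- test_contrast(sim$counts, norm, disp, "bic_1h", "untreated")
  p <- res$p_value[res$status == "ok"]
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  expect_lte(mean(res$fdr < 0.05, na.rm = TRUE), 0.07)
})

test_that("shrinkage matches the conjugate posterior mode and preserves sign", {
  res <- tibble::tibble(
    gene_id = paste0("g", 1:4),
    contrast = "x", base_mean = 100,
    l2fc_mle = c(0, 2, 2, -1.5),
    l2fc_shrunk = NA_real_,
    se = c(0.3, 5, 1e-4, 0.5),
    stat = NA_real_, p_value = NA_real_, fdr = NA_real_,
    status = "ok", boundary = FALSE
  )
  tau <- 0.8
  out <- shrink_lfc(res, prior_scale = tau)
  # independent oracle: numeric maximization of the log posterior
  post_mode <- vapply(seq_len(4), function(i) {
    stats::optimize(function(b) {
      stats::dnorm(res$l2fc_mle[i], b, res$se[i], log = TRUE) +
        stats::dnorm(b, 0, tau, log = TRUE)
    }, interval = c(-10, 10), maximum = TRUE, tol = 1e-12)$maximum
  }, numeric(1))
  expect_equal(out$l2fc_shrunk, post_mode, tolerance = 1e-6)
  expect_equal(out$l2fc_shrunk[1], 0)
  expect_lt(abs(out$l2fc_shrunk[2]), 0.5 * abs(res$l2fc_mle[2]))
  expect_equal(out$l2fc_shrunk[3], 2, tolerance = 1e-6)
  expect_true(all(sign(out$l2fc_shrunk) == sign(res$l2fc_mle)))
  expect_true(all(abs(out$l2fc_shrunk) <= abs(res$l2fc_mle) + 1e-12))
})

test_that("BH adjustment validates input and handles NAs", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(c(0.01, NA, 0.04)),
               c(0.02, NA, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("rescaling one sample leaves contrast statistics stable", {
  m <- two_group_counts(rpois(150, 120) + 30, rpois(150, 120) + 30,
                        alpha = 0.03, n_per_group = 4, seed = 10)
  d <- two_group_design(4)
  run <- function(mm) {
    norm <- estimate_size_factors(mm, d)
    disp <- estimate_dispersions(mm, norm)
    test_contrast(mm, norm, disp, "bic_2h", "untreated")
  }
  r1 <- run(m)
  m2 <- m
  m2[, 1] <- 4L * m2[, 1]
  r2 <- run(m2)
  n1 <- estimate_size_factors(m, d)$size_factors$size_factor
  n2 <- estimate_size_factors(m2, d)$size_factors$size_factor
  # factor ratios (centering-independent) scale by 4 for the scaled sample
  expect_equal(n2[1] / n2[2], 4 * n1[1] / n1[2], tolerance = 0.05)
  expect_lt(max(abs(r1$l2fc_mle - r2$l2fc_mle)), 0.05)
  expect_gt(cor(r1$stat, r2$stat), 0.99)
})

test_that("the engine agrees with DESeq2 on a simulated fixture", {
  skip_if_not_installed("DESeq2")
  cfg <- sim_config(n_genes = 300, seed = 12)
  sim <- simulate_experiment(cfg)
  norm <- estimate_size_factors(sim$counts, sim$design)
  disp <- estimate_dispersions(sim$counts, norm)
  res <- test_contrast(sim$counts, norm, disp, "bic_2h", "untreated")

  m <- counts_matrix_for_tests(sim$counts)
  keep <- sim$design$condition %in% c("untreated", "bic_2h")
  coldata <- data.frame(condition = factor(
    sim$design$condition[keep], levels = c("untreated", "bic_2h")))
  dds <- DESeq2::DESeqDataSetFromMatrix(m[, keep], coldata, ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds)
  ok <- res$status == "ok" & !is.na(ref$log2FoldChange)
  expect_gt(cor(res$l2fc_mle[ok], ref$log2FoldChange[ok]), 0.98)
  expect_lt(median(abs(res$l2fc_mle[ok] - ref$log2FoldChange[ok])), 0.1)
  both_sig <- res$fdr[ok] < 0.05 & ref$padj[ok] < 0.05
  either_sig <- res$fdr[ok] < 0.05 | ref$padj[ok] < 0.05
  expect_gt(sum(both_sig, na.rm = TRUE) / sum(either_sig, na.rm = TRUE), 0.8)
})

test_that("merged tables take the union of analysis-ready genes", {
  a <- tibble::tibble(gene_id = c("g1", "g2", "g3"), contrast = "c1",
                      base_mean = 1, l2fc_mle = 0.5, l2fc_shrunk = 0.4,
                      se = 0.1, stat = 5, p_value = 0.01, fdr = 0.01,
                      status = c("ok", "NA", "ok"), boundary = FALSE)
  b <- a
  b$contrast <- "c2"
  b$status <- c("NA", "ok", "NA")
  merged <- merge_contrasts(list(c1 = a, c2 = b))
  expect_setequal(merged$gene_id, c("g1", "g2", "g3"))
  expect_true(all(c("c1_l2fc", "c2_fdr") %in% names(merged)))
})
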