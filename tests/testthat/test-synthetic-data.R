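test_that("configuration validation rejects bad fractions and multipliers", {
  expect_error(sim_config(10, archetype_fractions = c(unresponsive = 0.5)),
               "sum to 1")
  bad_profiles <- effect_profiles_default()
  bad_profiles$active[1] <- -0.2
  expect_error(sim_config(10, effect_profiles = bad_profiles), "> 0")
  expect_error(sim_config(10, dispersion_fixed = -1), ">= 0")
})

test_that("an all-unresponsive configuration yields flat condition means", {
  cfg <- sim_config(n_genes = 25,
                    archetype_fractions = c(unresponsive = 1),
                    seed = 3)
  truth <- simulate_truth(cfg)
  mean_cols <- grep("^mean_", names(truth), value = TRUE)
  m <- as.matrix(truth[mean_cols])
  expect_true(all(abs(m - m[, 1]) < 1e-12))
  expect_true(all(truth$passive_effect == 1))
})

test_that("intervention means follow the configured multipliers", {
  profiles <- tibble::tibble(profile = "p", passive = 0.5, active = 0.25,
                             tboa = 0.7, prob = 1)
  cfg <- sim_config(n_genes = 40,
                    archetype_fractions = c(late.induced = 1),
                    effect_profiles = profiles, seed = 5)
  truth <- simulate_truth(cfg)
  # TTX level is the passive multiple of the protocol-endpoint Bic level
  expect_equal(truth$mean_lp_ttx, 0.5 * truth$mean_bic_2h)
  # TTX/NMDA is the active multiple of the TTX level
  expect_equal(truth$mean_lp_ttx_nmda, 0.25 * truth$mean_lp_ttx)
  expect_equal(truth$mean_lp_tboa, 0.7 * truth$mean_bic_2h)
  # late kinetics: rising from 1 h to 2 h, peak fold at 2 h
  expect_true(all(truth$mean_bic_2h > truth$mean_bic_1h))
  expect_equal(truth$mean_bic_2h, truth$baseline * truth$fold)
})

test_that("archetype proportions match configured fractions within one gene", {
  cfg1 <- sim_config(n_genes = 10000, seed = 1)
  cfg2 <- sim_config(n_genes = 10000, seed = 99)
  t1 <- simulate_truth(cfg1)
  t2 <- simulate_truth(cfg2)
  expect_false(isTRUE(all.equal(t1$baseline, t2$baseline)))
  for (tt in list(t1, t2)) {
    counts <- table(tt$archetype)
    for (a in names(cfg1$archetype_fractions)) {
      expect_lte(abs(counts[[a]] - cfg1$archetype_fractions[[a]] * 10000), 1)
    }
  }
})

test_that("truth and counts are bit-identical for identical config and seed", {
  cfg <- sim_config(n_genes = 60, n_replicates = 2, seed = 11)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$counts, b$counts)
})

test_that("zero dispersion gives Poisson-like variance-to-mean ratios", {
  cfg <- sim_config(n_genes = 300, baseline_meanlog = log(200),
                    baseline_sdlog = 0.5, dispersion_fixed = 0,
                    lib_size_range = c(1, 1),
                    archetype_fractions = c(unresponsive = 1), seed = 21)
  truth <- simulate_truth(cfg)
  design <- study_design(200, conditions = "untreated")
  counts <- simulate_counts(truth, design, cfg)
  m <- counts_matrix_for_tests(counts)
  means <- rowMeans(m)
  vars <- apply(m, 1, var)
  keep <- means >= 50
  ratio <- vars[keep] / means[keep]
  expect_gte(mean(ratio >= 0.8 & ratio <= 1.25), 0.95)
})

test_that("unresponsive genes pass a known-dispersion NB likelihood-ratio test", {
  cfg <- sim_config(n_genes = 1000, lib_size_range = c(1, 1),
                    archetype_fractions = c(unresponsive = 1), seed = 33)
  sim <- simulate_experiment(cfg)
  m <- counts_matrix_for_tests(sim$counts)
  a_idx <- which(sim$design$condition == "untreated")
  b_idx <- which(sim$design$condition == "bic_2h")
  # independent oracle: NB LRT with the true dispersion, chi-square df 1
  lrt_p <- vapply(seq_len(nrow(m)), function(g) {
    ya <- m[g, a_idx]; yb <- m[g, b_idx]
    size <- 1 / max(sim$truth$dispersion[g], 1e-12)
    ll <- function(y, mu) sum(stats::dnbinom(y, mu = mu, size = size,
                                             log = TRUE))
    l0 <- ll(c(ya, yb), mean(c(ya, yb)))
    l1 <- ll(ya, mean(ya)) + ll(yb, mean(yb))
    stats::pchisq(2 * (l1 - l0), df = 1, lower.tail = FALSE)
  }, numeric(1))
  expect_gte(mean(lrt_p > 0.05, na.rm = TRUE), 0.94)
})

test_that("zero replicates give an empty matrix with the full gene index", {
  cfg <- sim_config(n_genes = 15, n_replicates = 0, seed = 2)
  truth <- simulate_truth(cfg)
  counts <- simulate_counts(truth, study_design(0), cfg)
  expect_equal(names(counts), "gene_id")
  expect_equal(counts$gene_id, truth$gene_id)
})

test_that("a design condition missing from truth is an error", {
  cfg <- sim_config(n_genes = 10, seed = 2)
  truth <- simulate_truth(cfg)
  truth$mean_lp_tboa <- NULL
  expect_error(simulate_counts(truth, study_design(2), cfg),
               "absent from truth")
})

test_that("realized gene-condition means converge to configured means", {
  cfg <- sim_config(n_genes = 120, baseline_meanlog = log(150),
                    baseline_sdlog = 0.3, lib_size_range = c(1, 1),
                    seed = 13)
  truth <- simulate_truth(cfg)
  design <- study_design(500, conditions = c("untreated", "bic_2h"))
  counts <- simulate_counts(truth, design, cfg)
  m <- counts_matrix_for_tests(counts)
  for (cond in c("untreated", "bic_2h")) {
    idx <- which(design$condition == cond)
    realized <- rowMeans(m[, idx])
    expected <- truth[[paste0("mean_", cond)]]
    keep <- expected >= 50
    expect_lt(max(abs(realized[keep] - expected[keep]) / expected[keep]),
              0.05)
  }
})

test_that("truth_eval returns perfect scores for truth-identical calls", {
  cfg <- sim_config(n_genes = 200, seed = 17)
  truth <- simulate_truth(cfg)
  induced <- truth$archetype %in% c("early.induced", "late.induced")
  ann <- tibble::tibble(
    gene_id = truth$gene_id,
    activity_class = ifelse(truth$archetype == "transient.induced",
                            "transient", truth$archetype),
    passive = ifelse(induced & truth$passive_effect < 1, "down", "ns"),
    active = ifelse(induced & truth$active_effect < 1, "down", "ns"),
    tboa = ifelse(truth$archetype == "late.induced" &
                    truth$tboa_effect < 1, "down", "ns")
  )
  ev <- truth_eval(ann, truth)
  expect_true(all(ev$sensitivity[ev$n_true > 0] == 1))
  expect_true(all(ev$fdr[ev$n_called > 0] == 0))

  # all-resistant calls: zero sensitivity for every shut-off component
  ann$passive <- "ns"; ann$active <- "ns"; ann$tboa <- "ns"
  ev0 <- truth_eval(ann, truth)
  shut <- ev0[ev0$section == "shutoff" & ev0$n_true > 0, ]
  expect_true(all(shut$sensitivity == 0))
})

test_that("truth_eval rejects mismatched gene universes", {
  cfg <- sim_config(n_genes = 20, seed = 1)
  truth <- simulate_truth(cfg)
  ann <- tibble::tibble(gene_id = c("x", truth$gene_id[-1]),
                        activity_class = "unresponsive")
  expect_error(truth_eval(ann, truth), "universes")
})
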