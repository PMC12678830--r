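make_bic_contrast <- function(genes, lfc, fdr, name) {
  tibble::tibble(gene_id = genes, contrast = name, base_mean = 100,
                 l2fc_mle = lfc, l2fc_shrunk = lfc, se = 0.1,
                 stat = lfc / 0.1, p_value = fdr, fdr = fdr,
                 status = ifelse(is.na(lfc), "NA", "ok"), boundary = FALSE)
}

# Build the three Bic contrasts plus condition means from per-gene profiles:
# rows of `profiles` are normalized means over (untreated, 0.5 h, 1 h, 2 h);
# significance is supplied per time point.
bic_fixture <- function(profiles, fdr05, fdr1, fdr2) {
  genes <- rownames(profiles)
  lfc <- log2((profiles[, 2:4] + 1) / (profiles[, 1] + 1))
  contrasts <- list(
    "bic_0.5h_vs_untreated" = make_bic_contrast(genes, lfc[, 1], fdr05,
                                                "bic_0.5h_vs_untreated"),
    "bic_1h_vs_untreated" = make_bic_contrast(genes, lfc[, 2], fdr1,
                                              "bic_1h_vs_untreated"),
    "bic_2h_vs_untreated" = make_bic_contrast(genes, lfc[, 3], fdr2,
                                              "bic_2h_vs_untreated"))
  cm <- profiles
  colnames(cm) <- c("untreated", "bic_0.5h", "bic_1h", "bic_2h")
  list(contrasts = contrasts, condition_means = cm)
}

test_that("categorization follows the time-course selection rules", {
  profiles <- rbind(
    early = c(10, 50, 80, 40),     # peak at 1 h
    late = c(10, 12, 40, 80),      # still rising 1 -> 2 h
    transient = c(10, 60, 12, 11), # up only at 0.5 h
    flat = c(10, 10, 11, 10),
    down_early = c(80, 30, 20, 60),
    down_late = c(80, 70, 40, 10)
  )
  fx <- bic_fixture(profiles,
                    fdr05 = c(0.01, 0.9, 0.001, 0.8, 0.2, 0.6),
                    fdr1 = c(0.001, 0.03, 0.6, 0.7, 0.01, 0.04),
                    fdr2 = c(0.04, 0.001, 0.9, 0.9, 0.2, 0.001))
  cls <- classify_activity(fx$contrasts, fx$condition_means)
  expect_equal(cls$activity_class,
               c("early.induced", "late.induced", "transient",
                 "unresponsive", "early.repressed", "late.repressed"))
  expect_equal(cls$protocol, c("SP", "LP", "none", "none", "SP", "LP"))
})

test_that("every gene receives exactly one class", {
  sim <- small_sim(n_genes = 250, n_replicates = 3, seed = 19)
  de <- run_contrasts(sim$counts, sim$design)
  cls <- classify_activity(de$contrasts,
                           de$normalization$condition_means)
  expect_equal(nrow(cls), 250)
  expect_true(all(cls$activity_class %in%
                    c("early.induced", "late.induced", "early.repressed",
                      "late.repressed", "transient", "unresponsive")))
  expect_false(anyNA(cls$activity_class))
})

test_that("raising the fdr cutoff never shrinks the responsive set", {
  sim <- small_sim(n_genes = 200, n_replicates = 3, seed = 23)
  de <- run_contrasts(sim$counts, sim$design)
  cm <- de$normalization$condition_means
  responsive_n <- vapply(c(0.01, 0.05, 0.2), function(cut) {
    cls <- classify_activity(de$contrasts, cm, fdr_cutoff = cut)
    sum(cls$activity_class != "unresponsive")
  }, numeric(1))
  expect_true(all(diff(responsive_n) >= 0))
})

test_that("the ANOVA screen is calibrated under the null and powered on ramps", {
  cfg <- sim_config(n_genes = 1000,
                    archetype_fractions = c(unresponsive = 1), seed = 29)
  sim <- simulate_experiment(cfg)
  norm <- estimate_size_factors(sim$counts, sim$design)
  scr <- anova_screen(norm)
  expect_lte(mean(scr$anova_fdr < 0.05), 0.07)

  # an 8-fold late ramp at mean 200 is detected at stringent FDR
  cfg2 <- sim_config(n_genes = 300, baseline_meanlog = log(200),
                     baseline_sdlog = 0.2, fold_range = c(8, 8.0001),
                     archetype_fractions = c(unresponsive = 0.8,
                                             late.induced = 0.2),
                     seed = 31)
  sim2 <- simulate_experiment(cfg2)
  norm2 <- estimate_size_factors(sim2$counts, sim2$design)
  scr2 <- anova_screen(norm2)
  ramp <- sim2$truth$archetype == "late.induced"
  expect_gte(mean(scr2$anova_fdr[ramp] < 0.01), 0.95)
})

test_that("the vectorized F statistic matches stats::aov per gene", {
  sim <- small_sim(n_genes = 30, n_replicates = 4, seed = 37)
  norm <- estimate_size_factors(sim$counts, sim$design)
  scr <- anova_screen(norm)
  keep <- norm$design$condition %in% bic_series_conditions_for_tests()
  grp <- factor(norm$design$condition[keep])
  for (g in c(2, 11, 27)) {
    y <- norm$normalized[g, keep]
    fit <- summary(stats::aov(y ~ grp))[[1]]
    expect_equal(scr$anova_f[g], fit[["F value"]][1], tolerance = 1e-10)
    expect_equal(scr$anova_p[g], fit[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("the ANOVA screen rejects designs without replication", {
  sim <- small_sim(n_genes = 20, n_replicates = 1, seed = 3)
  norm <- estimate_size_factors(sim$counts, sim$design)
  expect_error(anova_screen(norm), "2 replicates")
})

test_that("candidate selection applies all three filters", {
  merged <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    c1_l2fc = c(1, NA, 1, 1),
    c1_l2fc_mle = 1, c1_p = 0.01, c1_fdr = 0.01
  )
  cls <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    activity_class = c("late.induced", "late.induced", "transient",
                       "late.induced"),
    protocol = c("LP", "LP", "none", "LP"),
    anova_p = 0.001,
    anova_fdr = c(0.001, 0.001, 0.001, 0.5)
  )
  # g2 lacks an L2FC, g3 has no class, g4 fails the ANOVA cutoff
  expect_equal(select_candidates(cls, merged), "g1")
  expect_error(select_candidates(dplyr::select(cls, -"anova_fdr"), merged),
               "anova_fdr")
})

test_that("early/late archetypes are recovered and transients excluded", {
  cfg <- sim_config(n_genes = 1500, seed = 41)
  sim <- simulate_experiment(cfg)
  de <- run_contrasts(sim$counts, sim$design)
  norm <- de$normalization
  cls <- classify_activity(de$contrasts, norm$condition_means,
                           anova = anova_screen(norm))
  truth_class <- ifelse(sim$truth$archetype == "transient.induced",
                        "transient", sim$truth$archetype)
  for (target in c("early.induced", "late.induced")) {
    is_t <- truth_class == target
    expect_gte(mean(cls$activity_class[is_t] == target), 0.85)
  }
  transients <- truth_class == "transient"
  excluded <- !cls$activity_class[transients] %in%
    c("early.induced", "late.induced", "early.repressed", "late.repressed")
  expect_gte(mean(excluded), 0.9)
})
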