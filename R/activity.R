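#' Per-gene ANOVA screen across the Bic induction series
#'
#' One-way ANOVA F-test per gene of size-factor-normalized counts across the
#' bicuculline time series (untreated, 0.5 h, 1 h, 2 h), with BH adjustment
#' across genes. The F statistic is computed vectorized over genes from the
#' within/between group sums of squares (identical to [stats::aov()] per
#' gene, see tests).
#'
#' @param normalization A [estimate_size_factors()] result carrying a design
#'   that contains the four Bic-series conditions with >= 2 replicates each.
#' @param conditions Conditions forming the groups (default the Bic series).
#' @return A tibble `gene_id`, `anova_f`, `anova_p`, `anova_fdr`. Genes with
#'   zero variance within every group and equal means get `anova_p = 1`.
#' @export
anova_screen <- function(normalization,
                         conditions = bic_series_conditions()) {
  stopifnot(inherits(normalization, "shutoff_normalization"))
  design <- normalization$design
  if (is.null(design)) stop("normalization must carry a design", call. = FALSE)
  idx <- which(design$condition %in% conditions)
  groups <- design$condition[idx]
  k <- length(unique(groups))
  if (k < 2) stop("ANOVA screen needs >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("ANOVA screen needs >= 2 replicates per group", call. = FALSE)
  }
  x <- normalization$normalized[, idx, drop = FALSE]
  n <- ncol(x)
  grand <- rowMeans(x)
  ss_between <- numeric(nrow(x))
  ss_within <- numeric(nrow(x))
  for (g in unique(groups)) {
    cols <- which(groups == g)
    gm <- rowMeans(x[, cols, drop = FALSE])
    ss_between <- ss_between + length(cols) * (gm - grand)^2
    ss_within <- ss_within + rowSums((x[, cols, drop = FALSE] - gm)^2)
  }
  df1 <- k - 1
  df2 <- n - k
  f <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  # constant genes: no evidence of change
  degenerate <- ss_within == 0 & ss_between == 0
  f[degenerate] <- 0
  p[degenerate] <- 1
  tibble::tibble(gene_id = rownames(x), anova_f = unname(f),
                 anova_p = unname(p), anova_fdr = bh_adjust(unname(p)))
}

#' Categorize genes by their Bic time-course response
#'
#' Assigns each gene one activity class from its response to the bicuculline
#' induction series. A gene is responsive when at least one Bic-vs-untreated
#' contrast is significant (`fdr < fdr_cutoff`); its direction (induced or
#' repressed) is the sign of the shrunken L2FC at the most significant time
#' point. Induced genes significant only at 0.5 h are `transient` (excluded
#' from protocol allocation; the same rule is applied symmetrically to
#' repressed genes). Otherwise the class-defining extremum is decided
#' between the 1 h and 2 h normalized condition means: highest (lowest, for
#' repressed) at 1 h gives an `early` class allocated to the short protocol,
#' and a level still rising (falling) from 1 h to 2 h gives a `late` class
#' allocated to the long protocol; means within `tie_rel` relative
#' difference are treated as still rising and classified late.
#'
#' With `strict = TRUE` (default) the class additionally requires
#' significance at the class-defining time point itself; responsive genes
#' failing that are left `unresponsive`. With `strict = FALSE` significance
#' anywhere in the series suffices.
#'
#' @param bic_contrasts Named list (or list-like) of the three
#'   [test_contrast()] tibbles `bic_0.5h_vs_untreated`, `bic_1h_vs_untreated`,
#'   `bic_2h_vs_untreated`.
#' @param condition_means Gene-by-condition matrix of normalized count means
#'   (from [estimate_size_factors()]).
#' @param anova Optional [anova_screen()] tibble merged into the output.
#' @param fdr_cutoff Significance threshold (default 0.05).
#' @param strict Require significance at the class-defining time (default
#'   `TRUE`).
#' @param tie_rel Relative 1 h/2 h tie margin treated as late (default 0.01).
#' @return A tibble `gene_id`, `activity_class` (`early.induced`,
#'   `late.induced`, `early.repressed`, `late.repressed`, `transient`,
#'   `unresponsive`), `protocol` (`SP`, `LP`, `none`), plus `anova_p`,
#'   `anova_fdr` when `anova` is given.
#' @export
classify_activity <- function(bic_contrasts, condition_means, anova = NULL,
                              fdr_cutoff = 0.05, strict = TRUE,
                              tie_rel = 0.01) {
  need <- c("bic_0.5h_vs_untreated", "bic_1h_vs_untreated",
            "bic_2h_vs_untreated")
  missing <- setdiff(need, names(bic_contrasts))
  if (length(missing) > 0) {
    stop("missing Bic contrast(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  genes <- bic_contrasts[[need[1]]]$gene_id
  lfc <- sapply(need, function(nm) {
    x <- bic_contrasts[[nm]]
    x$l2fc_shrunk[match(genes, x$gene_id)]
  })
  fdr <- sapply(need, function(nm) {
    x <- bic_contrasts[[nm]]
    x$fdr[match(genes, x$gene_id)]
  })
  m1 <- condition_means[match(genes, rownames(condition_means)), "bic_1h"]
  m2 <- condition_means[match(genes, rownames(condition_means)), "bic_2h"]

  sig <- !is.na(fdr) & fdr < fdr_cutoff
  sig_up <- sig & !is.na(lfc) & lfc > 0
  sig_down <- sig & !is.na(lfc) & lfc < 0

  classify_one <- function(i) {
    if (!any(sig[i, ])) return("unresponsive")
    best <- which.min(ifelse(sig[i, ], fdr[i, ], Inf))
    induced <- lfc[i, best] > 0
    s_dir <- if (induced) sig_up[i, ] else sig_down[i, ]
    if (s_dir[1] && !s_dir[2] && !s_dir[3]) return("transient")
    if (!any(s_dir)) return("unresponsive") # significant only opposite to its own direction
    # class-defining extremum between 1 h and 2 h; ties go late
    rel_gap <- abs(m1[i] - m2[i]) / max(m1[i], m2[i], .Machine$double.eps)
    late_extremum <- if (induced) m2[i] >= m1[i] || rel_gap <= tie_rel
                     else m2[i] <= m1[i] || rel_gap <= tie_rel
    if (strict) {
      if (late_extremum && s_dir[3]) {
        return(if (induced) "late.induced" else "late.repressed")
      }
      if (!late_extremum && s_dir[2]) {
        return(if (induced) "early.induced" else "early.repressed")
      }
      # responsive but not significant at its extremum time
      return("unresponsive")
    }
    if (late_extremum) {
      if (induced) "late.induced" else "late.repressed"
    } else {
      if (induced) "early.induced" else "early.repressed"
    }
  }
  cls <- vapply(seq_along(genes), classify_one, character(1))
  protocol <- dplyr::case_when(
    cls %in% c("early.induced", "early.repressed") ~ "SP",
    cls %in% c("late.induced", "late.repressed") ~ "LP",
    TRUE ~ "none"
  )
  out <- tibble::tibble(gene_id = genes, activity_class = cls,
                        protocol = protocol)
  if (!is.null(anova)) {
    out <- dplyr::left_join(
      out, dplyr::select(anova, "gene_id", "anova_p", "anova_fdr"),
      by = "gene_id")
  }
  out
}

#' Select candidate genes for embedding and concordance analyses
#'
#' Candidates must (1) change expression over the Bic series (ANOVA FDR below
#' `anova_fdr_cutoff`), (2) be classified to an activity class (early/late,
#' induced or repressed; transient and unresponsive genes are excluded), and
#' (3) carry an L2FC value in every pair-wise comparison of the merged table
#' (genes undetectable in any condition are dropped).
#'
#' @param classification [classify_activity()] output containing `anova_fdr`.
#' @param merged Wide merged table from [run_contrasts()].
#' @param anova_fdr_cutoff ANOVA FDR threshold (default 0.01).
#' @param classes Classes eligible as candidates (default the four
#'   early/late classes).
#' @return Character vector of candidate gene ids.
#' @export
select_candidates <- function(classification, merged,
                              anova_fdr_cutoff = 0.01,
                              classes = c("early.induced", "late.induced",
                                          "early.repressed",
                                          "late.repressed")) {
  if (!"anova_fdr" %in% names(classification)) {
    stop("classification must carry anova_fdr (pass anova to classify_activity)",
         call. = FALSE)
  }
  lfc_cols <- grep("_l2fc$", names(merged), value = TRUE)
  complete <- merged$gene_id[
    rowSums(is.na(merged[lfc_cols])) == 0
  ]
  keep <- classification$gene_id[
    !is.na(classification$anova_fdr) &
      classification$anova_fdr < anova_fdr_cutoff &
      classification$activity_class %in% classes
  ]
  intersect(keep, complete)
}
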