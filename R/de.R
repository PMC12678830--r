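#' Method-of-moments negative-binomial dispersion estimates
#'
#' Estimates one NB dispersion \eqn{\alpha_g} per gene by pooling
#' method-of-moments estimates across conditions: within each condition with
#' at least two replicates, \eqn{\hat\alpha = (v - m)/m^2} from the mean and
#' variance of normalized counts, combined across conditions with weights
#' proportional to residual degrees of freedom. Estimates are floored at
#' `floor` (default 1e-8, effectively Poisson) and flagged when clamped.
#' The NB parameterization throughout the package is variance
#' \eqn{= \mu + \alpha\mu^2}; \eqn{\alpha} is the reciprocal of the `size`
#' parameter used by [stats::rnbinom()].
#'
#' An optional mean-dispersion trend (loess of log dispersion on log mean)
#' can be used to smooth per-gene estimates toward the fitted curve.
#'
#' @param counts Count tibble or matrix.
#' @param normalization A [estimate_size_factors()] result carrying a design.
#' @param floor Lower bound for the estimate.
#' @param trend If `TRUE`, replace each estimate by the geometric mean of the
#'   gene-wise estimate and a loess trend fit (a mild shrink toward the
#'   mean-dispersion curve).
#' @return A tibble `gene_id`, `base_mean`, `dispersion`, `clamped`.
#' @export
estimate_dispersions <- function(counts, normalization, floor = 1e-8,
                                 trend = FALSE) {
  stopifnot(inherits(normalization, "shutoff_normalization"))
  design <- normalization$design
  if (is.null(design)) {
    stop("normalization must carry a design to pool dispersions by condition",
         call. = FALSE)
  }
  norm <- normalization$normalized
  conds <- unique(design$condition)
  reps <- table(design$condition)
  if (all(reps < 2)) {
    stop("dispersion estimation requires >= 2 replicates in >= 1 condition",
         call. = FALSE)
  }

  num <- numeric(nrow(norm))
  den <- numeric(nrow(norm))
  for (cc in conds) {
    idx <- which(design$condition == cc)
    n_c <- length(idx)
    if (n_c < 2) next
    x <- norm[, idx, drop = FALSE]
    m <- rowMeans(x)
    v <- rowSums((x - m)^2) / (n_c - 1)
    ok <- m > 0
    a <- ifelse(ok, (v - m) / m^2, NA_real_)
    w <- n_c - 1
    num <- num + ifelse(ok, w * a, 0)
    den <- den + ifelse(ok, w, 0)
  }
  alpha <- ifelse(den > 0, num / den, floor)
  clamped <- is.na(alpha) | alpha < floor
  alpha[clamped] <- floor
  base_mean <- rowMeans(norm)

  if (trend) {
    use <- base_mean > 0 & alpha > floor
    if (sum(use) >= 50) {
      fit <- stats::loess(log(alpha[use]) ~ log(base_mean[use]), span = 0.75)
      trend_alpha <- exp(stats::predict(
        fit, pmin(pmax(log(base_mean), min(log(base_mean[use]))),
                  max(log(base_mean[use])))))
      alpha <- pmax(sqrt(alpha * trend_alpha), floor)
    }
  }

  tibble::tibble(gene_id = rownames(norm), base_mean = unname(base_mean),
                 dispersion = unname(alpha), clamped = unname(clamped))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment. `NA` p-values are excluded from
#' the number of tests and passed through as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of BH-adjusted p-values, same length and order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Negative-binomial Wald contrast between two conditions
#'
#' Fits, per gene, an NB generalized linear model with log link, the sample
#' size factor as offset and condition as the only covariate, using the
#' gene's pooled dispersion estimate, and tests the condition coefficient
#' with a two-sided Wald test. With a two-level factor the iteratively
#' reweighted least-squares update reduces to weighted group means, which is
#' vectorized across all genes.
#'
#' Genes with zero counts in every sample of the comparison get `status =
#' "NA"` and no statistics (they are not analysis-ready for this contrast).
#' Genes with all zeros in exactly one group sit on the boundary of the
#' parameter space; they are refit after adding a 0.5 pseudocount to the
#' gene's counts (continuity correction) and flagged `boundary`.
#'
#' @param counts Count tibble or matrix.
#' @param normalization A [estimate_size_factors()] result with design.
#' @param dispersions Result of [estimate_dispersions()].
#' @param numerator,denominator Condition labels; the log2 fold change is
#'   numerator over denominator.
#' @param name Contrast name (default `"<numerator>_vs_<denominator>"`).
#' @param shrink Apply [shrink_lfc()] to fill `l2fc_shrunk` (default `TRUE`).
#' @return A tibble with one row per gene: `gene_id`, `contrast`,
#'   `base_mean`, `l2fc_mle`, `l2fc_shrunk`, `se`, `stat`, `p_value`, `fdr`,
#'   `status` (`ok`/`NA`), `boundary`.
#' @export
test_contrast <- function(counts, normalization, dispersions,
                          numerator, denominator, name = NULL,
                          shrink = TRUE) {
  stopifnot(inherits(normalization, "shutoff_normalization"))
  design <- normalization$design
  if (is.null(design)) stop("normalization must carry a design", call. = FALSE)
  for (cond in c(numerator, denominator)) {
    if (!cond %in% design$condition) {
      stop("unknown condition '", cond, "'", call. = FALSE)
    }
  }
  if (is.null(name)) name <- paste0(numerator, "_vs_", denominator)
  m <- counts_matrix(counts)
  m <- m[, design$sample_id, drop = FALSE]
  idx_b <- which(design$condition == numerator)
  idx_a <- which(design$condition == denominator)
  if (length(idx_a) < 2 || length(idx_b) < 2) {
    stop("both conditions need >= 2 samples", call. = FALSE)
  }
  sel <- c(idx_a, idx_b)
  y <- m[, sel, drop = FALSE]
  sf <- normalization$size_factors$size_factor[sel]
  grp_b <- c(rep(FALSE, length(idx_a)), rep(TRUE, length(idx_b)))
  alpha <- dispersions$dispersion[match(rownames(m), dispersions$gene_id)]

  total <- rowSums(y)
  status <- ifelse(total == 0, "NA", "ok")
  zero_a <- rowSums(y[, !grp_b, drop = FALSE]) == 0
  zero_b <- rowSums(y[, grp_b, drop = FALSE]) == 0
  boundary <- status == "ok" & (zero_a | zero_b)
  y_fit <- y
  y_fit[boundary, ] <- y_fit[boundary, , drop = FALSE] + 0.5

  fit <- nb_two_group_irls(y_fit, sf, grp_b, alpha)
  ln2 <- log(2)
  l2fc <- fit$beta1 / ln2
  se <- fit$se_beta1 / ln2
  stat <- fit$beta1 / fit$se_beta1
  p <- 2 * stats::pnorm(-abs(stat))

  nas <- status == "NA"
  l2fc[nas] <- NA_real_
  se[nas] <- NA_real_
  stat[nas] <- NA_real_
  p[nas] <- NA_real_

  norm_cmp <- sweep(y, 2, sf, "/")
  base_mean <- rowMeans(norm_cmp)
  base_mean[nas] <- NA_real_

  out <- tibble::tibble(
    gene_id = rownames(m),
    contrast = name,
    base_mean = unname(base_mean),
    l2fc_mle = unname(l2fc),
    l2fc_shrunk = NA_real_,
    se = unname(se),
    stat = unname(stat),
    p_value = unname(p),
    fdr = bh_adjust(unname(p)),
    status = unname(status),
    boundary = unname(boundary)
  )
  if (shrink) out <- shrink_lfc(out)
  out
}

# Vectorized IRLS for the two-group NB GLM with log link and offset log(sf).
# With a binary design the weighted-least-squares update is the weighted mean
# of the working response within each group.
nb_two_group_irls <- function(y, sf, grp_b, alpha, max_iter = 50,
                              tol = 1e-10) {
  a_idx <- which(!grp_b)
  b_idx <- which(grp_b)
  norm <- sweep(y, 2, sf, "/")
  eta_a <- log(rowMeans(norm[, a_idx, drop = FALSE]) + 0.1)
  eta_b <- log(rowMeans(norm[, b_idx, drop = FALSE]) + 0.1)
  alpha <- pmax(alpha, 0)
  n <- ncol(y)
  grp_eta <- function(eta_a, eta_b) {
    eta <- matrix(eta_a, nrow = length(eta_a), ncol = n)
    eta[, b_idx] <- eta_b
    eta
  }
  sw_a <- sw_b <- NULL
  for (it in seq_len(max_iter)) {
    eta <- grp_eta(eta_a, eta_b)
    mu <- sweep(exp(eta), 2, sf, "*")
    w <- mu / (1 + alpha * mu)
    z <- eta + (y - mu) / mu
    sw_a <- rowSums(w[, a_idx, drop = FALSE])
    sw_b <- rowSums(w[, b_idx, drop = FALSE])
    new_a <- rowSums((w * z)[, a_idx, drop = FALSE]) / sw_a
    new_b <- rowSums((w * z)[, b_idx, drop = FALSE]) / sw_b
    delta <- max(abs(new_a - eta_a), abs(new_b - eta_b), na.rm = TRUE)
    eta_a <- new_a
    eta_b <- new_b
    if (is.finite(delta) && delta < tol) break
  }
  list(beta1 = eta_b - eta_a, se_beta1 = sqrt(1 / sw_a + 1 / sw_b))
}

#' Empirical-Bayes shrinkage of log2 fold changes
#'
#' Applies a zero-centered normal prior to the Wald log2 fold changes: with a
#' normal likelihood approximation (MLE, standard error) and prior variance
#' \eqn{\tau^2}, the posterior mode is the MLE scaled by
#' \eqn{\tau^2 / (\tau^2 + se^2)}. Genes with precise estimates are nearly
#' unshrunk; noisy low-count genes are pulled toward zero. The prior scale is
#' estimated from the data by moments (\eqn{\hat\tau^2 =
#' \mathrm{mean}(l2fc^2) - \mathrm{mean}(se^2)}, floored), unless supplied.
#' Shrinkage never changes the sign of an estimate.
#'
#' @param result A contrast result tibble from [test_contrast()].
#' @param prior_scale Optional prior standard deviation \eqn{\tau} (log2
#'   units); estimated from the contrast when `NULL`.
#' @return `result` with `l2fc_shrunk` filled in.
#' @export
shrink_lfc <- function(result, prior_scale = NULL) {
  ok <- result$status == "ok" & !is.na(result$l2fc_mle)
  if (is.null(prior_scale)) {
    tau2 <- max(mean(result$l2fc_mle[ok]^2) - mean(result$se[ok]^2), 1e-6)
  } else {
    stopifnot(prior_scale > 0)
    tau2 <- prior_scale^2
  }
  shrunk <- rep(NA_real_, nrow(result))
  shrunk[ok] <- result$l2fc_mle[ok] * tau2 / (tau2 + result$se[ok]^2)
  result$l2fc_shrunk <- shrunk
  attr(result, "prior_scale") <- sqrt(tau2)
  result
}

#' Run a set of pair-wise contrasts and merge the results
#'
#' Normalizes, estimates dispersions, fits every contrast in `contrasts` and
#' merges the per-contrast tables into one wide per-gene table over the union
#' of analysis-ready genes (genes with statistics in at least one contrast) —
#' the package's analog of a merged differential-expression results table.
#'
#' @param counts Count tibble or matrix.
#' @param design Design sheet (see [study_design()]).
#' @param contrasts Contrast specification tibble (see
#'   [default_contrasts()]); conditions must exist in the design.
#' @param shrink Apply LFC shrinkage per contrast (default `TRUE`).
#' @param trend Passed to [estimate_dispersions()].
#' @return An object of class `shutoff_de`: list with `contrasts` (named
#'   list of per-contrast tibbles), `merged` (wide tibble with
#'   `<name>_l2fc`, `<name>_l2fc_mle`, `<name>_p`, `<name>_fdr` columns),
#'   `normalization`, `dispersions` and `contrast_spec`.
#' @export
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 60, n_replicates = 3))
#' de <- run_contrasts(sim$counts, sim$design)
#' glance(de)
run_contrasts <- function(counts, design, contrasts = default_contrasts(),
                          shrink = TRUE, trend = FALSE) {
  validate_design(design)
  normalization <- estimate_size_factors(counts, design)
  dispersions <- estimate_dispersions(counts, normalization, trend = trend)
  fits <- purrr::pmap(
    list(contrasts$name, contrasts$numerator, contrasts$denominator),
    function(nm, num, den) {
      test_contrast(counts, normalization, dispersions, num, den,
                    name = nm, shrink = shrink)
    }
  )
  names(fits) <- contrasts$name
  structure(list(contrasts = fits,
                 merged = merge_contrasts(fits),
                 normalization = normalization,
                 dispersions = dispersions,
                 contrast_spec = contrasts),
            class = "shutoff_de")
}

#' Merge per-contrast results into one wide per-gene table
#'
#' @param contrast_list Named list of [test_contrast()] tibbles.
#' @return A wide tibble keyed by `gene_id`, restricted to the union of
#'   genes analysis-ready (`status == "ok"`) in at least one contrast, with
#'   `<contrast>_l2fc` (shrunken), `<contrast>_l2fc_mle`, `<contrast>_p` and
#'   `<contrast>_fdr` columns.
#' @export
merge_contrasts <- function(contrast_list) {
  stopifnot(length(contrast_list) > 0, !is.null(names(contrast_list)))
  keep <- unique(unlist(lapply(contrast_list,
                               function(x) x$gene_id[x$status == "ok"])))
  all_genes <- contrast_list[[1]]$gene_id
  keep <- all_genes[all_genes %in% keep]
  out <- tibble::tibble(gene_id = keep)
  for (nm in names(contrast_list)) {
    x <- contrast_list[[nm]]
    i <- match(keep, x$gene_id)
    out[[paste0(nm, "_l2fc")]] <- x$l2fc_shrunk[i]
    out[[paste0(nm, "_l2fc_mle")]] <- x$l2fc_mle[i]
    out[[paste0(nm, "_p")]] <- x$p_value[i]
    out[[paste0(nm, "_fdr")]] <- x$fdr[i]
  }
  out
}

#' @export
print.shutoff_de <- function(x, ...) {
  cat("Differential-expression result:", length(x$contrasts), "contrasts,",
      nrow(x$merged), "analysis-ready genes\n")
  invisible(x)
}

#' @method tidy shutoff_de
#' @export
tidy.shutoff_de <- function(x, ...) {
  dplyr::bind_rows(x$contrasts)
}

#' @method glance shutoff_de
#' @export
glance.shutoff_de <- function(x, ...) {
  purrr::map_dfr(x$contrasts, function(res) {
    ok <- res$status == "ok"
    sig <- ok & !is.na(res$fdr) & res$fdr < 0.05
    tibble::tibble(
      contrast = res$contrast[1],
      n_ok = sum(ok),
      n_na = sum(!ok),
      n_sig = sum(sig),
      n_up = sum(sig & res$l2fc_shrunk > 0, na.rm = TRUE),
      n_down = sum(sig & res$l2fc_shrunk < 0, na.rm = TRUE)
    )
  })
}
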