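#' Condition-wise log2 fold-change matrix vs untreated
#'
#' For every treated condition, `log2((mean_cond + c) / (mean_untreated +
#' c))` from normalized condition means with pseudocount `c` (default 1 so
#' zero means stay finite). The untreated column (identically zero) is
#' excluded from the output.
#'
#' @param normalization A [estimate_size_factors()] result with condition
#'   means.
#' @param pseudocount Pseudocount `c` (default 1).
#' @return A tibble `gene_id` plus one L2FC column per treated condition.
#' @export
condition_l2fc_matrix <- function(normalization, pseudocount = 1) {
  stopifnot(inherits(normalization, "shutoff_normalization"))
  cm <- normalization$condition_means
  if (is.null(cm)) stop("normalization lacks condition means", call. = FALSE)
  if (!"untreated" %in% colnames(cm)) {
    stop("no untreated condition in the design", call. = FALSE)
  }
  ref <- cm[, "untreated"]
  conds <- setdiff(colnames(cm), "untreated")
  out <- tibble::tibble(gene_id = rownames(cm))
  for (cc in conds) {
    out[[cc]] <- unname(log2((cm[, cc] + pseudocount) /
                               (ref + pseudocount)))
  }
  out
}

#' Filter informative genes by L2FC standard deviation
#'
#' Keeps rows whose across-condition standard deviation of L2FC values is
#' strictly greater than `sd_threshold` — the heatmap's informative-gene
#' rule.
#'
#' @param l2fc_matrix Tibble from [condition_l2fc_matrix()].
#' @param sd_threshold Threshold (default 0.5).
#' @return The filtered tibble.
#' @export
informative_gene_filter <- function(l2fc_matrix, sd_threshold = 0.5) {
  m <- as.matrix(l2fc_matrix[setdiff(names(l2fc_matrix), "gene_id")])
  sds <- apply(m, 1, stats::sd)
  l2fc_matrix[sds > sd_threshold, , drop = FALSE]
}

#' Hierarchical clustering of the L2FC heatmap
#'
#' Agglomerative clustering of genes (rows) and conditions (columns) by
#' Euclidean distance with complete linkage, as used for the expression-
#' change heatmap. Merge order for tied distances follows [stats::hclust()]
#' (lower-index clusters merge first), which makes leaf orders
#' deterministic.
#'
#' @param l2fc_matrix Tibble from [condition_l2fc_matrix()] (>= 2 rows,
#'   finite values).
#' @return A list with `row_hclust`, `col_hclust` ([stats::hclust] objects)
#'   and `row_order`, `col_order` (leaf orders as labels).
#' @export
hierarchical_cluster <- function(l2fc_matrix) {
  m <- as.matrix(l2fc_matrix[setdiff(names(l2fc_matrix), "gene_id")])
  rownames(m) <- l2fc_matrix$gene_id
  if (nrow(m) < 2) stop("need >= 2 rows to cluster", call. = FALSE)
  if (any(!is.finite(m))) stop("non-finite values in L2FC matrix",
                               call. = FALSE)
  row_h <- stats::hclust(stats::dist(m, method = "euclidean"),
                         method = "complete")
  col_h <- if (ncol(m) >= 2) {
    stats::hclust(stats::dist(t(m), method = "euclidean"),
                  method = "complete")
  } else {
    NULL
  }
  list(row_hclust = row_h, col_hclust = col_h,
       row_order = rownames(m)[row_h$order],
       col_order = if (is.null(col_h)) colnames(m)
                   else colnames(m)[col_h$order])
}

#' PCA of transformed expression values
#'
#' Principal component analysis of samples: normalized counts are
#' variance-stabilized as `log2(x + 1)` (a documented approximation to a
#' regularized-log transform), the `top_n` most variable genes across all
#' samples are kept, and sample coordinates are obtained by SVD of the
#' centered matrix.
#'
#' @param normalization A [estimate_size_factors()] result (>= 3 samples).
#' @param top_n Number of most-varying genes (default 500); capped at the
#'   gene count with a warning.
#' @return An object of class `shutoff_pca`: list with `coords` (tibble
#'   `sample_id`, `PC1` ... joined with the design), `var_fraction` (per-PC
#'   variance fractions) and `genes_used`.
#' @export
pca_embed <- function(normalization, top_n = 500) {
  stopifnot(inherits(normalization, "shutoff_normalization"))
  x <- log2(normalization$normalized + 1)
  if (ncol(x) < 3) stop("PCA needs >= 3 samples", call. = FALSE)
  vars <- apply(x, 1, stats::var)
  if (top_n > nrow(x)) {
    warning("top_n exceeds gene count; using all ", nrow(x), " genes")
    top_n <- nrow(x)
  }
  keep <- order(vars, decreasing = TRUE)[seq_len(top_n)]
  pc <- stats::prcomp(t(x[keep, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  var_fraction <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- tibble::as_tibble(pc$x[, seq_len(min(10, ncol(pc$x))),
                                   drop = FALSE])
  coords <- dplyr::bind_cols(
    tibble::tibble(sample_id = colnames(x)), coords)
  if (!is.null(normalization$design)) {
    coords <- dplyr::left_join(coords, normalization$design,
                               by = "sample_id")
  }
  structure(list(coords = coords, var_fraction = var_fraction,
                 genes_used = rownames(x)[keep]),
            class = "shutoff_pca")
}

#' @export
print.shutoff_pca <- function(x, ...) {
  cat("PCA over", nrow(x$coords), "samples;",
      length(x$genes_used), "genes\n")
  cat("PC1 variance:", sprintf("%.1f%%", 100 * x$var_fraction[1]), "\n")
  invisible(x)
}

#' @method tidy shutoff_pca
#' @export
tidy.shutoff_pca <- function(x, ...) {
  x$coords
}

#' @method glance shutoff_pca
#' @export
glance.shutoff_pca <- function(x, ...) {
  tibble::tibble(pc = paste0("PC", seq_along(x$var_fraction)),
                 var_fraction = x$var_fraction)
}

#' Exact t-SNE embedding of candidate genes
#'
#' Embeds candidate genes in two dimensions from their L2FC profiles over
#' all comparisons with exact (theta = 0, non-Barnes-Hut) t-SNE, without
#' de-duplicating identical rows and with a fixed seed, so coordinates are
#' bit-reproducible. Coordinates carry gene ids so any effect column can be
#' overlaid as color.
#'
#' @param l2fc_matrix Tibble (`gene_id` + numeric columns), e.g. a candidate
#'   subset of [condition_l2fc_matrix()] or effect vectors.
#' @param seed Random seed (default 102).
#' @param perplexity t-SNE perplexity (default 30); needs at least
#'   `3 * perplexity + 1` genes.
#' @param exact Use exact mode (`theta = 0`, default) rather than
#'   Barnes-Hut.
#' @param ... Passed to [Rtsne::Rtsne()].
#' @return A tibble `gene_id`, `tsne1`, `tsne2` (class `shutoff_tsne`).
#' @export
tsne_embed <- function(l2fc_matrix, seed = 102, perplexity = 30,
                       exact = TRUE, ...) {
  m <- as.matrix(l2fc_matrix[setdiff(names(l2fc_matrix), "gene_id")])
  if (nrow(m) < 3 * perplexity + 1) {
    stop("too few genes (", nrow(m), ") for perplexity ", perplexity,
         "; lower the perplexity", call. = FALSE)
  }
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  fit <- Rtsne::Rtsne(m, dims = 2, perplexity = perplexity,
                      theta = if (exact) 0 else 0.5,
                      check_duplicates = FALSE, pca = FALSE, ...)
  out <- tibble::tibble(gene_id = l2fc_matrix$gene_id,
                        tsne1 = fit$Y[, 1], tsne2 = fit$Y[, 2])
  class(out) <- c("shutoff_tsne", class(out))
  out
}
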