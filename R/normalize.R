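# Convert a count tibble (gene_id + sample columns) to an integer matrix
# with gene rownames. Accepts a plain matrix unchanged.
counts_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  stopifnot(is.data.frame(counts), "gene_id" %in% names(counts))
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

#' Median-of-ratios size factors and normalized counts
#'
#' Estimates one multiplicative size factor per sample by the
#' median-of-ratios method: a pseudo-reference is formed as the per-gene
#' geometric mean over samples, using only genes with nonzero counts in every
#' sample, and each sample's factor is the median of its count-to-reference
#' ratios. Factors are then centered to geometric mean 1, so normalized
#' counts keep the overall scale of the raw data. Per-condition means of
#' normalized counts are precomputed for downstream categorization.
#'
#' @param counts Count tibble (`gene_id` plus one column per sample) or
#'   matrix.
#' @param design A design sheet matching the count columns (see
#'   [study_design()]); optional, but required for condition means.
#' @return An object of class `shutoff_normalization`: list with
#'   `size_factors` (tibble `sample_id`, `size_factor`), `normalized`
#'   (gene-by-sample matrix of counts divided by factors), `condition_means`
#'   (gene-by-condition matrix, `NULL` without a design) and `design`.
#' @export
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 50, n_replicates = 2))
#' norm <- estimate_size_factors(sim$counts, sim$design)
#' tidy(norm)
estimate_size_factors <- function(counts, design = NULL) {
  m <- counts_matrix(counts)
  if (!is.null(design)) {
    validate_design(design)
    missing <- setdiff(colnames(m), design$sample_id)
    if (length(missing) > 0) {
      stop("sample(s) in counts missing from design: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    design <- design[match(colnames(m), design$sample_id), , drop = FALSE]
  }
  ref_ok <- rowSums(m > 0) == ncol(m)
  if (!any(ref_ok)) {
    stop("normalization error: no gene has nonzero counts in every sample",
         call. = FALSE)
  }
  logm <- log(m[ref_ok, , drop = FALSE])
  log_ref <- rowMeans(logm)
  log_sf <- apply(logm - log_ref, 2, stats::median)
  log_sf <- log_sf - mean(log_sf) # center to geometric mean 1
  sf <- unname(exp(log_sf))
  normalized <- sweep(m, 2, sf, "/")

  condition_means <- NULL
  if (!is.null(design)) {
    conds <- unique(design$condition)
    condition_means <- vapply(conds, function(cc) {
      rowMeans(normalized[, design$condition == cc, drop = FALSE])
    }, numeric(nrow(m)))
    rownames(condition_means) <- rownames(m)
  }
  structure(list(size_factors = tibble::tibble(sample_id = colnames(m),
                                               size_factor = sf),
                 normalized = normalized,
                 condition_means = condition_means,
                 design = design),
            class = "shutoff_normalization")
}

#' @export
print.shutoff_normalization <- function(x, ...) {
  cat("Normalization over", ncol(x$normalized), "samples,",
      nrow(x$normalized), "genes\n")
  cat("size factor range:",
      paste(signif(range(x$size_factors$size_factor), 4), collapse = " - "),
      "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy shutoff_normalization
#' @export
tidy.shutoff_normalization <- function(x, ...) {
  x$size_factors
}
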