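#' Gene-wise concordance of two interference effects
#'
#' Signed similarity of two log2 fold changes,
#' \eqn{s = a b / \sqrt{a^2 + b^2}}: positive when the effects agree in
#' direction, negative when they oppose, zero when either is zero, with
#' magnitude bounded by the smaller of the two inputs. The indeterminate
#' origin (0, 0) is defined as 0 by continuous extension. Vectorized with
#' recycling.
#'
#' @param a,b Finite numeric vectors of L2FC values.
#' @return Numeric vector of similarity values.
#' @export
#' @examples
#' similarity(1, 1)    # 1/sqrt(2)
#' similarity(3, 4)    # 2.4
#' similarity(-3, 4)   # -2.4
similarity <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || any(!is.finite(a)) ||
      any(!is.finite(b))) {
    stop("similarity requires finite numeric inputs", call. = FALSE)
  }
  denom <- sqrt(a^2 + b^2)
  ifelse(denom == 0, 0, a * b / denom)
}

# Effect-vector definitions over the long-protocol contrasts. "Control" is
# the Bic-only condition at the protocol endpoint (2 h Bic for the LP).
effect_vector_map <- function() {
  c(passive = "lp_ttx_vs_bic_2h",         # TTX vs control
    spillover = "lp_tboa_vs_bic_2h",      # TBOA vs control
    total = "lp_ttx_nmda_vs_bic_2h",      # TTX/NMDA vs control
    active = "lp_ttx_nmda_vs_lp_ttx",     # TTX/NMDA vs TTX
    active_tboa = "lp_tboa_vs_lp_ttx")    # TBOA vs TTX
}

#' Build per-gene interference effect vectors
#'
#' Extracts, for a candidate gene set, the five long-protocol interference
#' effects used by the correlation and concordance analyses: `passive` (TTX
#' vs control), `spillover` (TBOA vs control), `total` (TTX/NMDA vs
#' control), `active` (TTX/NMDA vs TTX) and `active_tboa` (TBOA vs TTX),
#' where control is the 2 h Bic-only condition. Genes with any missing value
#' are dropped with a message.
#'
#' @param merged Wide merged table from [run_contrasts()].
#' @param candidates Character vector of candidate gene ids (see
#'   [select_candidates()]).
#' @param use `"shrunk"` (default) or `"mle"` L2FC columns.
#' @return A tibble `gene_id`, `passive`, `spillover`, `total`, `active`,
#'   `active_tboa` with all columns finite.
#' @export
build_effect_vectors <- function(merged, candidates,
                                 use = c("shrunk", "mle")) {
  use <- match.arg(use)
  if (length(candidates) == 0) {
    stop("empty candidate set", call. = FALSE)
  }
  suffix <- if (use == "shrunk") "_l2fc" else "_l2fc_mle"
  map <- effect_vector_map()
  cols <- paste0(map, suffix)
  missing <- setdiff(cols, names(merged))
  if (length(missing) > 0) {
    stop("merged table lacks contrast column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  i <- match(candidates, merged$gene_id)
  if (anyNA(i)) {
    stop("candidate gene(s) absent from merged table", call. = FALSE)
  }
  out <- tibble::tibble(gene_id = candidates)
  for (k in seq_along(map)) {
    out[[names(map)[k]]] <- merged[[cols[k]]][i]
  }
  complete <- stats::complete.cases(out)
  if (any(!complete)) {
    message("dropping ", sum(!complete),
            " candidate(s) with missing effect values")
  }
  out[complete, , drop = FALSE]
}

#' Per-gene similarity between two effect columns
#'
#' Applies [similarity()] gene-wise to two columns of an effect-vector
#' table; the default pairing (total excitotoxicity vs glutamate spillover)
#' measures the concordance between the TTX/NMDA and TBOA interventions.
#'
#' @param effect_vectors [build_effect_vectors()] output.
#' @param a,b Effect column names (defaults `"total"`, `"spillover"`).
#' @return A tibble `gene_id`, `similarity`.
#' @export
gene_similarity <- function(effect_vectors, a = "total", b = "spillover") {
  stopifnot(all(c(a, b) %in% names(effect_vectors)))
  tibble::tibble(gene_id = effect_vectors$gene_id,
                 similarity = similarity(effect_vectors[[a]],
                                         effect_vectors[[b]]))
}

#' Pair-wise Pearson correlation of interference effects
#'
#' Pearson correlation between every pair of effect columns across the
#' candidate genes.
#'
#' @param effect_vectors [build_effect_vectors()] output (>= 3 genes).
#' @return A symmetric correlation matrix with unit diagonal; zero-variance
#'   columns give `NA` entries with a warning.
#' @export
pairwise_pearson <- function(effect_vectors) {
  m <- as.matrix(effect_vectors[setdiff(names(effect_vectors), "gene_id")])
  if (nrow(m) < 3) stop("need >= 3 genes for correlations", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance effect column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
  }
  suppressWarnings(stats::cor(m, method = "pearson"))
}
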