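#' Read gene sets from a GMT file
#'
#' Tab-separated gene-set format: one set per line — name, description, then
#' member gene ids.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) unique(x[-c(1, 2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set overrepresentation
#'
#' One-sided upper-tail hypergeometric test of each gene set against a query
#' set, over an expressed-gene background, with BH adjustment across tested
#' sets. Query and sets are intersected with the background first; sets with
#' no background overlap are skipped. With background size `N`, set size
#' `K`, query size `n` and overlap `x`, the p-value is `P(X >= x)` for
#' `X ~ Hypergeometric(N, K, n)`.
#'
#' @param query Character vector of gene ids (intersected with background).
#' @param gene_sets Named list of gene-id vectors (e.g. [read_gmt()]).
#' @param background Character vector of expressed-gene ids (non-empty).
#' @return A tibble `set`, `set_size` (K), `query_size` (n), `overlap` (x),
#'   `p_value`, `fdr`, `overlap_genes` (comma-separated ids), sorted by
#'   p-value.
#' @export
#' @examples
#' hypergeom_enrich(c("a", "b", "c"),
#'                  list(s1 = c("a", "b", "z")),
#'                  background = letters[1:10])
hypergeom_enrich <- function(query, gene_sets, background) {
  background <- unique(background)
  if (length(background) == 0) stop("empty background", call. = FALSE)
  query <- intersect(unique(query), background)
  n <- length(query)
  big_n <- length(background)
  rows <- purrr::imap(gene_sets, function(members, nm) {
    members <- intersect(unique(members), background)
    k <- length(members)
    if (k == 0) return(NULL)
    hits <- intersect(query, members)
    x <- length(hits)
    p <- stats::phyper(x - 1, k, big_n - k, n, lower.tail = FALSE)
    tibble::tibble(set = nm, set_size = k, query_size = n, overlap = x,
                   p_value = p,
                   overlap_genes = paste(sort(hits), collapse = ","))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(set = character(), set_size = integer(),
                          query_size = integer(), overlap = integer(),
                          p_value = numeric(), fdr = numeric(),
                          overlap_genes = character()))
  }
  out$fdr <- bh_adjust(out$p_value)
  dplyr::arrange(
    dplyr::select(out, "set", "set_size", "query_size", "overlap",
                  "p_value", "fdr", "overlap_genes"),
    .data$p_value, .data$set)
}

#' Compare enrichment across several gene clusters
#'
#' Runs [hypergeom_enrich()] for each query cluster against a shared
#' background and stacks the results, keeping sets passing the p-value and
#' FDR cutoffs (defaults 0.01 and 0.05).
#'
#' @param queries Named list of gene-id vectors (the clusters).
#' @param gene_sets Named list of gene sets.
#' @param background Expressed-gene background.
#' @param p_cutoff,fdr_cutoff Filtering thresholds.
#' @return A tibble as [hypergeom_enrich()] plus a `cluster` column.
#' @export
enrich_clusters <- function(queries, gene_sets, background,
                            p_cutoff = 0.01, fdr_cutoff = 0.05) {
  stopifnot(is.list(queries), !is.null(names(queries)))
  purrr::imap_dfr(queries, function(q, nm) {
    res <- hypergeom_enrich(q, gene_sets, background)
    res <- res[res$p_value < p_cutoff & res$fdr < fdr_cutoff, , drop = FALSE]
    if (nrow(res) == 0) return(NULL)
    dplyr::bind_cols(tibble::tibble(cluster = nm), res)
  })
}
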