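#' Classify shut-off susceptibility of activity-responsive genes
#'
#' For each gene allocated to a protocol, calls the passive component from
#' the TTX vs Bic-only contrast, the active component from the TTX/NMDA vs
#' TTX contrast, and (LP genes only) the TBOA component from the TBOA vs
#' Bic-only contrast: `down` when the shrunken L2FC is negative with FDR
#' below `fdr_cutoff` (a significant shut-off), `up` when positive and
#' significant (a boost), `ns` otherwise. A gene is `evaluable` only when
#' statistics exist for every pair-wise comparison of its protocol — the
#' conservative rule that drops genes undetectable in one or more
#' conditions. TBOA is `not_tested` for SP genes (TBOA is applied in the LP
#' only).
#'
#' @param classification [classify_activity()] output (only genes with
#'   `protocol` SP or LP are classified; others are dropped).
#' @param contrasts Named list of [test_contrast()] tibbles containing the
#'   protocol contrasts (see [default_contrasts()]).
#' @param fdr_cutoff Significance threshold (default 0.05).
#' @return A tibble `gene_id`, `activity_class`, `protocol`, `passive`,
#'   `active`, `tboa`, `evaluable`. Calls are `NA` for non-evaluable genes.
#' @export
classify_shutoff <- function(classification, contrasts, fdr_cutoff = 0.05) {
  alloc <- classification[classification$protocol %in% c("SP", "LP"), ,
                          drop = FALSE]
  if (nrow(alloc) == 0) {
    return(tibble::tibble(gene_id = character(), activity_class = character(),
                          protocol = character(), passive = character(),
                          active = character(), tboa = character(),
                          evaluable = logical()))
  }
  call_one <- function(res, genes) {
    i <- match(genes, res$gene_id)
    lfc <- res$l2fc_shrunk[i]
    fdr <- res$fdr[i]
    ok <- res$status[i] == "ok" & !is.na(lfc) & !is.na(fdr)
    dplyr::case_when(
      ok & fdr < fdr_cutoff & lfc < 0 ~ "down",
      ok & fdr < fdr_cutoff & lfc > 0 ~ "up",
      ok ~ "ns",
      TRUE ~ NA_character_
    )
  }
  status_ok <- function(res, genes) {
    i <- match(genes, res$gene_id)
    !is.na(i) & res$status[i] == "ok"
  }
  out <- purrr::map_dfr(c("SP", "LP"), function(proto) {
    genes <- alloc$gene_id[alloc$protocol == proto]
    if (length(genes) == 0) return(NULL)
    spec <- protocol_contrast_names(proto)
    needed <- unlist(spec[!is.na(unlist(spec))])
    missing <- setdiff(needed, names(contrasts))
    if (length(missing) > 0) {
      stop("missing contrast(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    evaluable <- Reduce(`&`, lapply(needed,
                                    function(nm) status_ok(contrasts[[nm]],
                                                           genes)))
    passive <- call_one(contrasts[[spec$passive]], genes)
    active <- call_one(contrasts[[spec$active]], genes)
    tboa <- if (is.na(spec$tboa)) rep("not_tested", length(genes))
            else call_one(contrasts[[spec$tboa]], genes)
    passive[!evaluable] <- NA_character_
    active[!evaluable] <- NA_character_
    tboa[!evaluable] <- NA_character_
    tibble::tibble(gene_id = genes, protocol = proto, passive = passive,
                   active = active, tboa = tboa, evaluable = evaluable)
  })
  out <- dplyr::left_join(
    dplyr::select(alloc, "gene_id", "activity_class"), out, by = "gene_id")
  dplyr::select(out, "gene_id", "activity_class", "protocol", "passive",
                "active", "tboa", "evaluable")
}

#' Convert a log2 fold change to a percent change
#'
#' The percent change in induced expression implied by an intervention's
#' L2FC: `100 * (2^l2fc - 1)`. Negative values are shut-off percentages
#' (`-50` means induction halved), positive values boosts. `NA` passes
#' through.
#'
#' @param l2fc Numeric vector of log2 fold changes.
#' @return Numeric vector of percentages, always > -100.
#' @export
#' @examples
#' shutoff_percent(c(0, -1, -2.19))
shutoff_percent <- function(l2fc) {
  stopifnot(is.numeric(l2fc))
  100 * (2^l2fc - 1)
}

#' Shut-off percentage metrics per gene
#'
#' Computes, for each allocated gene, the percent change of induced
#' expression under each intervention of its protocol: `shutoff_pct` (total:
#' TTX/NMDA vs Bic-only), `passive_pct` (TTX vs Bic-only), `active_pct`
#' (TTX/NMDA vs TTX) and, for LP genes, `tboa_pct` (TBOA vs Bic-only). By
#' default percentages derive from the shrunken L2FC of the respective
#' pair-wise contrast; `from = "mle"` uses the unshrunken estimates and
#' `from = "means"` the ratio of normalized condition means (sensitivity
#' analysis).
#'
#' @param classification [classify_activity()] output.
#' @param contrasts Named list of contrast tibbles.
#' @param from `"shrunk"` (default), `"mle"` or `"means"`.
#' @param condition_means Required for `from = "means"`.
#' @return A tibble `gene_id`, `protocol`, `shutoff_pct`, `passive_pct`,
#'   `active_pct`, `tboa_pct` (NA where not tested).
#' @export
shutoff_metrics <- function(classification, contrasts,
                            from = c("shrunk", "mle", "means"),
                            condition_means = NULL) {
  from <- match.arg(from)
  alloc <- classification[classification$protocol %in% c("SP", "LP"), ,
                          drop = FALSE]
  grab <- function(res, genes) {
    i <- match(genes, res$gene_id)
    if (from == "mle") res$l2fc_mle[i] else res$l2fc_shrunk[i]
  }
  purrr::map_dfr(c("SP", "LP"), function(proto) {
    genes <- alloc$gene_id[alloc$protocol == proto]
    if (length(genes) == 0) return(NULL)
    spec <- protocol_contrast_names(proto)
    if (from == "means") {
      if (is.null(condition_means)) {
        stop("condition_means required for from = \"means\"", call. = FALSE)
      }
      endpoint <- if (proto == "SP") "bic_1h" else "bic_2h"
      ttx <- if (proto == "SP") "sp_ttx" else "lp_ttx"
      nmda <- if (proto == "SP") "sp_ttx_nmda" else "lp_ttx_nmda"
      i <- match(genes, rownames(condition_means))
      ratio <- function(a, b)

        log2((condition_means[i, a] + 0.5) / (condition_means[i, b] + 0.5))
      l_total <- ratio(nmda, endpoint)
      l_passive <- ratio(ttx, endpoint)
      l_active <- ratio(nmda, ttx)
      l_tboa <- if (proto == "LP") ratio("lp_tboa", endpoint)
                else rep(NA_real_, length(genes))
    } else {
      l_total <- grab(contrasts[[spec$total]], genes)
      l_passive <- grab(contrasts[[spec$passive]], genes)
      l_active <- grab(contrasts[[spec$active]], genes)
      l_tboa <- if (is.na(spec$tboa)) rep(NA_real_, length(genes))
                else grab(contrasts[[spec$tboa]], genes)
    }
    tibble::tibble(gene_id = genes, protocol = proto,
                   shutoff_pct = shutoff_percent(l_total),
                   passive_pct = shutoff_percent(l_passive),
                   active_pct = shutoff_percent(l_active),
                   tboa_pct = shutoff_percent(l_tboa))
  })
}

#' Rank genes by total shut-off percentage
#'
#' Sorts evaluable activity-induced genes by `shutoff_pct` ascending (most
#' negative, i.e. strongest total shut-off, first) and returns the top
#' `top_n` with their per-component calls and percentages — the package's
#' analog of the "most affected genes" ranking table. Ties are broken
#' lexicographically by gene id.
#'
#' @param calls [classify_shutoff()] output.
#' @param metrics [shutoff_metrics()] output.
#' @param top_n Rows to keep (default 20); `Inf` keeps all.
#' @param classes Induction classes to rank (default the induced classes).
#' @return A tibble `gene_id`, `induction_class`, `shutoff_pct`, `passive`,
#'   `passive_pct`, `active`, `active_pct`, `tboa`, `tboa_pct`.
#' @export
build_ranking <- function(calls, metrics, top_n = 20,
                          classes = c("early.induced", "late.induced")) {
  joined <- dplyr::inner_join(calls, metrics, by = c("gene_id", "protocol"))
  joined <- joined[joined$evaluable & joined$activity_class %in% classes &
                     !is.na(joined$shutoff_pct), , drop = FALSE]
  joined <- dplyr::arrange(joined, .data$shutoff_pct, .data$gene_id)
  out <- dplyr::transmute(
    joined,
    gene_id = .data$gene_id,
    induction_class = sub("\\.induced$", "", .data$activity_class),
    shutoff_pct = .data$shutoff_pct,
    passive = .data$passive, passive_pct = .data$passive_pct,
    active = .data$active, active_pct = .data$active_pct,
    tboa = .data$tboa, tboa_pct = .data$tboa_pct
  )
  utils::head(out, top_n)
}

#' Summarize shut-off category overlaps
#'
#' Partitions the evaluable genes into mutually exclusive categories —
#' `both` (passive and active shut-off), `passive_only`, `active_only`,
#' `boosted` (no shut-off call but a significant boost in either component)
#' and `resistant` (all non-significant) — and reports the pair-wise
#' intersections of the TBOA, passive and active shut-off gene sets (the
#' Venn counts), plus the count of genes boosted by both components.
#'
#' @param calls [classify_shutoff()] output.
#' @param classes Activity classes to summarize (default induced classes).
#' @return A list of class `shutoff_overlap` with `categories` (tibble
#'   `category`, `n`), `sets` (named list of gene-id vectors `passive`,
#'   `active`, `tboa`), `intersections` (tibble of pair-wise overlap counts)
#'   and `boosted_both` (count).
#' @export
overlap_summary <- function(calls,
                            classes = c("early.induced", "late.induced")) {
  x <- calls[calls$evaluable & calls$activity_class %in% classes, ,
             drop = FALSE]
  p_down <- x$passive == "down"
  a_down <- x$active == "down"
  t_down <- !is.na(x$tboa) & x$tboa == "down" & x$tboa != "not_tested"
  boosted <- !p_down & !a_down & (x$passive == "up" | x$active == "up")
  category <- dplyr::case_when(
    p_down & a_down ~ "both",
    p_down ~ "passive_only",
    a_down ~ "active_only",
    boosted ~ "boosted",
    TRUE ~ "resistant"
  )
  levels <- c("passive_only", "active_only", "both", "boosted", "resistant")
  n_per <- vapply(levels, function(l) sum(category == l), integer(1))
  categories <- tibble::tibble(category = levels, n = unname(n_per))
  sets <- list(passive = x$gene_id[p_down], active = x$gene_id[a_down],
               tboa = x$gene_id[t_down])
  pairs <- utils::combn(names(sets), 2, simplify = FALSE)
  intersections <- purrr::map_dfr(pairs, function(pr) {
    tibble::tibble(set_a = pr[1], set_b = pr[2],
                   n = length(intersect(sets[[pr[1]]], sets[[pr[2]]])))
  })
  structure(list(categories = categories, sets = sets,
                 intersections = intersections,
                 boosted_both = sum(x$passive == "up" & x$active == "up"),
                 n_evaluable = nrow(x)),
            class = "shutoff_overlap")
}

#' @export
print.shutoff_overlap <- function(x, ...) {
  cat("Shut-off categories over", x$n_evaluable, "evaluable genes\n")
  print(x$categories)
  cat("boosted by both components:", x$boosted_both, "\n")
  invisible(x)
}
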