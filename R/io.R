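#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a header row of sample ids with the first column named `gene_id`
#' holding gene identifiers and integer counts elsewhere.
#'
#' @param path Path to a TSV file.
#' @return A count tibble (`gene_id` + integer sample columns).
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path, call. = FALSE)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(x) == 0 || ncol(x) < 2) {
    stop("counts file is empty or has no sample columns", call. = FALSE)
  }
  if (names(x)[1] != "gene_id") {
    stop("first column of a counts file must be 'gene_id'", call. = FALSE)
  }
  prob <- readr::problems(x)
  if (nrow(prob) > 0) {
    stop("parse error in ", path, " at line ", prob$row[1] + 1, ": ",
         prob$expected[1], call. = FALSE)
  }
  if (anyDuplicated(x$gene_id)) {
    stop("duplicate gene ids in counts file", call. = FALSE)
  }
  for (col in setdiff(names(x), "gene_id")) {
    v <- x[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))) | is.na(v))[1]
      stop("non-numeric count in column '", col, "' at line ", bad + 1,
           call. = FALSE)
    }
    if (any(v < 0)) {
      stop("negative count in column '", col, "' at line ",
           which(v < 0)[1] + 1, call. = FALSE)
    }
    if (any(v != floor(v))) {
      stop("non-integer count in column '", col, "' at line ",
           which(v != floor(v))[1] + 1, call. = FALSE)
    }
    x[[col]] <- as.integer(round(v))
  }
  x
}

#' Write a count matrix to TSV
#'
#' @param counts Count tibble or matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  if (is.matrix(counts)) {
    counts <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(counts)),
                               tibble::as_tibble(counts))
  }
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read a study design sheet from TSV
#'
#' Requires columns `sample_id`, `protocol`, `treatment`, `time_h`,
#' `replicate`. The canonical condition label is reconstructed from
#' protocol, treatment and time and validated against [condition_table()].
#'
#' @param path Path to a TSV file.
#' @return A validated design tibble with a `condition` column.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path, call. = FALSE)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(x) == 0) stop("design file is empty", call. = FALSE)
  req <- c("sample_id", "protocol", "treatment", "time_h", "replicate")
  missing <- setdiff(req, names(x))
  if (length(missing) > 0) {
    stop("design file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ct <- condition_table()
  key <- paste(x$protocol, x$treatment, x$time_h)
  ct_key <- paste(ct$protocol, ct$treatment, ct$time_h)
  idx <- match(key, ct_key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("unknown protocol/treatment/time combination at line ", bad + 1,
         ": ", key[bad], call. = FALSE)
  }
  x$condition <- ct$condition[idx]
  validate_design(x)
  dplyr::select(x, "sample_id", "condition", "protocol", "treatment",
                "time_h", "replicate")
}

#' Write a study design sheet to TSV
#'
#' @param design Design tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  readr::write_tsv(
    dplyr::select(design, "sample_id", "protocol", "treatment", "time_h",
                  "replicate"), path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Thresholds, seeds and switches for [run_pipeline()].
#'
#' @param fdr Per-contrast significance threshold (default 0.05).
#' @param anova_fdr Candidate-selection ANOVA FDR threshold (default 0.01).
#' @param heatmap_sd Informative-gene SD threshold (default 0.5).
#' @param pseudocount Pseudocount for condition-mean L2FCs (default 1).
#' @param top_n Rows in the shut-off ranking (default 20).
#' @param strict Strict extremum-time significance in categorization.
#' @param shrink Apply LFC shrinkage.
#' @param percent_from Source of shut-off percentages (`"shrunk"`, `"mle"`,
#'   `"means"`).
#' @param pca_top_n Most-varying genes for PCA (default 500).
#' @param tsne_seed Seed for the t-SNE embedding (default 102).
#' @param tsne_perplexity t-SNE perplexity (default 30).
#' @param tsne_max_genes Cap on genes embedded by exact t-SNE (default 1000;
#'   exact-mode cost grows quadratically). A deterministic subsample is
#'   taken above the cap.
#' @param contrasts Contrast specification (default [default_contrasts()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fdr = 0.05, anova_fdr = 0.01, heatmap_sd = 0.5,
                            pseudocount = 1, top_n = 20, strict = TRUE,
                            shrink = TRUE,
                            percent_from = c("shrunk", "mle", "means"),
                            pca_top_n = 500, tsne_seed = 102,
                            tsne_perplexity = 30, tsne_max_genes = 1000,
                            contrasts = default_contrasts()) {
  percent_from <- match.arg(percent_from)
  stopifnot(fdr > 0, fdr <= 1, anova_fdr > 0, anova_fdr <= 1,
            heatmap_sd >= 0, pseudocount > 0, top_n >= 0)
  structure(list(fdr = fdr, anova_fdr = anova_fdr, heatmap_sd = heatmap_sd,
                 pseudocount = pseudocount, top_n = top_n, strict = strict,
                 shrink = shrink, percent_from = percent_from,
                 pca_top_n = pca_top_n, tsne_seed = tsne_seed,
                 tsne_perplexity = tsne_perplexity,
                 tsne_max_genes = tsne_max_genes, contrasts = contrasts),
            class = "pipeline_config")
}

#' Run the full shut-off decomposition pipeline
#'
#' Executes normalization, the full contrast set, the ANOVA screen,
#' activity-class categorization, candidate selection, shut-off
#' classification with percentage metrics, ranking and overlap summary,
#' effect-vector concordance and correlations (over late-induced
#' candidates), the condition L2FC matrix with informative-gene clustering,
#' PCA, and a seed-fixed exact t-SNE of candidate genes. All stages are
#' deterministic given the inputs and configuration.
#'
#' @param counts Count tibble or matrix.
#' @param design Design tibble (see [study_design()] / [read_design()]).
#' @param gene_sets Optional named list of gene sets; enrichment of the
#'   passive/active/resistant shut-off clusters is run when supplied.
#' @param config A [pipeline_config()].
#' @return An object of class `shutoff_pipeline`; see the elements
#'   `annotation` (per-gene merged table), `ranking`, `overlap`,
#'   `correlations`, `pca`, `tsne`, `enrichment`, plus all intermediates.
#' @export
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 80, n_replicates = 3))
#' res <- run_pipeline(sim$counts, sim$design)
#' res$ranking
run_pipeline <- function(counts, design, gene_sets = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_design(design)
  de <- run_contrasts(counts, design, contrasts = config$contrasts,
                      shrink = config$shrink)
  norm <- de$normalization
  anova <- anova_screen(norm)
  classification <- classify_activity(
    de$contrasts, norm$condition_means, anova = anova,
    fdr_cutoff = config$fdr, strict = config$strict)
  candidates <- select_candidates(classification, de$merged,
                                  anova_fdr_cutoff = config$anova_fdr)
  calls <- classify_shutoff(classification, de$contrasts,
                            fdr_cutoff = config$fdr)
  metrics <- shutoff_metrics(classification, de$contrasts,
                             from = config$percent_from,
                             condition_means = norm$condition_means)
  ranking <- build_ranking(calls, metrics, top_n = config$top_n)
  overlap <- overlap_summary(calls)

  late_candidates <- intersect(
    candidates,
    classification$gene_id[classification$activity_class == "late.induced"])
  effect_vectors <- NULL
  correlations <- NULL
  sim_table <- NULL
  if (length(late_candidates) >= 3) {
    effect_vectors <- build_effect_vectors(de$merged, late_candidates)
    if (nrow(effect_vectors) >= 3) {
      correlations <- pairwise_pearson(effect_vectors)
      sim_table <- gene_similarity(effect_vectors)
    }
  }

  l2fc_matrix <- condition_l2fc_matrix(norm,
                                       pseudocount = config$pseudocount)
  informative <- informative_gene_filter(l2fc_matrix,
                                         sd_threshold = config$heatmap_sd)
  clustering <- if (nrow(informative) >= 2) hierarchical_cluster(informative)
                else NULL
  pca <- pca_embed(norm, top_n = min(config$pca_top_n, nrow(l2fc_matrix)))

  tsne <- NULL
  if (length(candidates) > 0) {
    lfc_cols <- grep("_l2fc$", names(de$merged), value = TRUE)
    cand_mat <- de$merged[match(candidates, de$merged$gene_id),
                          c("gene_id", lfc_cols)]
    if (nrow(cand_mat) > config$tsne_max_genes) {
      old <- .Random.seed_exists()
      set.seed(config$tsne_seed)
      keep <- sort(sample.int(nrow(cand_mat), config$tsne_max_genes))
      restore_seed(old)
      cand_mat <- cand_mat[keep, , drop = FALSE]
    }
    perp <- config$tsne_perplexity
    if (nrow(cand_mat) < 3 * perp + 1) {
      perp <- max(2, floor((nrow(cand_mat) - 1) / 3))
    }
    if (nrow(cand_mat) >= 3 * perp + 1 && perp >= 2) {
      tsne <- tsne_embed(cand_mat, seed = config$tsne_seed,
                         perplexity = perp)
    }
  }

  enrichment <- NULL
  if (!is.null(gene_sets)) {
    background <- expressed_background(de$merged)
    cat_calls <- calls[calls$evaluable &
                         calls$activity_class %in%
                           c("early.induced", "late.induced"), ]
    queries <- list(
      passive_shutoff = cat_calls$gene_id[cat_calls$passive == "down"],
      active_shutoff = cat_calls$gene_id[cat_calls$active == "down"],
      resistant = cat_calls$gene_id[cat_calls$passive != "down" &
                                      cat_calls$active != "down"])
    enrichment <- enrich_clusters(queries, gene_sets, background,
                                  p_cutoff = 1, fdr_cutoff = 1)
  }

  annotation <- classification
  annotation <- dplyr::left_join(
    annotation,
    dplyr::select(calls, "gene_id", "passive", "active", "tboa",
                  "evaluable"),
    by = "gene_id")
  annotation <- dplyr::left_join(
    annotation,
    dplyr::select(metrics, "gene_id", "shutoff_pct", "passive_pct",
                  "active_pct", "tboa_pct"),
    by = "gene_id")
  annotation$candidate <- annotation$gene_id %in% candidates

  structure(list(config = config, design = design, de = de,
                 normalization = norm, anova = anova,
                 classification = classification, candidates = candidates,
                 shutoff_calls = calls, shutoff_metrics = metrics,
                 ranking = ranking, overlap = overlap,
                 effect_vectors = effect_vectors,
                 correlations = correlations, similarity = sim_table,
                 l2fc_matrix = l2fc_matrix, informative = informative,
                 clustering = clustering, pca = pca, tsne = tsne,
                 enrichment = enrichment, annotation = annotation,
                 merged = de$merged),
            class = "shutoff_pipeline")
}

# Background for enrichment: genes with DE statistics available in every
# Bic-vs-untreated comparison (the expressed-gene universe).
expressed_background <- function(merged) {
  fdr_cols <- paste0(c("bic_0.5h", "bic_1h", "bic_2h"),
                     "_vs_untreated_fdr")
  fdr_cols <- intersect(fdr_cols, names(merged))
  merged$gene_id[rowSums(is.na(merged[fdr_cols])) == 0]
}

#' @export
print.shutoff_pipeline <- function(x, ...) {
  cat("Shut-off decomposition pipeline\n")
  cat("  genes:", nrow(x$classification), " candidates:",
      length(x$candidates), "\n")
  cat("  evaluable induced genes:", x$overlap$n_evaluable, "\n")
  invisible(x)
}

#' @method tidy shutoff_pipeline
#' @export
tidy.shutoff_pipeline <- function(x, ...) {
  x$annotation
}

#' @method glance shutoff_pipeline
#' @export
glance.shutoff_pipeline <- function(x, ...) {
  cat_n <- function(l) {
    n <- x$overlap$categories$n[x$overlap$categories$category == l]
    if (length(n) == 0) 0L else n
  }
  tibble::tibble(
    n_genes = nrow(x$classification),
    n_candidates = length(x$candidates),
    n_evaluable = x$overlap$n_evaluable,
    n_passive_only = cat_n("passive_only"),
    n_active_only = cat_n("active_only"),
    n_both = cat_n("both"),
    n_boosted = cat_n("boosted"),
    n_resistant = cat_n("resistant"),
    pc1_var_fraction = x$pca$var_fraction[1]
  )
}

#' Write pipeline outputs to a directory
#'
#' Writes the merged annotated gene table, per-contrast tables, size
#' factors, ranking, overlap summary, effect vectors, correlations,
#' similarity, L2FC matrix with leaf orders, PCA and t-SNE coordinates, the
#' resolved configuration (YAML) and a provenance log. All tables are
#' UTF-8 TSV with `NA` for missing values and re-parseable by the package's
#' readers.
#'
#' @param pipeline A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(pipeline, out_dir) {
  stopifnot(inherits(pipeline, "shutoff_pipeline"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  wr <- function(x, name) readr::write_tsv(x, p(name))

  merged_annotated <- dplyr::left_join(pipeline$annotation,
                                       pipeline$merged, by = "gene_id")
  wr(merged_annotated, "merged_annotated.tsv")
  wr(pipeline$normalization$size_factors, "size_factors.tsv")
  dir.create(p("contrasts"), showWarnings = FALSE)
  for (nm in names(pipeline$de$contrasts)) {
    wr(pipeline$de$contrasts[[nm]], file.path("contrasts",
                                              paste0(nm, ".tsv")))
  }
  wr(pipeline$ranking, "ranking.tsv")
  wr(pipeline$l2fc_matrix, "l2fc_matrix.tsv")
  wr(pipeline$informative, "informative_genes.tsv")
  if (!is.null(pipeline$clustering)) {
    wr(tibble::tibble(gene_id = pipeline$clustering$row_order),
       "heatmap_row_order.tsv")
    wr(tibble::tibble(condition = pipeline$clustering$col_order),
       "heatmap_col_order.tsv")
  }
  wr(pipeline$pca$coords, "pca_coords.tsv")
  wr(tibble::tibble(pc = paste0("PC", seq_along(pipeline$pca$var_fraction)),
                    var_fraction = pipeline$pca$var_fraction),
     "pca_variance.tsv")
  if (!is.null(pipeline$tsne)) wr(pipeline$tsne, "tsne_coords.tsv")
  if (!is.null(pipeline$effect_vectors)) {
    wr(pipeline$effect_vectors, "effect_vectors.tsv")
    cors <- tibble::as_tibble(pipeline$correlations, rownames = "effect")
    wr(cors, "effect_correlations.tsv")
    wr(pipeline$similarity, "similarity.tsv")
  }
  if (!is.null(pipeline$enrichment)) wr(pipeline$enrichment,
                                        "enrichment.tsv")
  ov <- pipeline$overlap
  yaml::write_yaml(list(
    categories = stats::setNames(as.list(ov$categories$n),
                                 ov$categories$category),
    intersections = purrr::pmap(ov$intersections,
                                function(set_a, set_b, n) {
                                  list(sets = c(set_a, set_b), n = n)
                                }),
    boosted_both = ov$boosted_both,
    n_evaluable = ov$n_evaluable), p("overlap_summary.yaml"))
  cfg <- pipeline$config
  cfg$contrasts <- NULL
  yaml::write_yaml(cfg, p("config.yaml"))
  writeLines(c(
    paste("package:", as.character(utils::packageVersion("synaptoff"))),
    paste("R:", R.version.string),
    paste("run at: <deterministic; timestamps omitted>"),
    paste("tsne_seed:", pipeline$config$tsne_seed),
    paste("fdr:", pipeline$config$fdr),
    paste("anova_fdr:", pipeline$config$anova_fdr)), p("log.txt"))
  invisible(out_dir)
}

#' Compare pipeline output with a reference annotated table
#'
#' Joins a user-supplied reference per-gene table (for instance a published
#' merged results table) with the pipeline annotation on gene id and reports
#' agreement summaries: the fraction of shared genes with identical activity
#' class and Spearman correlations of the shut-off percentage columns.
#' Intended as an approximate cross-check; column names in the reference
#' must match the annotation's (`activity_class`, `shutoff_pct`, ...).
#'
#' @param annotation Pipeline `annotation` tibble.
#' @param reference Reference tibble with a `gene_id` column.
#' @return A tibble of agreement metrics.
#' @export
validate_against_reference <- function(annotation, reference) {
  stopifnot("gene_id" %in% names(reference))
  shared <- dplyr::inner_join(annotation, reference, by = "gene_id",
                              suffix = c("", ".ref"))
  out <- tibble::tibble(metric = "n_shared_genes",
                        value = as.numeric(nrow(shared)))
  if (all(c("activity_class", "activity_class.ref") %in% names(shared))) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      metric = "activity_class_agreement",
      value = mean(shared$activity_class == shared$activity_class.ref,
                   na.rm = TRUE)))
  }
  for (col in c("shutoff_pct", "passive_pct", "active_pct", "tboa_pct")) {
    ref_col <- paste0(col, ".ref")
    if (all(c(col, ref_col) %in% names(shared))) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        metric = paste0(col, "_spearman"),
        value = suppressWarnings(
          stats::cor(shared[[col]], shared[[ref_col]],
                     method = "spearman", use = "complete.obs"))))
    }
  }
  out
}
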