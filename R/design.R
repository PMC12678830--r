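#' Canonical experimental conditions
#'
#' The experiment contrasts nine conditions in cultured hippocampal neurons:
#' an untreated control; a bicuculline (Bic) induction time series (0.5, 1 and
#' 2 h of action-potential firing); a short protocol (SP) in which an
#' intervention is applied for 0.5 h after 0.5 h of firing (samples collected
#' at 1 h total, compared against 1 h Bic); and a long protocol (LP) in which
#' the intervention is applied for 1 h after 1 h of firing (samples at 2 h,
#' compared against 2 h Bic). Interventions are TTX (firing cessation, the
#' passive component of excitotoxicity), TTX/NMDA (toxic extrasynaptic NMDA
#' receptor signaling on top of firing cessation, the active component) and,
#' in the LP only, TBOA (glutamate spillover, a milder excitotoxicity model).
#'
#' @return A tibble with columns `condition`, `protocol` (`none`, `bic`,
#'   `SP`, `LP`), `treatment` (`untreated`, `bic`, `ttx`, `ttx_nmda`,
#'   `tboa`) and `time_h` (total time from firing onset, hours).
#' @export
#' @examples
#' condition_table()
condition_table <- function() {
  tibble::tribble(
    ~condition,    ~protocol, ~treatment,  ~time_h,
    "untreated",   "none",    "untreated", 0,
    "bic_0.5h",    "bic",     "bic",       0.5,
    "bic_1h",      "bic",     "bic",       1,
    "bic_2h",      "bic",     "bic",       2,
    "sp_ttx",      "SP",      "ttx",       1,
    "sp_ttx_nmda", "SP",      "ttx_nmda",  1,
    "lp_ttx",      "LP",      "ttx",       2,
    "lp_ttx_nmda", "LP",      "ttx_nmda",  2,
    "lp_tboa",     "LP",      "tboa",      2
  )
}

#' Build a replicated study design
#'
#' Expands [condition_table()] into a per-sample design sheet with
#' `n_replicates` biological replicates per condition.
#'
#' @param n_replicates Replicates per condition (default 5, the design used
#'   for primary-neuron preparations).
#' @param conditions Character vector of conditions to include (default all
#'   nine).
#' @return A tibble with columns `sample_id`, `condition`, `protocol`,
#'   `treatment`, `time_h`, `replicate`.
#' @export
#' @examples
#' study_design(2)
study_design <- function(n_replicates = 5,
                         conditions = condition_table()$condition) {
  stopifnot(is.numeric(n_replicates), n_replicates >= 0,
            n_replicates == round(n_replicates))
  ct <- condition_table()
  unknown <- setdiff(conditions, ct$condition)
  if (length(unknown) > 0) {
    stop("unknown condition(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ct <- ct[match(conditions, ct$condition), , drop = FALSE]
  design <- tidyr::expand_grid(ct, replicate = seq_len(n_replicates))
  design$sample_id <- paste0(design$condition, "_r", design$replicate)
  dplyr::select(design, "sample_id", "condition", "protocol", "treatment",
                "time_h", "replicate")
}

#' Default pair-wise contrast set
#'
#' Enumerates the pair-wise comparisons analyzed in the pipeline: every
#' treated condition against the untreated control (8), the within-protocol
#' intervention comparisons for the SP (TTX vs 1 h Bic, TTX/NMDA vs 1 h Bic,
#' TTX/NMDA vs TTX) and for the LP (TTX vs 2 h Bic, TTX/NMDA vs 2 h Bic,
#' TTX/NMDA vs TTX, TBOA vs 2 h Bic), plus TBOA vs TTX in the LP, which the
#' effect-concordance analysis ("active effect of TBOA") requires.
#'
#' @return A tibble with columns `name`, `numerator`, `denominator`,
#'   `protocol` (the protocol tag used when deciding gene evaluability) and
#'   `effect` (a label for the within-protocol interference effect the
#'   contrast measures, `NA` for the vs-untreated set).
#' @export
#' @examples
#' default_contrasts()
default_contrasts <- function() {
  vs_untreated <- tibble::tibble(
    numerator = c("bic_0.5h", "bic_1h", "bic_2h", "sp_ttx", "sp_ttx_nmda",
                  "lp_ttx", "lp_ttx_nmda", "lp_tboa"),
    denominator = "untreated",
    protocol = c("bic", "bic", "bic", "SP", "SP", "LP", "LP", "LP"),
    effect = NA_character_
  )
  within_protocol <- tibble::tribble(
    ~numerator,    ~denominator,  ~protocol, ~effect,
    "sp_ttx",      "bic_1h",      "SP",      "passive",
    "sp_ttx_nmda", "bic_1h",      "SP",      "total",
    "sp_ttx_nmda", "sp_ttx",      "SP",      "active",
    "lp_ttx",      "bic_2h",      "LP",      "passive",
    "lp_ttx_nmda", "bic_2h",      "LP",      "total",
    "lp_ttx_nmda", "lp_ttx",      "LP",      "active",
    "lp_tboa",     "bic_2h",      "LP",      "spillover",
    "lp_tboa",     "lp_ttx",      "LP",      "active_tboa"
  )
  out <- dplyr::bind_rows(vs_untreated, within_protocol)
  out$name <- paste0(out$numerator, "_vs_", out$denominator)
  dplyr::select(out, "name", "numerator", "denominator", "protocol", "effect")
}

# Bic time-series conditions used by the ANOVA screen and categorization.
bic_series_conditions <- function() c("untreated", "bic_0.5h", "bic_1h", "bic_2h")

# Defining contrasts per protocol for the shut-off decomposition.
protocol_contrast_names <- function(protocol) {
  switch(protocol,
    SP = list(passive = "sp_ttx_vs_bic_1h",
              total   = "sp_ttx_nmda_vs_bic_1h",
              active  = "sp_ttx_nmda_vs_sp_ttx",
              tboa    = NA_character_),
    LP = list(passive = "lp_ttx_vs_bic_2h",
              total   = "lp_ttx_nmda_vs_bic_2h",
              active  = "lp_ttx_nmda_vs_lp_ttx",
              tboa    = "lp_tboa_vs_bic_2h"),
    stop("no interference contrasts for protocol '", protocol, "'",
         call. = FALSE)
  )
}

validate_design <- function(design) {
  req <- c("sample_id", "condition", "protocol", "treatment", "time_h",
           "replicate")
  missing <- setdiff(req, names(design))
  if (length(missing) > 0) {
    stop("design sheet lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in design sheet", call. = FALSE)
  }
  ct <- condition_table()
  bad <- setdiff(unique(design$condition), ct$condition)
  if (length(bad) > 0) {
    stop("unknown condition token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(design)
}
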