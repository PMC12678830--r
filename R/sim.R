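#' Configuration for the synthetic nine-condition experiment
#'
#' Builds the configuration object for the truth-labeled count simulator.
#' The simulator emulates the statistical structure of the
#' bicuculline/TTX/NMDA/TBOA design: per-gene baseline abundance (log-normal),
#' archetype-specific induction kinetics over the Bic time series,
#' intervention effect multipliers (passive and active shut-off, boosting,
#' milder TBOA reduction), negative-binomial overdispersion and per-sample
#' library-size factors.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Replicates per condition (default 5).
#' @param baseline_meanlog,baseline_sdlog Parameters of the log-normal
#'   distribution of the per-gene baseline expected count \eqn{\lambda_g}
#'   (defaults `log(100)` and 1: a median baseline of 100 counts with a
#'   realistic right tail).
#' @param dispersion_shape,dispersion_scale Gamma parameters for the per-gene
#'   NB dispersion \eqn{\alpha_g} (defaults shape 2, scale 0.025: mean
#'   dispersion 0.05, typical of replicated primary-culture bulk RNA-seq).
#' @param dispersion_fixed If non-`NULL`, use this single dispersion for all
#'   genes instead of gamma draws; `0` gives the Poisson limit.
#' @param lib_size_range Interval for the uniform per-sample library-size
#'   factor (default `c(0.7, 1.4)`).
#' @param archetype_fractions Named proportions over the six gene archetypes
#'   `unresponsive`, `early.induced`, `late.induced`, `transient.induced`,
#'   `early.repressed`, `late.repressed`; must sum to 1.
#' @param fold_range Interval for the per-gene peak induction/repression fold
#'   `F`, drawn log2-uniformly (default `c(4, 16)`).
#' @param effect_profiles Tibble with columns `profile`, `passive`, `active`,
#'   `tboa`, `prob` giving the intervention multiplier profiles assigned to
#'   activity-responsive genes (see [effect_profiles_default()]). Multipliers
#'   must be positive; probabilities must sum to 1. A multiplier < 1 is a
#'   shut-off, > 1 a boost.
#' @param seed Master seed; stage-specific sub-streams (truth, library
#'   factors, counts) are derived from it by fixed offsets.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 100, seed = 1)
sim_config <- function(n_genes,
                       n_replicates = 5,
                       baseline_meanlog = log(100),
                       baseline_sdlog = 1,
                       dispersion_shape = 2,
                       dispersion_scale = 0.025,
                       dispersion_fixed = NULL,
                       lib_size_range = c(0.7, 1.4),
                       archetype_fractions = c(
                         unresponsive = 0.55,
                         early.induced = 0.12,
                         late.induced = 0.12,
                         transient.induced = 0.06,
                         early.repressed = 0.075,
                         late.repressed = 0.075
                       ),
                       fold_range = c(4, 16),
                       effect_profiles = effect_profiles_default(),
                       seed = 1L) {
  stopifnot(is.numeric(n_genes), n_genes >= 1,
            is.numeric(n_replicates), n_replicates >= 0)
  if (abs(sum(archetype_fractions) - 1) > 1e-8 ||
      any(archetype_fractions < 0)) {
    stop("configuration error: archetype_fractions must be non-negative and sum to 1",
         call. = FALSE)
  }
  bad <- setdiff(names(archetype_fractions), sim_archetypes())
  if (length(bad) > 0) {
    stop("configuration error: unknown archetype(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(c(effect_profiles$passive, effect_profiles$active,
            effect_profiles$tboa) <= 0)) {
    stop("configuration error: effect multipliers must be > 0", call. = FALSE)
  }
  if (abs(sum(effect_profiles$prob) - 1) > 1e-8 ||
      any(effect_profiles$prob < 0)) {
    stop("configuration error: effect profile probabilities must sum to 1",
         call. = FALSE)
  }
  if (!is.null(dispersion_fixed) && dispersion_fixed < 0) {
    stop("configuration error: dispersion must be >= 0", call. = FALSE)
  }
  stopifnot(length(lib_size_range) == 2, all(lib_size_range > 0),
            length(fold_range) == 2, all(fold_range > 1))
  seed <- as.integer(seed)
  stopifnot(!is.na(seed), abs(seed) < 2^31 - 1000)
  structure(list(
    n_genes = as.integer(n_genes),
    n_replicates = as.integer(n_replicates),
    baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog,
    dispersion_shape = dispersion_shape,
    dispersion_scale = dispersion_scale,
    dispersion_fixed = dispersion_fixed,
    lib_size_range = lib_size_range,
    archetype_fractions = archetype_fractions,
    fold_range = fold_range,
    effect_profiles = effect_profiles,
    seed = seed
  ), class = "sim_config")
}

sim_archetypes <- function() {
  c("unresponsive", "early.induced", "late.induced", "transient.induced",
    "early.repressed", "late.repressed")
}

responsive_archetypes <- function() {
  c("early.induced", "late.induced", "early.repressed", "late.repressed")
}

#' Default intervention effect-multiplier profiles
#'
#' Multiplier profiles assigned to activity-responsive genes. `passive`
#' scales the intervention-condition mean relative to the Bic-only level of
#' the allocated protocol's endpoint (TTX vs Bic); `active` scales the
#' TTX/NMDA mean relative to the TTX mean; `tboa` scales the TBOA mean
#' relative to the Bic-only endpoint. The default mix mirrors the qualitative
#' picture of the real experiment: genes shut off only passively, only
#' actively (with a milder TBOA reduction), by both, resistant genes, and
#' passively boosted genes whose induction the toxic NMDA signal suppresses.
#'
#' @return A tibble with columns `profile`, `passive`, `active`, `tboa`,
#'   `prob`.
#' @export
effect_profiles_default <- function() {
  tibble::tribble(
    ~profile,        ~passive, ~active, ~tboa, ~prob,
    "resistant",     1,        1,       1,     0.25,
    "passive_only",  0.5,      1,       1,     0.20,
    "active_only",   1,        0.4,     0.6,   0.25,
    "both",          0.5,      0.4,     0.5,   0.15,
    "passive_boost", 1.6,      0.4,     0.8,   0.15
  )
}

#' Effect profiles with built-in passive/active anticorrelation
#'
#' A two-profile mix encoding the anticorrelated structure seen in the real
#' data: genes whose induction is boosted by firing cessation but suppressed
#' by the active NMDA-receptor signal, and genes shut off passively but
#' barely touched by the active component. Useful for checking that the
#' effect-vector correlation analysis recovers a negative Pearson r between
#' the passive and active effects.
#'
#' @return A tibble in the [effect_profiles_default()] format.
#' @export
effect_profiles_anticorrelated <- function() {
  tibble::tribble(
    ~profile,                   ~passive, ~active, ~tboa, ~prob,
    "passive_boost_active_shut", 1.8,     0.3,     0.6,   0.5,
    "passive_shut_active_none",  0.45,    1.1,     0.9,   0.5
  )
}

# Largest-remainder apportionment: archetype counts match the configured
# fractions to within one gene regardless of seed.
apportion_counts <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

# Bic time-course multipliers (0.5 h, 1 h, 2 h) relative to baseline for a
# gene with peak fold f. Curves are chosen to trip the max-at-time
# categorization rules unambiguously; repressed curves are reciprocals.
archetype_kinetics <- function(archetype, f) {
  switch(archetype,
    unresponsive      = cbind(1, 1, 1),
    early.induced     = cbind(f, f, f / 2),
    late.induced      = cbind(1, f / 2, f),
    transient.induced = cbind(f, 1, 1),
    early.repressed   = cbind(1 / f, 1 / f, 2 / f),
    late.repressed    = cbind(1, 2 / f, 1 / f),
    stop("unknown archetype ", archetype, call. = FALSE)
  )
}

#' Generate per-gene simulation truth
#'
#' Draws per-gene baselines, dispersions, archetypes, induction folds and
#' intervention effect profiles, and derives the expected count for every
#' condition. Archetype counts follow the configured fractions by
#' largest-remainder apportionment (exact to within one gene); which gene
#' gets which archetype is randomized under the truth sub-stream of the
#' master seed. Intervention-condition means are defined relative to the
#' Bic-only level at the allocated protocol's endpoint: TTX = passive
#' multiplier times the Bic endpoint mean, TTX/NMDA = active multiplier times
#' the TTX mean, TBOA = TBOA multiplier times the Bic endpoint mean.
#' Unresponsive and transient genes carry neutral multipliers (all 1).
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per gene: `gene_id`, `archetype`, `fold`,
#'   `profile`, `passive_effect`, `active_effect`, `tboa_effect`,
#'   `baseline`, `dispersion`, and one `mean_<condition>` column per
#'   condition.
#' @export
#' @examples
#' truth <- simulate_truth(sim_config(n_genes = 20, seed = 1))
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  old <- .Random.seed_exists()
  set.seed(config$seed + 11L)
  on.exit(restore_seed(old), add = TRUE)

  fractions <- config$archetype_fractions
  counts_per <- apportion_counts(fractions, n)
  archetype <- sample(rep(names(fractions), counts_per))

  baseline <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  dispersion <- if (is.null(config$dispersion_fixed)) {
    stats::rgamma(n, shape = config$dispersion_shape,
                  scale = config$dispersion_scale)
  } else {
    rep(config$dispersion_fixed, n)
  }
  lf <- log2(config$fold_range)
  fold <- 2^stats::runif(n, lf[1], lf[2])

  ep <- config$effect_profiles
  profile <- rep("neutral", n)
  responsive <- archetype %in% responsive_archetypes()
  if (any(responsive)) {
    profile[responsive] <- sample(ep$profile, sum(responsive), replace = TRUE,
                                  prob = ep$prob)
  }
  idx <- match(profile, ep$profile)
  passive_effect <- ifelse(is.na(idx), 1, ep$passive[idx])
  active_effect <- ifelse(is.na(idx), 1, ep$active[idx])
  tboa_effect <- ifelse(is.na(idx), 1, ep$tboa[idx])

  kin <- t(vapply(seq_len(n),
                  function(i) archetype_kinetics(archetype[i], fold[i])[1, ],
                  numeric(3)))
  mean_untreated <- baseline
  mean_bic_05 <- baseline * kin[, 1]
  mean_bic_1 <- baseline * kin[, 2]
  mean_bic_2 <- baseline * kin[, 3]

  tibble::tibble(
    gene_id = sprintf("g%05d", seq_len(n)),
    archetype = archetype,
    fold = fold,
    profile = profile,
    passive_effect = passive_effect,
    active_effect = active_effect,
    tboa_effect = tboa_effect,
    baseline = baseline,
    dispersion = dispersion,
    mean_untreated = mean_untreated,
    `mean_bic_0.5h` = mean_bic_05,
    mean_bic_1h = mean_bic_1,
    mean_bic_2h = mean_bic_2,
    mean_sp_ttx = passive_effect * mean_bic_1,
    mean_sp_ttx_nmda = active_effect * passive_effect * mean_bic_1,
    mean_lp_ttx = passive_effect * mean_bic_2,
    mean_lp_ttx_nmda = active_effect * passive_effect * mean_bic_2,
    mean_lp_tboa = tboa_effect * mean_bic_2
  )
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a count matrix from simulation truth
#'
#' Draws counts gene by sample from
#' \eqn{NB(\mu = s_j \mu_{g,cond(j)}, \alpha_g)} where \eqn{s_j} is the
#' per-sample library-size factor (uniform on the configured interval) and
#' the NB variance is \eqn{\mu + \alpha \mu^2} (\eqn{\alpha} is the
#' reciprocal of the `size` parameter of [stats::rnbinom()]); \eqn{\alpha =
#' 0} falls back to Poisson draws. Reproducible given the configuration's
#' master seed (library factors and counts use fixed seed offsets).
#'
#' @param truth Output of [simulate_truth()].
#' @param design A [study_design()] whose conditions are all present in
#'   `truth`.
#' @param config The [sim_config()] used to build `truth`.
#' @return A count tibble (`gene_id` plus one integer column per sample)
#'   with the per-sample library-size factors attached as attribute
#'   `lib_factors` (a tibble `sample_id`, `lib_factor`).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 20, n_replicates = 2, seed = 1)
#' counts <- simulate_counts(simulate_truth(cfg), study_design(2), cfg)
simulate_counts <- function(truth, design, config) {
  stopifnot(inherits(config, "sim_config"))
  validate_design(design)
  conds <- unique(design$condition)
  mean_cols <- if (length(conds) > 0) paste0("mean_", conds) else character(0)
  missing <- setdiff(mean_cols, names(truth))
  if (length(missing) > 0) {
    stop("design condition(s) absent from truth: ",
         paste(sub("^mean_", "", missing), collapse = ", "), call. = FALSE)
  }
  n_genes <- nrow(truth)
  n_samples <- nrow(design)
  if (n_samples == 0) {
    return(tibble::tibble(gene_id = truth$gene_id))
  }

  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)

  set.seed(config$seed + 23L)
  lib_factor <- stats::runif(n_samples, config$lib_size_range[1],
                             config$lib_size_range[2])

  set.seed(config$seed + 37L)
  counts <- matrix(0L, nrow = n_genes, ncol = n_samples)
  for (j in seq_len(n_samples)) {
    mu <- lib_factor[j] * truth[[paste0("mean_", design$condition[j])]]
    alpha <- truth$dispersion
    pois <- alpha <= 0
    col <- integer(n_genes)
    if (any(pois)) col[pois] <- stats::rpois(sum(pois), mu[pois])
    if (any(!pois)) {
      col[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois],
                                   size = 1 / alpha[!pois])
    }
    counts[, j] <- col
  }
  colnames(counts) <- design$sample_id
  out <- dplyr::bind_cols(tibble::tibble(gene_id = truth$gene_id),
                          tibble::as_tibble(counts))
  attr(out, "lib_factors") <- tibble::tibble(sample_id = design$sample_id,
                                             lib_factor = lib_factor)
  out
}

#' Simulate a complete experiment
#'
#' Convenience wrapper: builds the replicated design, the truth table and the
#' count matrix from one configuration.
#'
#' @param config A [sim_config()].
#' @return A list with elements `config`, `design`, `truth`, `counts`.
#' @export
simulate_experiment <- function(config) {
  design <- study_design(config$n_replicates)
  truth <- simulate_truth(config)
  counts <- simulate_counts(truth, design, config)
  list(config = config, design = design, truth = truth, counts = counts)
}

#' Evaluate pipeline calls against simulation truth
#'
#' Confusion-matrix summaries of the activity-class assignments and shut-off
#' calls against the simulated ground truth. A gene is truly susceptible to a
#' shut-off component when its configured multiplier is < 1 (truly boosted
#' when > 1); shut-off truth is evaluated over the activity-induced
#' archetypes (`early.induced`/`late.induced`; the TBOA component over
#' `late.induced` only, since TBOA is applied in the LP). Genes the pipeline
#' excluded or left uncalled count as misses for sensitivity.
#'
#' @param annotation Per-gene tibble with columns `gene_id`,
#'   `activity_class` and (optionally) shut-off calls `passive`, `active`,
#'   `tboa` (values `down`/`up`/`ns`/`not_tested` or `NA`), e.g. the merged
#'   table of [run_pipeline()].
#' @param truth Output of [simulate_truth()].
#' @return A tibble with columns `section` (`activity_class` or `shutoff`),
#'   `category`, `n_true`, `n_called`, `sensitivity`, `specificity`, `fdr`.
#' @export
truth_eval <- function(annotation, truth) {
  stopifnot(is.data.frame(annotation), is.data.frame(truth))
  if (!setequal(annotation$gene_id, truth$gene_id) ||
      nrow(annotation) != nrow(truth)) {
    stop("gene universes of calls and truth do not match", call. = FALSE)
  }
  ann <- annotation[match(truth$gene_id, annotation$gene_id), , drop = FALSE]

  true_class <- ifelse(truth$archetype == "transient.induced", "transient",
                       truth$archetype)
  called_class <- ann$activity_class
  class_rows <- purrr::map_dfr(unique(true_class), function(cl) {
    truth_pos <- true_class == cl
    call_pos <- !is.na(called_class) & called_class == cl
    confusion_row("activity_class", cl, truth_pos, call_pos)
  })

  shut_rows <- NULL
  induced <- truth$archetype %in% c("early.induced", "late.induced")
  for (comp in c("passive", "active", "tboa")) {
    if (!comp %in% names(ann)) next
    eff <- truth[[paste0(comp, "_effect")]]
    scope <- if (comp == "tboa") truth$archetype == "late.induced" else induced
    call <- ann[[comp]]
    down_call <- !is.na(call) & call == "down"
    shut_rows <- dplyr::bind_rows(
      shut_rows,
      confusion_row("shutoff", comp, scope & eff < 1, scope & down_call,
                    universe = scope)
    )
  }
  dplyr::bind_rows(class_rows, shut_rows)
}

confusion_row <- function(section, category, truth_pos, call_pos,
                          universe = NULL) {
  if (is.null(universe)) universe <- rep(TRUE, length(truth_pos))
  tp <- sum(truth_pos & call_pos)
  fp <- sum(!truth_pos & call_pos & universe)
  tn <- sum(!truth_pos & !call_pos & universe)
  tibble::tibble(
    section = section,
    category = category,
    n_true = sum(truth_pos),
    n_called = sum(call_pos & universe),
    sensitivity = if (sum(truth_pos) > 0) tp / sum(truth_pos) else NA_real_,
    specificity = if (fp + tn > 0) tn / (fp + tn) else NA_real_,
    fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_
  )
}
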