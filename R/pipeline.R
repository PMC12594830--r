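# Orchestration: YAML configuration, validation, and end-to-end runs from
# quantification tables (or a synthetic preset) to a results directory.
# All intermediates are files; no stage mutates another stage's inputs.
# A single seed governs all stochastic stages; per-stage seeds derive from it.

.PIPELINE_STAGES <- c("metrics", "differential", "lability", "dose",
                      "enrichment", "multivariate")

.CONFIG_KEYS <- c("preset", "inputs", "seed", "out_dir", "stages",
                  "contrasts", "fc_cutoff", "alpha", "nperm", "gsea_weight",
                  "gmt", "lability", "dose", "residual_sd", "missing_rate")

.default_contrasts <- function(preset) {
  switch(preset,
         dtt_ablation = "TCEP-DTT",
         acoa_dose = c("acoa_1-acoa_0", "acoa_10-acoa_0"),
         fractionation = c("Light-Supernatant", "Heavy-Supernatant", "Heavy-Light"),
         cold_bat = "C6-RT",
         smoke = "B-A",
         NULL)
}

#' Validate a pipeline configuration and fill defaults
#'
#' Rejects unknown keys (naming the offending key path), requires exactly
#' one of `preset`/`inputs`, checks stage names, and fills the default
#' thresholds: `fc_cutoff = 2`, `alpha = 0.05`, `nperm = 10000`.
#'
#' @param config named list
#' @return validated config list with defaults filled
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown)) abort_("unknown config key '%s'", unknown[1])
  if (!is.null(config$inputs)) {
    bad <- setdiff(names(config$inputs), c("peptides", "proteins", "design"))
    if (length(bad)) abort_("unknown config key 'inputs.%s'", bad[1])
    miss <- setdiff(c("peptides", "proteins", "design"), names(config$inputs))
    if (length(miss)) abort_("config key 'inputs.%s' is required", miss[1])
  }
  if (!is.null(config$lability)) {
    bad <- setdiff(names(config$lability), "contrast")
    if (length(bad)) abort_("unknown config key 'lability.%s'", bad[1])
  }
  if (!is.null(config$dose)) {
    bad <- setdiff(names(config$dose), c("baseline", "doses"))
    if (length(bad)) abort_("unknown config key 'dose.%s'", bad[1])
  }
  if (is.null(config$preset) == is.null(config$inputs)) {
    abort_("config must name exactly one of 'preset' or 'inputs'")
  }
  config$fc_cutoff <- config$fc_cutoff %||% 2
  config$alpha <- config$alpha %||% 0.05
  config$nperm <- config$nperm %||% 10000
  config$gsea_weight <- config$gsea_weight %||% 1
  config$out_dir <- config$out_dir %||% "thioacetylome_results"
  config$stages <- config$stages %||% c("metrics", "differential", "multivariate")
  bad_stage <- setdiff(config$stages, .PIPELINE_STAGES)
  if (length(bad_stage)) {
    abort_("unknown stage '%s'; valid stages: %s", bad_stage[1],
           paste(.PIPELINE_STAGES, collapse = ", "))
  }
  if (config$alpha <= 0 || config$alpha >= 1) abort_("alpha must be in (0, 1)")
  if (config$fc_cutoff < 1) abort_("fc_cutoff must be >= 1 (linear fold scale)")
  config
}

#' Load and validate a YAML pipeline configuration
#'
#' @param path YAML file
#' @return validated config list with defaults filled (see
#'   [validate_config()])
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_("config file '%s' does not exist", path)
  validate_config(yaml::read_yaml(path))
}

# Design-table prerequisites of the enabled stages, checked before any
# computation so contradictory configs fail fast.
.check_stage_prerequisites <- function(config, design) {
  if ("lability" %in% config$stages && !"reducing_agent" %in% names(design)) {
    abort_("lability stage requires a 'reducing_agent' covariate in the design")
  }
  if ("dose" %in% config$stages && !"dose_mM" %in% names(design) &&
      is.null(config$dose)) {
    abort_("dose stage requires a 'dose_mM' covariate or a 'dose:' config block")
  }
  if ("enrichment" %in% config$stages && is.null(config$gmt)) {
    abort_("enrichment stage requires a 'gmt' gene-set file in the config")
  }
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages on a synthetic preset or on quantification
#' tables and writes one TSV per output plus a run log recording the seed,
#' package version and effective thresholds. Rerunning with the same config
#' and seed is bit-identical.
#'
#' @param config validated config list, or the path of a YAML config
#' @return invisibly, a list with `out_dir` and the written file paths
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_config(config)
  config <- validate_config(config)
  seed <- config$seed

  if (!is.null(config$preset)) {
    spec <- preset_scenario(config$preset, residual_sd = config$residual_sd,
                            missing_rate = config$missing_rate, seed = seed)
    design <- .build_design(spec)
    .check_stage_prerequisites(config, design)
    sim <- simulate_experiment(spec)
    x <- sim$experiment
  } else {
    design <- utils::read.csv(config$inputs$design, stringsAsFactors = FALSE)
    .check_stage_prerequisites(config, design)
    x <- read_experiment(config$inputs$peptides, config$inputs$proteins,
                         config$inputs$design)
  }
  eff_seed <- seed %||% (if (!is.null(config$preset)) spec$seed else 1L)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    write_results_table(df, p)
    files <<- c(files, p)
  }

  contrasts <- config$contrasts %||%
    (if (!is.null(config$preset)) .default_contrasts(config$preset))
  fit <- NULL
  need_fit <- any(c("differential", "lability", "enrichment") %in% config$stages)
  if (need_fit) {
    if (is.null(contrasts)) abort_("differential analysis needs 'contrasts' in the config")
    fit <- fit_differential(x, as.list(contrasts))
  }

  if ("metrics" %in% config$stages) {
    mf <- modification_fraction(x)
    emit(data.frame(metric = names(mf), value = unlist(mf)), "metrics_summary.tsv")
    gi <- vapply(unique(x$design$group), function(g)
      normalized_acetyl_intensity(x, group = g), numeric(1))
    emit(data.frame(group = names(gi), normalized_acetyl_intensity = unname(gi)),
         "group_intensity.tsv")
    emit(rank_sites_by_psm(x), "psm_ranking.tsv")
  }

  if ("differential" %in% config$stages || need_fit) {
    emit(fit, "differential.tsv")
  }

  if ("lability" %in% config$stages) {
    lab_contrast <- (config$lability$contrast %||% contrasts[[1]])
    site_res <- acetyl_site_results(x, fit, contrast = lab_contrast)
    lab <- classify_lability(site_res, fc_cutoff = config$fc_cutoff,
                             alpha = config$alpha)
    emit(lab$calls, "lability_calls.tsv")
    emit(data.frame(metric = names(lab$summary), value = unlist(lab$summary)),
         "lability_summary.tsv")
  }

  if ("dose" %in% config$stages) {
    if (!is.null(config$dose)) {
      baseline <- config$dose$baseline
      doses <- unlist(config$dose$doses)
    } else {
      dm <- unique(x$design[, c("group", "dose_mM")])
      dm <- dm[order(as.numeric(dm$dose_mM)), ]
      baseline <- dm$group[1]
      doses <- dm$group[-1]
    }
    folds <- site_dose_folds(x, baseline, doses)
    fold_cols <- paste0("fold_", doses)
    ok <- stats::complete.cases(folds[, fold_cols, drop = FALSE])
    folds$class <- NA_character_
    if (length(doses) >= 2) {
      folds$class[ok] <- classify_dose_response(folds[[fold_cols[1]]][ok],
                                                folds[[fold_cols[length(fold_cols)]]][ok])
    }
    emit(folds, "dose_calls.tsv")
  }

  if ("enrichment" %in% config$stages) {
    genesets <- read_gmt(config$gmt)
    first <- fit[fit$contrast == (if (is.character(contrasts)) contrasts[[1]] else names(contrasts)[1]), ]
    ranks <- aggregate_stats_to_protein(first)
    fg <- unique(first$accession[!is.na(first$adj_p) & first$adj_p < config$alpha &
                                   abs(first$log2FC) >= log2(config$fc_cutoff)])
    bg <- unique(first$accession)
    if (length(fg) > 0) emit(fisher_ora(fg, bg, genesets), "ora.tsv")
    stat <- stats::setNames(ranks$stat, ranks$accession)
    emit(preranked_gsea(stat, genesets, nperm = config$nperm,
                        weight = config$gsea_weight,
                        seed = (eff_seed %% 1000000L) + 77L),
         "gsea.tsv")
  }

  if ("multivariate" %in% config$stages) {
    nm <- peptide_to_protein_normalize(x)
    parts <- split_by_variance(nm)
    mat <- parts$variant$values
    keep <- rowSums(is.na(mat)) == 0
    mat <- mat[keep, , drop = FALSE]
    if (nrow(mat) >= 2) {
      pca <- suppressWarnings(pca_scores(mat))
      emit(data.frame(sample_id = rownames(pca$scores), pca$scores,
                      check.names = FALSE), "pca_scores.tsv")
      emit(data.frame(component = seq_along(pca$variance_explained),
                      variance_explained = pca$variance_explained),
           "pca_variance.tsv")
      hc <- suppressWarnings(hcluster(mat))
      emit(data.frame(step = seq_len(nrow(hc$merge)), left = hc$merge[, 1],
                      right = hc$merge[, 2], height = hc$height),
           "hclust_merge.tsv")
      z <- zscore_rows(mat)
      emit(data.frame(analyte_id = rownames(z), z, check.names = FALSE),
           "zscores.tsv")
    }
  }

  log_lines <- c(
    sprintf("thioacetylome version: %s", as.character(utils::packageVersion("thioacetylome"))),
    sprintf("seed: %s", eff_seed),
    sprintf("input: %s", if (!is.null(config$preset)) paste0("preset ", config$preset)
            else config$inputs$peptides),
    sprintf("stages: %s", paste(config$stages, collapse = ", ")),
    sprintf("fold-change cutoff: %s-fold; alpha: %s; nperm: %s",
            config$fc_cutoff, config$alpha, config$nperm),
    sprintf("contrasts: %s", paste(unlist(contrasts), collapse = ", ")))
  log_path <- file.path(config$out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  files <- c(files, log_path)

  invisible(list(out_dir = config$out_dir, files = files))
}
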