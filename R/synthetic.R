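# Synthetic acetylome generator.
#
# Generates peptide/protein quantification tables with the statistical
# structure the analysis stages assume: log2-normal peptide intensities,
# a subpopulation of acetyl-cysteine peptides, group effects (reducing-agent
# ablation, acetyl-CoA dose titration, compartment membership, a coordinated
# latent shift), biological-replicate blocking, and missing values injected
# completely at random. Protein abundance is the per-sample sum of member
# peptide abundances.

.AA_NO_C <- strsplit("ADEFGHIKLMNPQRSTVWY", "")[[1]]

#' Build a validated synthetic-scenario specification
#'
#' @param name scenario label
#' @param n_proteins number of multi-peptide proteins
#' @param peptides_per_protein peptides per multi-peptide protein
#' @param n_singleton_proteins proteins represented by a single peptide
#'   (these become the non-variant part after peptide-to-protein
#'   normalization)
#' @param cys_peptide_fraction fraction of peptides containing cysteine
#' @param n_acetyl number of acetyl-cysteine peptides (one site each); if
#'   `NULL`, `acetyl_site_fraction` of the cysteine peptides
#' @param acetyl_site_fraction fraction of cysteine-containing peptides
#'   bearing an acetyl site (used when `n_acetyl` is `NULL`)
#' @param acetyl_placement `"per_protein"` places one acetyl peptide on each
#'   of the first `n_acetyl` proteins (distinct site keys); `"random"`
#'   samples among cysteine peptides
#' @param groups named integer vector of samples per group
#' @param block_scheme `"paired"` (the i-th sample of every group shares a
#'   biological block) or `"per_sample"` (no replicated blocks)
#' @param effect_model list describing injected effects; `type` is one of
#'   `"none"`, `"group_log2fc"`, `"reducing_agent_ablation"`,
#'   `"dose_titration"`, `"fraction_membership"`, `"latent_shift"`
#' @param residual_sd residual standard deviation on the log2 scale
#' @param missing_rate probability a measured cell is missing, independent
#'   across cells
#' @param seed integer seed governing all randomness of the scenario
#' @param acetyl_intensity_scale multiplicative intensity scale of acetyl
#'   peptides relative to bulk peptides (acetyl-cysteine peptides are a
#'   low-abundance subpopulation)
#' @param base_log2_mean,base_log2_sd log2-normal parameters of base
#'   peptide intensities
#' @param ambiguous_fraction fraction of acetyl annotations written as
#'   ambiguous `K/C` tokens
#' @param covariates optional named list: group -> named character vector of
#'   covariate values added to the design table
#' @return object of class `scenario_spec`
#' @export
scenario_spec <- function(name,
                          n_proteins,
                          peptides_per_protein,
                          n_singleton_proteins = 0L,
                          cys_peptide_fraction = 0.4,
                          n_acetyl = NULL,
                          acetyl_site_fraction = 0.5,
                          acetyl_placement = c("per_protein", "random"),
                          groups,
                          block_scheme = c("paired", "per_sample"),
                          effect_model = list(type = "none"),
                          residual_sd = 0.4,
                          missing_rate = 0,
                          seed = 1L,
                          acetyl_intensity_scale = 0.05,
                          base_log2_mean = 20,
                          base_log2_sd = 1.5,
                          ambiguous_fraction = 0.1,
                          covariates = NULL) {
  acetyl_placement <- match.arg(acetyl_placement)
  block_scheme <- match.arg(block_scheme)
  stopifnot(n_proteins >= 1, peptides_per_protein >= 1, n_singleton_proteins >= 0)
  if (cys_peptide_fraction < 0 || cys_peptide_fraction > 1) {
    abort_("cys_peptide_fraction must be in [0, 1]")
  }
  if (acetyl_site_fraction < 0 || acetyl_site_fraction > 1) {
    abort_("acetyl_site_fraction must be in [0, 1]")
  }
  if (missing_rate < 0 || missing_rate >= 1) abort_("missing_rate must be in [0, 1)")
  if (residual_sd < 0) abort_("residual_sd must be >= 0")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    abort_("groups must be a named vector of per-group sample counts")
  }
  if (any(groups < 1)) abort_("every group needs >= 1 sample")
  n_pep <- n_proteins * peptides_per_protein + n_singleton_proteins
  n_cys_nominal <- round(cys_peptide_fraction * n_pep)
  n_ac <- if (!is.null(n_acetyl)) as.integer(n_acetyl) else round(acetyl_site_fraction * n_cys_nominal)
  if (n_ac > 0 && cys_peptide_fraction == 0) {
    abort_("infeasible scenario: acetyl sites requested but cys_peptide_fraction is 0")
  }
  if (acetyl_placement == "per_protein" && n_ac > n_proteins) {
    abort_("infeasible scenario: per-protein placement needs n_acetyl <= n_proteins")
  }
  if (n_ac > n_pep) abort_("infeasible scenario: more acetyl peptides than peptides")
  structure(list(
    name = name, n_proteins = as.integer(n_proteins),
    peptides_per_protein = as.integer(peptides_per_protein),
    n_singleton_proteins = as.integer(n_singleton_proteins),
    cys_peptide_fraction = cys_peptide_fraction,
    n_acetyl = as.integer(n_ac),
    acetyl_placement = acetyl_placement,
    groups = groups, block_scheme = block_scheme,
    effect_model = effect_model,
    residual_sd = residual_sd, missing_rate = missing_rate,
    seed = as.integer(seed),
    acetyl_intensity_scale = acetyl_intensity_scale,
    base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
    ambiguous_fraction = ambiguous_fraction,
    covariates = covariates
  ), class = "scenario_spec")
}

#' Named scenario presets
#'
#' Fixed scenario specifications mirroring the study conditions each
#' analysis stage is exercised against:
#'
#' * `dtt_ablation`: 300 acetyl-cysteine sites, 267 thioester-labile
#'   (log2FC +2 for TCEP over DTT on the peptide/protein ratio scale) and 33
#'   with a reverse effect (log2FC -1.2), residual sd 0.4, n = 3 per arm,
#'   paired liver blocks, seed 1.
#' * `acoa_dose`: 100 baseline acetyl sites plus 13 sites induced at 1 mM
#'   and 47 more at 10 mM acetyl-CoA; stoichiometry multipliers solved so
#'   the normalized summed acetyl intensity rises exactly 3.7-fold (1 mM)
#'   and 8.6-fold (10 mM) over control while unique sites expand by exactly
#'   13% and 60%; three exemplar sites carry per-site folds (catalase-like
#'   3.0/3.3, GDH-like 4.5/36, GAPDH-like 1.0/15).
#' * `fractionation`: three subcellular compartments whose acetyl-site
#'   memberships have marginal sizes 392/249/237 and a three-way
#'   intersection of exactly 87.
#' * `cold_bat`: two temperature groups (n = 3, one block per animal) with
#'   100 sites loading on a single coordinated latent component.
#' * `smoke`: a tiny 20-peptide set for end-to-end smoke tests.
#'
#' @param name preset name
#' @param residual_sd,missing_rate,seed optional overrides of the preset
#'   values (e.g. `residual_sd = 0` for noise-free runs)
#' @return a [scenario_spec()]
#' @export
preset_scenario <- function(name, residual_sd = NULL, missing_rate = NULL,
                            seed = NULL) {
  valid <- c("dtt_ablation", "acoa_dose", "fractionation", "cold_bat", "smoke")
  if (length(name) != 1L || !name %in% valid) {
    abort_("unknown preset '%s'; valid presets: %s",
           paste(name, collapse = ","), paste(valid, collapse = ", "))
  }
  spec <- switch(name,
    dtt_ablation = scenario_spec(
      name = "dtt_ablation", n_proteins = 300, peptides_per_protein = 8,
      n_singleton_proteins = 50, cys_peptide_fraction = 0.4, n_acetyl = 300,
      acetyl_placement = "per_protein", base_log2_sd = 1.0,
      groups = c(TCEP = 3L, DTT = 3L), block_scheme = "paired",
      effect_model = list(type = "reducing_agent_ablation",
                          n_labile = 267L, n_reverse = 33L,
                          log2fc_labile = 2, log2fc_reverse = -1.2),
      residual_sd = 0.4, missing_rate = 0.05, seed = 1,
      covariates = list(TCEP = c(reducing_agent = "TCEP"),
                        DTT = c(reducing_agent = "DTT"))),
    acoa_dose = scenario_spec(
      name = "acoa_dose", n_proteins = 170, peptides_per_protein = 4,
      n_singleton_proteins = 40, cys_peptide_fraction = 0.45, n_acetyl = 160,
      acetyl_placement = "per_protein",
      groups = c(acoa_0 = 3L, acoa_1 = 3L, acoa_10 = 3L),
      block_scheme = "paired",
      effect_model = list(type = "dose_titration",
                          n_baseline = 100L, n_new_1 = 13L, n_new_10 = 47L,
                          intensity_fold = c(3.7, 8.6),
                          expansion_pct = c(13, 60),
                          exemplar_folds = list(catalase_like = c(3.0, 3.3),
                                                gdh_like = c(4.5, 36),
                                                gapdh_like = c(1.0, 15)),
                          exemplar_positions = c(catalase_like = 393L,
                                                 gdh_like = 112L,
                                                 gapdh_like = 150L)),
      residual_sd = 0.3, missing_rate = 0.02, seed = 2,
      covariates = list(acoa_0 = c(dose_mM = "0"),
                        acoa_1 = c(dose_mM = "1"),
                        acoa_10 = c(dose_mM = "10"))),
    fractionation = scenario_spec(
      name = "fractionation", n_proteins = 560, peptides_per_protein = 3,
      cys_peptide_fraction = 0.55, n_acetyl = 554,
      acetyl_placement = "per_protein",
      groups = c(Supernatant = 3L, Light = 3L, Heavy = 3L),
      block_scheme = "paired",
      effect_model = list(type = "fraction_membership",
                          unique_counts = c(Supernatant = 195L, Light = 62L,
                                            Heavy = 60L),
                          pair_counts = c("Supernatant+Light" = 60L,
                                          "Supernatant+Heavy" = 50L,
                                          "Light+Heavy" = 40L),
                          triple_count = 87L,
                          fraction_level = c(Supernatant = 2, Light = 1,
                                             Heavy = 0.7)),
      residual_sd = 0.4, missing_rate = 0.05, seed = 3,
      covariates = list(Supernatant = c(compartment = "cytoplasm"),
                        Light = c(compartment = "ER_golgi"),
                        Heavy = c(compartment = "mito_nuclei"))),
    cold_bat = scenario_spec(
      name = "cold_bat", n_proteins = 250, peptides_per_protein = 4,
      cys_peptide_fraction = 0.4, n_acetyl = 200,
      acetyl_placement = "per_protein",
      groups = c(RT = 3L, C6 = 3L), block_scheme = "per_sample",
      effect_model = list(type = "latent_shift", n_affected = 100L,
                          shift = 1.5),
      residual_sd = 0.4, missing_rate = 0.05, seed = 4,
      covariates = list(RT = c(temperature = "22C"),
                        C6 = c(temperature = "6C"))),
    smoke = scenario_spec(
      name = "smoke", n_proteins = 10, peptides_per_protein = 2,
      cys_peptide_fraction = 0.5, n_acetyl = 6,
      acetyl_placement = "per_protein",
      groups = c(A = 2L, B = 2L), block_scheme = "paired",
      effect_model = list(type = "group_log2fc", log2fc = c(B = 1),
                          n_affected = 3L, scope = "acetyl"),
      residual_sd = 0.3, missing_rate = 0, seed = 5)
  )
  if (!is.null(residual_sd)) spec$residual_sd <- residual_sd
  if (!is.null(missing_rate)) spec$missing_rate <- missing_rate
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  spec
}

# ---- skeleton generation ----------------------------------------------------

.random_sequences <- function(n, is_cys) {
  lens <- sample(8:18, n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(.AA_NO_C, L, replace = TRUE), collapse = "")
  }, character(1))
  for (i in which(is_cys)) {
    L <- lens[i]
    pos <- sample.int(L, 1)
    substr(seqs[i], pos, pos) <- "C"
  }
  seqs
}

.build_design <- function(spec) {
  groups <- spec$groups
  rows <- lapply(names(groups), function(g) {
    n <- groups[[g]]
    data.frame(sample_id = paste0(g, "_", seq_len(n)),
               group = g,
               block = if (spec$block_scheme == "paired") paste0("block_", seq_len(n))
                       else paste0(g, "_animal_", seq_len(n)),
               stringsAsFactors = FALSE)
  })
  design <- do.call(rbind, rows)
  if (!is.null(spec$covariates)) {
    covnames <- unique(unlist(lapply(spec$covariates, names)))
    for (cv in covnames) {
      design[[cv]] <- vapply(design$group, function(g) {
        v <- spec$covariates[[g]]
        if (!is.null(v) && cv %in% names(v)) v[[cv]] else NA_character_
      }, character(1))
    }
  }
  design
}

#' Generate the peptide/protein skeleton for a scenario
#'
#' Deterministic under the scenario seed. Produces peptide sequences with
#' acetyl sites placed only on cysteine residues (or ambiguous K/C), unique
#' accessions and peptide ids, base intensities, the per-group effect
#' multiplier matrix, the sample design, and the ground-truth site table.
#'
#' @param spec a [scenario_spec()]
#' @return a list of class `acetylome_proteome` with elements `peptides`,
#'   `base`, `accession_of`, `acetyl_idx`, `multipliers`, `truth`, `design`,
#'   `spec`
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  with_seed_(spec$seed, {
    n_core <- spec$n_proteins * spec$peptides_per_protein
    n_pep <- n_core + spec$n_singleton_proteins
    core_acc <- sprintf("P%05d", seq_len(spec$n_proteins))
    single_acc <- if (spec$n_singleton_proteins > 0)
      sprintf("S%05d", seq_len(spec$n_singleton_proteins)) else character(0)
    accession_of <- c(core_acc[ceiling(seq_len(n_core) / spec$peptides_per_protein)],
                      single_acc)
    peptide_id <- sprintf("pep%05d", seq_len(n_pep))

    # acetyl placement
    if (spec$acetyl_placement == "per_protein") {
      acetyl_idx <- (seq_len(spec$n_acetyl) - 1L) * spec$peptides_per_protein + 1L
    } else {
      acetyl_idx <- sort(sample.int(n_pep, spec$n_acetyl))
    }
    # cysteine-containing peptides: all acetyl peptides plus random others
    n_cys <- max(round(spec$cys_peptide_fraction * n_pep), spec$n_acetyl)
    is_cys <- logical(n_pep)
    is_cys[acetyl_idx] <- TRUE
    extra <- setdiff(seq_len(n_pep), acetyl_idx)
    n_extra <- min(n_cys - spec$n_acetyl, length(extra))
    if (n_extra > 0) is_cys[sample(extra, n_extra)] <- TRUE

    sequence <- .random_sequences(n_pep, is_cys)
    psm_count <- 1L + stats::rpois(n_pep, 11)
    psm_count[acetyl_idx] <- 1L + stats::rpois(length(acetyl_idx), 5)

    # acetyl-site annotations: protein-coordinate position from a random
    # peptide start offset; a fraction of tokens are ambiguous K/C
    sites <- rep("", n_pep)
    for (i in acetyl_idx) {
      cpos <- regexpr("C", sequence[i], fixed = TRUE)
      start <- sample.int(400L, 1)
      pos <- start + as.integer(cpos) - 1L
      amb <- stats::runif(1) < spec$ambiguous_fraction
      prob <- sample(c(NA, 50, 100), 1, prob = c(0.3, 0.3, 0.4))
      tok <- paste0(if (amb) "K/C" else "C", pos,
                    if (!is.na(prob)) paste0("(", prob, ")") else "")
      sites[i] <- paste0("[", tok, "]")
    }

    base <- 2^stats::rnorm(n_pep, spec$base_log2_mean, spec$base_log2_sd)
    # acetyl-cysteine peptides are a low-stoichiometry subpopulation: their
    # base intensity is a fixed fraction of the parent protein's remaining
    # (unmodified) peptide signal
    for (i in acetyl_idx) {
      sib <- setdiff(which(accession_of == accession_of[i]), i)
      ref <- if (length(sib)) sum(base[sib]) else base[i]
      base[i] <- spec$acetyl_intensity_scale * ref
    }

    peptides <- data.frame(peptide_id = peptide_id, sequence = sequence,
                           accessions = accession_of, sites = sites,
                           psm_count = psm_count, stringsAsFactors = FALSE)
    skel <- list(peptides = peptides, base = base, accession_of = accession_of,
                 acetyl_idx = acetyl_idx, groups = names(spec$groups))
    eff <- .build_effects(skel, spec)
    structure(list(peptides = eff$peptides, base = base,
                   accession_of = accession_of, acetyl_idx = acetyl_idx,
                   multipliers = eff$multipliers, truth = eff$truth,
                   design = .build_design(spec), spec = spec),
              class = "acetylome_proteome")
  })
}

# site key of the (single) acetyl site of peptide i
.acetyl_key <- function(peptides, accession_of, i) {
  s <- parse_site_annotation(peptides$sites[i])
  make_site_key(accession_of[i], s$residue[1], s$position[1], peptides$sequence[i])
}

.base_multipliers <- function(n_pep, groups) {
  m <- matrix(1, n_pep, length(groups), dimnames = list(NULL, groups))
  m
}

.build_effects <- function(skel, spec) {
  type <- spec$effect_model$type %||% "none"
  fn <- switch(type,
               none = .effects_none,
               group_log2fc = .effects_group_log2fc,
               reducing_agent_ablation = .effects_reducing_agent,
               dose_titration = .effects_dose,
               fraction_membership = .effects_fraction,
               latent_shift = .effects_latent,
               abort_("unknown effect model type '%s'", type))
  fn(skel, spec)
}

.truth_frame <- function(skel, class, extra = NULL) {
  idx <- skel$acetyl_idx
  keys <- vapply(idx, function(i) .acetyl_key(skel$peptides, skel$accession_of, i),
                 character(1))
  out <- data.frame(site_key = keys, peptide_id = skel$peptides$peptide_id[idx],
                    accession = skel$accession_of[idx], class = class,
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  out
}

.effects_none <- function(skel, spec) {
  list(peptides = skel$peptides,
       multipliers = .base_multipliers(nrow(skel$peptides), skel$groups),
       truth = .truth_frame(skel, class = rep("stable", length(skel$acetyl_idx)),
                            extra = data.frame(true_log2fc = rep(0, length(skel$acetyl_idx)))))
}

.effects_group_log2fc <- function(skel, spec) {
  em <- spec$effect_model
  idx_pool <- if (identical(em$scope %||% "acetyl", "acetyl")) skel$acetyl_idx
              else seq_len(nrow(skel$peptides))
  n_aff <- min(em$n_affected %||% length(idx_pool), length(idx_pool))
  affected <- idx_pool[seq_len(n_aff)]
  mult <- .base_multipliers(nrow(skel$peptides), skel$groups)
  for (g in names(em$log2fc)) {
    if (!g %in% skel$groups) abort_("effect group '%s' not in design groups", g)
    mult[affected, g] <- 2^em$log2fc[[g]]
  }
  cls <- ifelse(skel$acetyl_idx %in% affected, "affected", "stable")
  fc <- ifelse(skel$acetyl_idx %in% affected, em$log2fc[[1]], 0)
  list(peptides = skel$peptides, multipliers = mult,
       truth = .truth_frame(skel, cls, data.frame(true_log2fc = fc)))
}

# Lability effects are injected on the peptide/protein *ratio* scale: the raw
# TCEP-group multiplier x for an acetyl peptide with base b and sibling-sum C
# is solved from R = [bx/(C+bx)] / [b/(C+b)], i.e. x = R*C / (C + b(1-R)),
# so the zero-noise pipeline recovers the injected log2FC exactly even though
# protein abundance is the sum of member peptides.
.effects_reducing_agent <- function(skel, spec) {
  em <- spec$effect_model
  idx <- skel$acetyl_idx
  n_lab <- em$n_labile; n_rev <- em$n_reverse
  if (length(idx) != n_lab + n_rev) {
    abort_("reducing-agent model expects %d acetyl sites, got %d",
           n_lab + n_rev, length(idx))
  }
  cls <- sample(c(rep("tcep_labile", n_lab), rep("dtt_up", n_rev)))
  beta <- ifelse(cls == "tcep_labile", em$log2fc_labile, em$log2fc_reverse)
  mult <- .base_multipliers(nrow(skel$peptides), skel$groups)
  for (k in seq_along(idx)) {
    i <- idx[k]
    sib <- which(skel$accession_of == skel$accession_of[i])
    C <- sum(skel$base[setdiff(sib, i)])
    b <- skel$base[i]
    R <- 2^beta[k]
    denom <- C + b * (1 - R)
    if (denom <= 0) abort_("infeasible lability effect: sibling signal too low for site %d", k)
    mult[i, "TCEP"] <- R * C / denom
  }
  list(peptides = skel$peptides, multipliers = mult,
       truth = .truth_frame(skel, cls, data.frame(true_log2fc = beta)))
}

# Dose-titration effects: exemplar sites carry fixed per-site folds; the
# common multiplier for the remaining baseline sites is solved so that the
# aggregate normalized summed acetyl intensity changes by exactly the target
# fold at each dose, given the induced sites that appear at that dose.
.effects_dose <- function(skel, spec) {
  em <- spec$effect_model
  idx <- skel$acetyl_idx
  n_base <- em$n_baseline; n1 <- em$n_new_1; n10 <- em$n_new_10
  if (length(idx) != n_base + n1 + n10) {
    abort_("dose model expects %d acetyl sites, got %d", n_base + n1 + n10, length(idx))
  }
  groups <- skel$groups  # acoa_0, acoa_1, acoa_10
  baseline <- idx[seq_len(n_base)]
  new1 <- idx[n_base + seq_len(n1)]
  new10 <- idx[n_base + n1 + seq_len(n10)]
  ex_names <- names(em$exemplar_folds)
  ex_idx <- baseline[seq_along(ex_names)]
  # rewrite exemplar annotations to their canonical residue positions
  peptides <- skel$peptides
  for (k in seq_along(ex_names)) {
    peptides$sites[ex_idx[k]] <- paste0("[C", em$exemplar_positions[[ex_names[k]]], "]")
  }
  skel$peptides <- peptides

  base <- skel$base
  A <- sum(base[baseline])
  ex_base <- base[ex_idx]
  A_rest <- A - sum(ex_base)
  present0 <- setdiff(seq_len(nrow(peptides)), c(new1, new10))
  T0 <- sum(base[present0])
  S <- c(sum(base[new1]), sum(base[new1]) + sum(base[new10]))
  m <- numeric(2)
  for (d in 1:2) {
    F <- em$intensity_fold[d]
    if (T0 <= F * A) abort_("infeasible dose target: acetyl signal fraction too high")
    A_target <- F * A * (T0 - A) / (T0 - F * A)
    E_d <- sum(ex_base * vapply(em$exemplar_folds, `[`, numeric(1), d))
    m[d] <- (A_target - S[d] - E_d) / A_rest
    if (m[d] <= 0) abort_("infeasible dose target: solved multiplier not positive")
  }
  mult <- .base_multipliers(nrow(peptides), groups)
  rest <- setdiff(baseline, ex_idx)
  mult[rest, groups[2]] <- m[1]
  mult[rest, groups[3]] <- m[2]
  for (k in seq_along(ex_names)) {
    mult[ex_idx[k], groups[2]] <- em$exemplar_folds[[k]][1]
    mult[ex_idx[k], groups[3]] <- em$exemplar_folds[[k]][2]
  }
  mult[new1, groups[1]] <- NA
  mult[new10, groups[1]] <- NA
  mult[new10, groups[2]] <- NA

  role <- rep("baseline", length(idx))
  role[match(ex_idx, idx)] <- ex_names
  role[match(new1, idx)] <- "induced_1mM"
  role[match(new10, idx)] <- "induced_10mM"
  fc1 <- ifelse(idx %in% rest, m[1], NA_real_)
  fc10 <- ifelse(idx %in% rest, m[2], NA_real_)
  for (k in seq_along(ex_names)) {
    fc1[match(ex_idx[k], idx)] <- em$exemplar_folds[[k]][1]
    fc10[match(ex_idx[k], idx)] <- em$exemplar_folds[[k]][2]
  }
  cls <- rep(NA_character_, length(idx))
  has_fold <- !is.na(fc1)
  cls[has_fold] <- classify_dose_response(fc1[has_fold], fc10[has_fold])
  cls[role == "induced_1mM"] <- "induced_1mM"
  cls[role == "induced_10mM"] <- "induced_10mM"
  skel$peptides <- peptides
  truth <- .truth_frame(skel, cls,
                        data.frame(role = role, fc1 = fc1, fc10 = fc10))
  attr(truth, "intensity_fold") <- em$intensity_fold
  attr(truth, "expansion_pct") <- em$expansion_pct
  attr(truth, "rest_multipliers") <- m
  list(peptides = peptides, multipliers = mult, truth = truth)
}

.effects_fraction <- function(skel, spec) {
  em <- spec$effect_model
  groups <- skel$groups
  u <- em$unique_counts; p <- em$pair_counts; t3 <- em$triple_count
  patterns <- c(
    rep(groups[1], u[[groups[1]]]), rep(groups[2], u[[groups[2]]]),
    rep(groups[3], u[[groups[3]]]),
    rep(paste(groups[1], groups[2], sep = "+"), p[[paste(groups[1], groups[2], sep = "+")]]),
    rep(paste(groups[1], groups[3], sep = "+"), p[[paste(groups[1], groups[3], sep = "+")]]),
    rep(paste(groups[2], groups[3], sep = "+"), p[[paste(groups[2], groups[3], sep = "+")]]),
    rep(paste(groups, collapse = "+"), t3))
  idx <- skel$acetyl_idx
  if (length(idx) != length(patterns)) {
    abort_("fractionation model expects %d acetyl sites, got %d",
           length(patterns), length(idx))
  }
  mult <- .base_multipliers(nrow(skel$peptides), groups)
  for (k in seq_along(idx)) {
    members <- strsplit(patterns[k], "+", fixed = TRUE)[[1]]
    for (g in groups) {
      mult[idx[k], g] <- if (g %in% members) em$fraction_level[[g]] else NA
    }
  }
  list(peptides = skel$peptides, multipliers = mult,
       truth = .truth_frame(skel, class = patterns))
}

.effects_latent <- function(skel, spec) {
  em <- spec$effect_model
  idx <- skel$acetyl_idx
  n_aff <- min(em$n_affected, length(idx))
  affected <- idx[seq_len(n_aff)]
  w <- stats::runif(n_aff, 0.5, 1.5) * sample(c(-1, 1), n_aff, replace = TRUE)
  mult <- .base_multipliers(nrow(skel$peptides), skel$groups)
  cold <- skel$groups[2]
  mult[affected, cold] <- 2^(w * em$shift)
  fc <- rep(0, length(idx))
  fc[match(affected, idx)] <- w * em$shift
  cls <- rep("stable", length(idx))
  cls[match(affected, idx)] <- ifelse(w > 0, "cold_up", "cold_down")
  list(peptides = skel$peptides, multipliers = mult,
       truth = .truth_frame(skel, cls, data.frame(true_log2fc = fc)))
}

# ---- quantification ---------------------------------------------------------

#' Simulate quantified abundances for a generated proteome
#'
#' Per sample of group g, peptide abundance is
#' `base * multiplier[g] * 2^Normal(0, residual_sd)`; structurally absent
#' cells (multiplier `NA`) stay missing and additional cells are set missing
#' independently at `missing_rate`. Protein abundance is the per-sample sum
#' of member peptide abundances (all-missing sums stay missing).
#'
#' @param proteome output of [generate_proteome()]
#' @param spec scenario; defaults to the one stored in `proteome`
#' @return an [acetylome_experiment()]
#' @export
simulate_quant <- function(proteome, spec = proteome$spec) {
  stopifnot(inherits(proteome, "acetylome_proteome"))
  design <- proteome$design
  n_pep <- nrow(proteome$peptides)
  noise_seed <- (spec$seed %% 1000000000L) + 1000003L
  abund <- with_seed_(noise_seed, {
    a <- matrix(NA_real_, n_pep, nrow(design),
                dimnames = list(proteome$peptides$peptide_id, design$sample_id))
    for (s in seq_len(nrow(design))) {
      g <- design$group[s]
      noise <- if (spec$residual_sd > 0) 2^stats::rnorm(n_pep, 0, spec$residual_sd) else rep(1, n_pep)
      a[, s] <- proteome$base * proteome$multipliers[, g] * noise
    }
    if (spec$missing_rate > 0) {
      drop <- matrix(stats::runif(length(a)) < spec$missing_rate, n_pep)
      a[drop] <- NA
    }
    a
  })
  accs <- unique(proteome$accession_of)
  prot <- matrix(NA_real_, length(accs), nrow(design),
                 dimnames = list(accs, design$sample_id))
  grp_idx <- split(seq_len(n_pep), proteome$accession_of)
  for (acc in accs) {
    rows <- grp_idx[[acc]]
    sub <- abund[rows, , drop = FALSE]
    sums <- colSums(sub, na.rm = TRUE)
    sums[colSums(!is.na(sub)) == 0] <- NA
    prot[acc, ] <- sums
  }
  acetylome_experiment(proteome$peptides, abund, prot, design)
}

#' Generate and quantify a scenario in one call
#'
#' @param spec a [scenario_spec()] or preset name
#' @param ... passed to [preset_scenario()] when `spec` is a name
#' @return list with `experiment` (an [acetylome_experiment()]), `truth`
#'   (ground-truth site table) and `proteome`
#' @export
simulate_experiment <- function(spec, ...) {
  if (is.character(spec)) spec <- preset_scenario(spec, ...)
  proteome <- generate_proteome(spec)
  list(experiment = simulate_quant(proteome, spec),
       truth = proteome$truth, proteome = proteome)
}
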