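# Descriptive statistics of the cysteine acetylome: modification fractions,
# normalized summed acetyl intensity, PSM-based site ranking, cross-condition
# fold/expansion summaries, and compartment set overlaps.

#' Modification fraction of acetyl-cysteine peptides
#'
#' Counts acetyl-cysteine peptides (>= 1 acetyl site on C or ambiguous K/C)
#' and cysteine-containing peptides, and reports the acetyl fraction of the
#' total and of the cysteine-containing peptides, as percentages to one
#' decimal.
#'
#' @param x an `acetylome_experiment` or peptide data.frame with `sequence`
#'   and `sites` columns
#' @return list with `n_acetyl_cys`, `n_total`, `n_cys_containing`,
#'   `pct_of_total`, `pct_of_cys`
#' @export
modification_fraction <- function(x) {
  pep <- if (inherits(x, "acetylome_experiment")) x$peptides else x
  n_total <- nrow(pep)
  if (n_total == 0L) abort_("no peptides: modification fraction undefined")
  acetyl <- vapply(lapply(pep$sites, parse_site_annotation),
                   is_acetyl_cys_sites, logical(1))
  cysc <- grepl("C", pep$sequence, fixed = TRUE)
  n_ac <- sum(acetyl)
  n_cys <- sum(cysc)
  list(n_acetyl_cys = n_ac, n_total = n_total, n_cys_containing = n_cys,
       pct_of_total = round(100 * n_ac / n_total, 1),
       pct_of_cys = if (n_cys > 0) round(100 * n_ac / n_cys, 1) else NA_real_)
}

#' Normalized summed acetyl-cysteine intensity
#'
#' Per sample, the summed intensity of acetyl-cysteine peptides divided by
#' the summed intensity of all peptides (missing cells are absent from both
#' sums). A group value is the mean of its member samples' ratios, which is
#' robust to per-sample loading differences.
#'
#' @param x an `acetylome_experiment`
#' @param samples sample ids to use (default: all, or the group's samples)
#' @param group a group label from the design (alternative to `samples`)
#' @param per_sample if `TRUE`, return the per-sample ratios instead of
#'   their mean
#' @return ratio in \[0, 1\] (or named vector of per-sample ratios)
#' @export
normalized_acetyl_intensity <- function(x, samples = NULL, group = NULL,
                                        per_sample = FALSE) {
  stopifnot(inherits(x, "acetylome_experiment"))
  if (!is.null(group)) {
    if (!group %in% x$design$group) abort_("group '%s' not in design", group)
    samples <- x$design$sample_id[x$design$group == group]
  }
  samples <- samples %||% x$design$sample_id
  acetyl <- acetyl_cys_flag(x)
  ratios <- vapply(samples, function(s) {
    col <- x$peptide_abund[, s]
    tot <- sum(col, na.rm = TRUE)
    if (!any(!is.na(col))) return(NA_real_)
    sum(col[acetyl], na.rm = TRUE) / tot
  }, numeric(1))
  if (all(is.na(ratios))) abort_("all abundances missing in requested scope")
  if (per_sample) return(ratios)
  mean(ratios, na.rm = TRUE)
}

#' Rank acetyl-cysteine sites by peptide spectral matches
#'
#' Orders the acetyl-site table by descending PSM count, breaking ties
#' lexicographically by accession and then position.
#'
#' @param x an `acetylome_experiment`
#' @return data.frame of sites ordered by PSM count
#' @export
rank_sites_by_psm <- function(x) {
  sites <- acetyl_site_table(x)
  if (nrow(sites) == 0L) return(sites)
  ord <- order(-sites$psm_count, sites$accession, sites$position,
               method = "radix")
  out <- sites[ord, ]
  rownames(out) <- NULL
  out
}

# acetyl site keys detected (non-missing in >= 1 sample) in a group
.detected_site_keys <- function(x, group) {
  samples <- x$design$sample_id[x$design$group == group]
  if (length(samples) == 0L) abort_("group '%s' not in design", group)
  sites <- acetyl_site_table(x)
  if (nrow(sites) == 0L) return(character(0))
  detected_pep <- rownames(x$peptide_abund)[
    rowSums(!is.na(x$peptide_abund[, samples, drop = FALSE])) > 0]
  unique(sites$site_key[sites$peptide_id %in% detected_pep])
}

#' Intensity fold and unique-site expansion between two conditions
#'
#' Compares a treated group to a baseline group: `intensity_fold` is the
#' ratio of normalized summed acetyl intensities and
#' `unique_site_expansion_pct` the percent change in the number of unique
#' acetyl sites, where a site counts as present in a group if its peptide is
#' detected (non-missing) in at least one of the group's samples.
#'
#' @param x an `acetylome_experiment`
#' @param baseline,treated group labels from the design
#' @return list with `intensity_fold`, `unique_site_expansion_pct`,
#'   `n_sites_baseline`, `n_sites_treated`
#' @export
condition_expansion <- function(x, baseline, treated) {
  nb <- .detected_site_keys(x, baseline)
  nt <- .detected_site_keys(x, treated)
  if (length(nb) == 0L) abort_("baseline group '%s' has no detected acetyl sites", baseline)
  rb <- normalized_acetyl_intensity(x, group = baseline)
  rt <- normalized_acetyl_intensity(x, group = treated)
  list(intensity_fold = rt / rb,
       unique_site_expansion_pct = 100 * (length(nt) - length(nb)) / length(nb),
       n_sites_baseline = length(nb), n_sites_treated = length(nt))
}

#' Venn region counts for 2-3 compartment site sets
#'
#' Computes the cardinality of every region of the Venn partition of the
#' given named sets of site keys. Percentages can be taken against either
#' the union or any single set; both denominators are reported.
#'
#' @param sets named list of 2 or 3 character vectors of site keys
#' @return data.frame with `region` (member set names joined by `&`) and
#'   `count`; the union size is attached as attribute `"union"`
#' @export
site_overlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) %in% c(2L, 3L), !is.null(names(sets)))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1,
                                                   dimnames = list(NULL, names(sets)))
  pattern <- apply(membership, 1L, function(m) paste(names(sets)[m], collapse = "&"))
  combos <- unlist(lapply(seq_along(sets), function(k) {
    utils::combn(names(sets), k, paste, collapse = "&")
  }))
  counts <- vapply(combos, function(cb) sum(pattern == cb), integer(1))
  out <- data.frame(region = combos, count = unname(counts),
                    stringsAsFactors = FALSE)
  attr(out, "union") <- length(universe)
  attr(out, "set_sizes") <- vapply(sets, length, integer(1))
  out
}
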