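# Bespoke site classifiers: thioester-lability calls from TCEP-vs-DTT
# contrasts, and dose-response typing of acetyl-CoA titration fold changes.

#' Classify thioester lability from a TCEP-vs-DTT contrast
#'
#' Labels each acetyl-cysteine site from its TCEP-over-DTT log2 fold change
#' and BH-adjusted p-value: `tcep_labile` (more abundant with TCEP, i.e.
#' ablated by DTT — the thioester signature), `dtt_up`, or
#' `not_significant`. A site is significant only if `|log2FC| >=
#' log2(fc_cutoff)` and `adj_p < alpha`. The summary reports the percent of
#' significant sites labeled `tcep_labile`, rounded to a whole percent.
#'
#' @param results data.frame with columns `site_key`, `log2FC`, `adj_p`
#' @param fc_cutoff fold-change cutoff (linear scale; default 2-fold)
#' @param alpha adjusted-p cutoff
#' @return list of class `lability_calls` with `calls` (per-site labels)
#'   and `summary` (`n_significant`, `n_tcep_labile`, `n_dtt_up`,
#'   `pct_tcep_labile`; the percentage is `NA` when nothing is significant)
#' @export
classify_lability <- function(results, fc_cutoff = 2, alpha = 0.05) {
  for (col in c("site_key", "log2FC", "adj_p")) {
    if (!col %in% names(results)) abort_("results lack column '%s'", col)
  }
  lfc <- results$log2FC
  cut <- log2(fc_cutoff)
  sig <- !is.na(lfc) & !is.na(results$adj_p) &
    abs(lfc) >= cut & results$adj_p < alpha
  label <- rep("not_significant", nrow(results))
  label[sig & lfc > 0] <- "tcep_labile"
  label[sig & lfc < 0] <- "dtt_up"
  calls <- data.frame(site_key = results$site_key, log2FC = lfc,
                      adj_p = results$adj_p, label = label,
                      stringsAsFactors = FALSE)
  n_sig <- sum(sig)
  summary <- list(
    n_significant = n_sig,
    n_tcep_labile = sum(label == "tcep_labile"),
    n_dtt_up = sum(label == "dtt_up"),
    pct_tcep_labile = if (n_sig > 0) round(100 * sum(label == "tcep_labile") / n_sig)
                      else NA_real_)
  structure(list(calls = calls, summary = summary), class = "lability_calls")
}

#' @export
print.lability_calls <- function(x, ...) {
  s <- x$summary
  cat(sprintf("lability calls: %d sites, %d significant (%s%% TCEP-labile, %d DTT-up)\n",
              nrow(x$calls), s$n_significant,
              ifelse(is.na(s$pct_tcep_labile), "NA", s$pct_tcep_labile),
              s$n_dtt_up))
  invisible(x)
}

#' Map contrast results onto acetyl-cysteine sites
#'
#' Joins [fit_differential()] output (per peptide-protein analyte) to the
#' acetyl-site table, yielding one row per site key for a named contrast.
#' Peptides with several acetyl sites contribute one row per site with the
#' same statistics.
#'
#' @param x an `acetylome_experiment`
#' @param results output of [fit_differential()]
#' @param contrast contrast name to keep (default: the only one present)
#' @return data.frame with `site_key`, `log2FC`, `adj_p` (plus carried
#'   columns)
#' @export
acetyl_site_results <- function(x, results, contrast = NULL) {
  sites <- acetyl_site_table(x)
  contrast <- contrast %||% unique(results$contrast)[1]
  res <- results[results$contrast == contrast, , drop = FALSE]
  key <- paste(res$peptide_id, res$accession, sep = "@")
  skey <- paste(sites$peptide_id, sites$accession, sep = "@")
  m <- match(skey, key)
  keep <- !is.na(m)
  data.frame(site_key = sites$site_key[keep],
             peptide_id = sites$peptide_id[keep],
             accession = sites$accession[keep],
             log2FC = res$log2FC[m[keep]],
             t = res$t[m[keep]],
             p = res$p[m[keep]],
             adj_p = res$adj_p[m[keep]],
             stringsAsFactors = FALSE)
}

#' Classify a dose-response from fold changes at two doses
#'
#' Given per-site fold changes relative to control at a low and a high
#' acetyl-CoA dose, assigns exactly one of four classes:
#' * `unresponsive`: `max(fc_low, fc_high) < min_fold`;
#' * `saturable`: `fc_low >= saturation_ratio * fc_high` and
#'   `fc_low >= min_fold` (near-maximal response already at the low dose);
#' * `threshold`: `fc_low < threshold_low` and `fc_high >= min_fold`
#'   (no low-dose response, all-or-nothing at the high dose);
#' * `linear`: everything else (the fold keeps growing with dose).
#'
#' The numeric boundaries are exposed as parameters; the defaults place the
#' canonical exemplars — catalase-like (3.0, 3.3), glutamate-dehydrogenase-
#' like (4.5, 36) and GAPDH-like (1.0, 15) — in the saturable, linear and
#' threshold classes respectively.
#'
#' @param fc_low,fc_high fold changes (> 0) at the low and high dose
#' @param min_fold minimum fold to count as responsive
#' @param saturation_ratio low-dose fold as a fraction of the high-dose
#'   fold above which the response is saturable
#' @param threshold_low low-dose fold below which a high-dose response is a
#'   threshold response
#' @return character vector of class labels
#' @examples
#' classify_dose_response(c(3.0, 4.5, 1.0), c(3.3, 36, 15))
#' @export
classify_dose_response <- function(fc_low, fc_high, min_fold = 2,
                                   saturation_ratio = 0.8,
                                   threshold_low = 1.5) {
  if (length(fc_low) != length(fc_high)) abort_("fold vectors differ in length")
  if (any(is.na(fc_low) | is.na(fc_high)) || any(fc_low <= 0 | fc_high <= 0)) {
    abort_("fold changes must be positive and non-missing")
  }
  out <- character(length(fc_low))
  for (i in seq_along(fc_low)) {
    f1 <- fc_low[i]; f2 <- fc_high[i]
    out[i] <- if (max(f1, f2) < min_fold) "unresponsive"
    else if (f1 >= saturation_ratio * f2 && f1 >= min_fold) "saturable"
    else if (f1 < threshold_low && f2 >= min_fold) "threshold"
    else "linear"
  }
  out
}

#' Per-site fold changes across dose groups
#'
#' Aggregates peptide abundances to acetyl-site intensities (per-sample sum
#' over a site's peptides), averages within dose groups and returns each
#' site's fold change relative to the baseline group. Sites without signal
#' at baseline get `NA` folds (de novo sites cannot be expressed as a fold
#' over control).
#'
#' @param x an `acetylome_experiment`
#' @param baseline baseline group label
#' @param doses character vector of treated group labels
#' @return data.frame with `site_key` and one `fold_<group>` column per
#'   treated group
#' @export
site_dose_folds <- function(x, baseline, doses) {
  sites <- acetyl_site_table(x)
  if (nrow(sites) == 0L) abort_("experiment contains no acetyl sites")
  keys <- unique(sites$site_key)
  site_intensity <- function(group) {
    samples <- x$design$sample_id[x$design$group == group]
    if (length(samples) == 0L) abort_("group '%s' not in design", group)
    vapply(keys, function(k) {
      peps <- unique(sites$peptide_id[sites$site_key == k])
      sub <- x$peptide_abund[peps, samples, drop = FALSE]
      per_sample <- colSums(sub, na.rm = TRUE)
      per_sample[colSums(!is.na(sub)) == 0] <- NA
      if (all(is.na(per_sample))) NA_real_ else mean(per_sample, na.rm = TRUE)
    }, numeric(1))
  }
  base_int <- site_intensity(baseline)
  out <- data.frame(site_key = keys, stringsAsFactors = FALSE)
  for (g in doses) {
    out[[paste0("fold_", g)]] <- site_intensity(g) / base_int
  }
  out
}
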