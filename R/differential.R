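# Two-part differential abundance analysis:
#   1. peptide-to-protein ratio normalization (one analyte per
#      peptide-protein pair);
#   2. partition into variant and non-variant analytes (non-variant rows,
#      whose ratios are exactly 1.0 in every sample, are analyzed on their
#      original peptide abundances);
#   3. consensus within-block correlation of both parts;
#   4. blocked least-squares contrasts with empirical-Bayes variance
#      moderation (Smyth-style moment estimation on log s^2);
#   5. a single Benjamini-Hochberg adjustment per contrast across the
#      concatenated parts.

#' Peptide-to-protein ratio normalization
#'
#' For each peptide-protein pair and sample, divides the peptide abundance
#' by the parent protein abundance, removing protein-expression effects from
#' modification quantification. Peptides mapping to multiple proteins become
#' one analyte per protein assignment; analytes whose protein has no
#' abundance row are dropped with a warning. Missing propagates.
#'
#' @param x an `acetylome_experiment`
#' @return list of class `normalized_matrix` with `ratios` (analyte x
#'   sample), `original` (peptide abundances aligned to analytes) and
#'   `analytes` (data.frame `analyte_id`, `peptide_id`, `accession`)
#' @export
peptide_to_protein_normalize <- function(x) {
  stopifnot(inherits(x, "acetylome_experiment"))
  acc_list <- strsplit(x$peptides$accessions, ";", fixed = TRUE)
  n_per <- lengths(acc_list)
  analytes <- data.frame(
    peptide_id = rep(x$peptides$peptide_id, n_per),
    accession = unlist(acc_list),
    stringsAsFactors = FALSE)
  analytes$analyte_id <- paste(analytes$peptide_id, analytes$accession, sep = "@")
  known <- analytes$accession %in% rownames(x$protein_abund)
  if (any(!known)) {
    warn_("dropping %d analyte(s) with no protein abundance row (e.g. %s)",
          sum(!known), paste(utils::head(unique(analytes$accession[!known]), 3),
                             collapse = ", "))
    analytes <- analytes[known, , drop = FALSE]
  }
  pep_m <- x$peptide_abund[analytes$peptide_id, , drop = FALSE]
  prot_m <- x$protein_abund[analytes$accession, , drop = FALSE]
  ratios <- pep_m / prot_m
  rownames(ratios) <- analytes$analyte_id
  rownames(pep_m) <- analytes$analyte_id
  structure(list(ratios = ratios, original = pep_m, analytes = analytes),
            class = "normalized_matrix")
}

#' Split analytes into variant and non-variant parts
#'
#' Non-variant analytes have ratios of exactly 1.0 (within `tol`) in every
#' non-missing sample — the peptide and protein abundances coincide — and
#' carry no information after normalization; they are analyzed on their
#' original peptide abundances instead. Both parts are log2-transformed.
#'
#' @param nm a `normalized_matrix`
#' @param tol zero-variance tolerance on `|ratio - 1|`
#' @return list of class `da_parts` with `variant` and `nonvariant`, each a
#'   list of `values` (log2 matrix) and `analytes`
#' @export
split_by_variance <- function(nm, tol = 1e-9) {
  stopifnot(inherits(nm, "normalized_matrix"))
  dev <- abs(nm$ratios - 1)
  nonvar <- apply(dev, 1L, function(r) {
    obs <- !is.na(r)
    any(obs) && all(r[obs] < tol)
  })
  nonvar[is.na(nonvar)] <- FALSE
  part <- function(rows, values) {
    list(values = log2(values[rows, , drop = FALSE]),
         analytes = nm$analytes[rows, , drop = FALSE])
  }
  structure(list(variant = part(which(!nonvar), nm$ratios),
                 nonvariant = part(which(nonvar), nm$original)),
            class = "da_parts")
}

#' Consensus within-block correlation
#'
#' Estimates a single correlation shared by all analytes between samples of
#' the same biological block, after removing group means: per analyte, the
#' mean product of within-block residual pairs is scaled by the mean squared
#' residual, the per-analyte values are combined as the 10%-trimmed mean on
#' the atanh scale, and the result is clipped to (-0.99, 0.99). With no
#' replicated blocks the estimate is 0, with a warning.
#'
#' @param values log2 value matrix (analytes x samples)
#' @param design design data.frame with `sample_id`, `group`, `block`
#' @param trim trimming fraction for the atanh-scale mean
#' @return list of class `correlation_estimate` with `rho` and `n_analytes`
#' @export
consensus_correlation <- function(values, design, trim = 0.1) {
  design <- design[match(colnames(values), design$sample_id), ]
  blocks <- split(seq_len(nrow(design)), design$block)
  blocks <- blocks[lengths(blocks) >= 2L]
  if (length(blocks) == 0L) {
    warn_("no replicated blocks; consensus correlation set to 0")
    return(structure(list(rho = 0, n_analytes = 0L),
                     class = "correlation_estimate"))
  }
  groups <- design$group
  rho_i <- apply(values, 1L, function(y) {
    obs <- !is.na(y)
    if (sum(obs) < 3L) return(NA_real_)
    res <- y
    for (g in unique(groups)) {
      sel <- obs & groups == g
      if (sum(sel) == 0L) next
      res[sel] <- y[sel] - mean(y[sel])
    }
    res[!obs] <- NA
    prods <- unlist(lapply(blocks, function(ix) {
      r <- res[ix]
      r <- r[!is.na(r)]
      if (length(r) < 2L) return(NULL)
      cmb <- utils::combn(r, 2L)
      cmb[1, ] * cmb[2, ]
    }))
    msq <- mean(res^2, na.rm = TRUE)
    if (is.null(prods) || length(prods) == 0L || msq <= 0) return(NA_real_)
    max(min(mean(prods) / msq, 0.999), -0.999)
  })
  rho_i <- rho_i[!is.na(rho_i)]
  if (length(rho_i) == 0L) {
    warn_("no analyte informed the consensus correlation; set to 0")
    return(structure(list(rho = 0, n_analytes = 0L),
                     class = "correlation_estimate"))
  }
  rho <- tanh(mean(atanh(rho_i), trim = trim))
  rho <- max(min(rho, 0.99), -0.99)
  structure(list(rho = rho, n_analytes = length(rho_i)),
            class = "correlation_estimate")
}

# ---- empirical Bayes --------------------------------------------------------

# Newton solve of trigamma(x) = y (used by the moment estimator of the
# prior degrees of freedom).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (iter in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

#' Empirical-Bayes squeezing of sample variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0^2`
#' from the marginal distribution of the sample variances by matching
#' moments of `log s^2` (Smyth 2004), then returns the posterior variances
#' `(d0*s0^2 + d*s^2) / (d0 + d)`. When the moment estimate of the
#' between-analyte variance of `log s^2` is non-positive, `d0` is infinite
#' and `s0^2` is the geometric mean of the sample variances, so identical
#' variances shrink to themselves.
#'
#' @param s2 per-analyte residual variances
#' @param df per-analyte residual degrees of freedom
#' @param prior_df optional forced prior df (e.g. `Inf`)
#' @return list with `df_prior`, `var_prior`, `var_post`
#' @export
squeeze_variances <- function(s2, df, prior_df = NULL) {
  ok <- !is.na(s2) & df > 0 & s2 > 0
  if (!any(ok)) return(list(df_prior = 0, var_prior = NA_real_, var_post = s2))
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  if (is.null(prior_df)) {
    evar <- stats::var(e) - mean(trigamma(df[ok] / 2))
    if (is.na(evar) || evar <= 0) {
      df_prior <- Inf
      var_prior <- exp(mean(z))
    } else {
      df_prior <- 2 * trigamma_inverse(evar)
      var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
    }
  } else {
    df_prior <- prior_df
    var_prior <- if (is.infinite(prior_df)) exp(mean(z))
                 else exp(emean + digamma(prior_df / 2) - log(prior_df / 2))
  }
  var_post <- if (is.infinite(df_prior)) rep(var_prior, length(s2))
              else (df_prior * var_prior + df * s2) / (df_prior + df)
  var_post[is.na(s2) & is.infinite(df_prior)] <- var_prior
  list(df_prior = df_prior, var_prior = var_prior, var_post = var_post)
}

# ---- moderated contrasts ----------------------------------------------------

.parse_contrast <- function(contrast, levels) {
  if (is.character(contrast) && length(contrast) == 1L) {
    parts <- strsplit(contrast, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2L) abort_("contrast '%s' must have the form 'A-B'", contrast)
    cv <- stats::setNames(numeric(length(levels)), levels)
    for (p in parts) if (!p %in% levels) abort_("contrast group '%s' not in design", p)
    cv[parts[1]] <- 1
    cv[parts[2]] <- -1
    return(cv)
  }
  if (is.numeric(contrast) && !is.null(names(contrast))) {
    cv <- stats::setNames(numeric(length(levels)), levels)
    cv[names(contrast)] <- contrast
    return(cv)
  }
  abort_("contrast must be an 'A-B' string or a named numeric vector")
}

# Cholesky whitening matrix for an equicorrelated within-block covariance
# restricted to the observed samples.
.whitener <- function(blocks, rho) {
  n <- length(blocks)
  if (rho == 0) return(diag(n))
  sigma <- diag(n)
  same <- outer(blocks, blocks, "==")
  sigma[same & !diag(n)] <- rho
  R <- chol(sigma)
  backsolve(R, diag(n), transpose = TRUE)  # L^{-1} with Sigma = L L'
}

#' Blocked least-squares contrasts with empirical-Bayes moderation
#'
#' Fits per-analyte group means by least squares, generalized to an
#' equicorrelated within-block covariance (whitening with the consensus
#' correlation `rho`), estimates contrasts, squeezes the residual variances
#' with [squeeze_variances()], and returns moderated t-statistics with
#' `d + d0` degrees of freedom. Analytes observed in fewer than half the
#' samples of any design group are excluded from fitting; analytes with
#' fewer than 2 residual degrees of freedom get no p-value.
#'
#' @param values log2 value matrix (analytes x samples)
#' @param design design data.frame (`sample_id`, `group`, `block`)
#' @param contrasts named list of contrasts (`"A-B"` strings or named
#'   numeric vectors over group levels)
#' @param rho consensus within-block correlation
#' @param min_present_fraction minimum fraction of each group's samples an
#'   analyte must be observed in
#' @param prior_df optional forced prior df passed to [squeeze_variances()]
#' @return data.frame with one row per analyte x contrast: `analyte_id`,
#'   `contrast`, `log2FC`, `t`, `df_total`, `p` (no adjustment yet)
#' @export
moderated_contrast_fit <- function(values, design, contrasts, rho = 0,
                                   min_present_fraction = 0.5,
                                   prior_df = NULL) {
  design <- design[match(colnames(values), design$sample_id), ]
  levels_ <- unique(design$group)
  if (length(levels_) < 2L) abort_("design needs at least 2 groups")
  group_sizes <- table(design$group)
  if (all(group_sizes < 2L)) abort_("every group has fewer than 2 samples")
  if (is.null(names(contrasts))) {
    names(contrasts) <- vapply(contrasts, function(cc)
      if (is.character(cc)) cc else paste(names(cc), collapse = ""), character(1))
  }
  cvecs <- lapply(contrasts, .parse_contrast, levels = levels_)

  n_an <- nrow(values)
  fits <- vector("list", n_an)
  s2 <- rep(NA_real_, n_an)
  dfres <- rep(0, n_an)
  for (i in seq_len(n_an)) {
    y <- values[i, ]
    obs <- which(!is.na(y))
    present_ok <- all(vapply(levels_, function(g) {
      in_g <- design$group == g
      sum(obs %in% which(in_g)) >= min_present_fraction * sum(in_g)
    }, logical(1)))
    if (!present_ok || length(obs) < 2L) next
    gobs <- factor(design$group[obs], levels = levels_)
    if (nlevels(droplevels(gobs)) < 1L) next
    X <- stats::model.matrix(~ 0 + gobs)
    colnames(X) <- levels(gobs)
    keep_cols <- colSums(X) > 0
    X <- X[, keep_cols, drop = FALSE]
    W <- .whitener(design$block[obs], rho)
    Xw <- W %*% X
    yw <- drop(W %*% y[obs])
    fit <- stats::lm.fit(Xw, yw)
    d <- length(obs) - fit$rank
    xtxi <- tryCatch(chol2inv(chol(crossprod(Xw))), error = function(e) NULL)
    if (is.null(xtxi)) next
    dimnames(xtxi) <- list(colnames(X), colnames(X))
    fits[[i]] <- list(coef = fit$coefficients, xtxi = xtxi,
                      groups = colnames(X))
    if (d > 0) {
      s2[i] <- sum(fit$residuals^2) / d
      dfres[i] <- d
    }
  }

  sq <- squeeze_variances(s2, dfres, prior_df = prior_df)
  df_total <- dfres + sq$df_prior

  out <- vector("list", length(cvecs))
  for (k in seq_along(cvecs)) {
    cv <- cvecs[[k]]
    fc <- tt <- pp <- rep(NA_real_, n_an)
    for (i in seq_len(n_an)) {
      f <- fits[[i]]
      if (is.null(f)) next
      used <- names(cv)[cv != 0]
      if (!all(used %in% f$groups)) next
      cs <- cv[f$groups]
      fc[i] <- sum(cs * f$coef)
      se_unscaled <- sqrt(drop(t(cs) %*% f$xtxi %*% cs))
      vpost <- sq$var_post[i]
      if (!is.na(vpost) && vpost > 0) {
        tt[i] <- fc[i] / (se_unscaled * sqrt(vpost))
        if (dfres[i] >= 2) {
          pp[i] <- 2 * stats::pt(-abs(tt[i]), df = df_total[i])
        }
      }
    }
    out[[k]] <- data.frame(analyte_id = rownames(values),
                           contrast = names(cvecs)[k],
                           log2FC = fc, t = tt, df_total = df_total,
                           p = pp, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "df_prior") <- sq$df_prior
  attr(res, "var_prior") <- sq$var_prior
  rownames(res) <- NULL
  res
}

#' Combine parts and apply Benjamini-Hochberg per contrast
#'
#' Concatenates the variant and non-variant results and applies one BH
#' step-up adjustment per contrast across all analytes with a p-value.
#'
#' @param ... result data.frames from [moderated_contrast_fit()]
#' @return combined data.frame with an `adj_p` column (`adj_p >= p`,
#'   monotone step-up)
#' @export
adjust_and_combine <- function(...) {
  parts <- list(...)
  labels <- names(parts) %||% rep(NA_character_, length(parts))
  for (i in seq_along(parts)) {
    if (nrow(parts[[i]]) > 0)
      parts[[i]]$part <- if (!is.na(labels[i]) && nzchar(labels[i])) labels[i] else paste0("part", i)
  }
  res <- do.call(rbind, parts[vapply(parts, nrow, integer(1)) > 0])
  if (is.null(res) || nrow(res) == 0L) return(res)
  res$adj_p <- NA_real_
  for (ct in unique(res$contrast)) {
    sel <- res$contrast == ct & !is.na(res$p)
    res$adj_p[sel] <- stats::p.adjust(res$p[sel], method = "BH")
  }
  rownames(res) <- NULL
  res
}

#' Full differential-abundance analysis of an experiment
#'
#' Runs normalization, the variant/non-variant split, per-part consensus
#' correlation (when blocks are replicated), per-part moderated contrasts
#' and the combined BH adjustment.
#'
#' @param x an `acetylome_experiment`
#' @param contrasts contrasts as in [moderated_contrast_fit()]
#' @param block use the design blocks for a consensus correlation
#'   (`FALSE` forces `rho = 0`)
#' @param min_present_fraction see [moderated_contrast_fit()]
#' @return data.frame of per-analyte contrast results (`analyte_id`,
#'   `peptide_id`, `accession`, `part`, `contrast`, `log2FC`, `t`, `p`,
#'   `adj_p`); per-part consensus correlations are attached as attribute
#'   `"rho"`
#' @export
fit_differential <- function(x, contrasts, block = TRUE,
                             min_present_fraction = 0.5) {
  nm <- peptide_to_protein_normalize(x)
  parts <- split_by_variance(nm)
  rho <- c(variant = 0, nonvariant = 0)
  fit_part <- function(part, label) {
    if (nrow(part$values) == 0L) return(NULL)
    r <- if (block) consensus_correlation(part$values, x$design)$rho else 0
    rho[label] <<- r
    moderated_contrast_fit(part$values, x$design, contrasts, rho = r,
                           min_present_fraction = min_present_fraction)
  }
  fv <- fit_part(parts$variant, "variant")
  fn <- fit_part(parts$nonvariant, "nonvariant")
  args <- list()
  if (!is.null(fv)) args$variant <- fv
  if (!is.null(fn)) args$nonvariant <- fn
  res <- do.call(adjust_and_combine, args)
  an <- rbind(parts$variant$analytes, parts$nonvariant$analytes)
  m <- match(res$analyte_id, an$analyte_id)
  res$peptide_id <- an$peptide_id[m]
  res$accession <- an$accession[m]
  attr(res, "rho") <- rho
  res
}
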