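# Protein-level aggregation of peptide statistics, Fisher's-exact
# overrepresentation against the identified background, and preranked
# permutation GSEA with a gene-set (not sample) permutation null.

#' Aggregate peptide-level statistics to proteins
#'
#' Averages the moderated t-statistics of all peptide-protein analytes
#' mapping to the same protein, and ranks proteins by the aggregated
#' statistic, descending. Multi-protein peptides contribute to every mapped
#' protein; singleton proteins keep their peptide's t.
#'
#' @param results data.frame with `accession` and `t` columns (one row per
#'   peptide-protein analyte, e.g. one contrast's rows from
#'   [fit_differential()])
#' @return data.frame with `accession`, `stat` (mean t), `n_peptides`,
#'   ordered by decreasing `stat`
#' @export
aggregate_stats_to_protein <- function(results) {
  ok <- !is.na(results$t)
  res <- results[ok, , drop = FALSE]
  if (nrow(res) == 0L) {
    return(data.frame(accession = character(0), stat = numeric(0),
                      n_peptides = integer(0)))
  }
  agg <- stats::aggregate(res$t, by = list(accession = res$accession),
                          FUN = mean)
  cnt <- table(res$accession)
  out <- data.frame(accession = agg$accession, stat = agg$x,
                    n_peptides = as.integer(cnt[agg$accession]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$stat, out$accession), ]
  rownames(out) <- NULL
  out
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path
#' @return named list of member-identifier vectors
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Fisher overrepresentation analysis
#'
#' One-sided hypergeometric (enrichment) test of a foreground set against
#' the identified background, per gene set; gene sets are intersected with
#' the background before testing and BH-adjusted across sets. Sets disjoint
#' from the background are skipped with a warning.
#'
#' @param foreground character vector, subset of `background`
#' @param background character vector of all identified proteins
#' @param genesets named list of member vectors
#' @return data.frame with `set`, `k` (foreground in set), `K` (background
#'   in set), `n` (foreground size), `N` (background size), `odds_ratio`,
#'   `p`, `adj_p`
#' @export
fisher_ora <- function(foreground, background, genesets) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (length(foreground) == 0L || length(background) == 0L) {
    abort_("foreground and background must be nonempty")
  }
  stray <- setdiff(foreground, background)
  if (length(stray)) {
    abort_("foreground not a subset of background (e.g. %s)",
           paste(utils::head(stray, 3), collapse = ", "))
  }
  N <- length(background)
  n <- length(foreground)
  rows <- lapply(names(genesets), function(nm) {
    members <- intersect(unique(genesets[[nm]]), background)
    if (length(members) == 0L) {
      warn_("gene set '%s' is disjoint from the background; skipped", nm)
      return(NULL)
    }
    K <- length(members)
    k <- length(intersect(members, foreground))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    or <- (k * (N - K - n + k)) / ((K - k) * (n - k))
    data.frame(set = nm, k = k, K = K, n = n, N = N,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    return(data.frame(set = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), adj_p = numeric(0)))
  }
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score: increments
# proportional to |stat|^weight inside the set, -1/(N-K) outside; ES is the
# extreme deviation of the running sum.
.gsea_es <- function(stat_sorted, in_set, weight) {
  N <- length(stat_sorted)
  K <- sum(in_set)
  w <- abs(stat_sorted)^weight
  hit <- ifelse(in_set, w, 0)
  sh <- sum(hit)
  if (sh == 0) return(list(es = 0, peak = 0L))
  steps <- hit / sh - ifelse(in_set, 0, 1 / (N - K))
  running <- cumsum(steps)
  peak <- which.max(abs(running))
  list(es = running[peak], peak = peak)
}

#' Preranked permutation gene-set enrichment analysis
#'
#' Computes weighted Kolmogorov-Smirnov enrichment scores over the ranked
#' protein statistic and a gene-set permutation null (random same-size
#' sets): `p = (1 + #{|ES_null| >= |ES|}) / (nperm + 1)` and
#' `NES = ES / mean(|ES_null| of matching sign)`. Ties in the statistic are
#' broken by a deterministic, order-based jitter. BH adjustment across
#' sets.
#'
#' @param stats named numeric vector of per-protein ranking statistics
#' @param genesets named list of member vectors
#' @param nperm number of null permutations
#' @param weight exponent on `|stat|` inside the set (0 = unweighted KS)
#' @param seed integer seed for the permutation null
#' @param min_size,max_size gene-set size filters (after intersection with
#'   the ranked universe)
#' @return data.frame with `set`, `size`, `ES`, `NES`, `p`, `adj_p` and a
#'   `leading_edge` column of semicolon-joined members
#' @export
preranked_gsea <- function(stats, genesets, nperm = 10000, weight = 1,
                           seed = 1L, min_size = 2, max_size = 500) {
  if (is.null(names(stats))) abort_("stats must be a named vector")
  stats <- stats[!is.na(stats)]
  if (anyDuplicated(names(stats))) abort_("duplicate protein ids in stats")
  if (anyDuplicated(stats)) {
    # deterministic jitter: tiny offset by current order, far below the
    # statistic's resolution, so tied statistics get a stable ranking
    eps <- max(abs(stats), 1) * 1e-10
    stats <- stats - seq_along(stats) * eps
  }
  ord <- order(stats, decreasing = TRUE)
  stat_sorted <- stats[ord]
  ids <- names(stat_sorted)
  N <- length(ids)
  sets <- lapply(genesets, function(m) intersect(unique(m), ids))
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size
  if (any(sizes >= N)) {
    abort_("gene set(s) covering all ranked proteins have no complement: %s",
           paste(names(sets)[sizes >= N], collapse = ", "))
  }
  sets <- sets[keep]
  if (length(sets) == 0L) {
    return(data.frame(set = character(0), size = integer(0), ES = numeric(0),
                      NES = numeric(0), p = numeric(0), adj_p = numeric(0),
                      leading_edge = character(0)))
  }
  res <- with_seed_(seed, {
    rows <- lapply(names(sets), function(nm) {
      members <- sets[[nm]]
      K <- length(members)
      in_set <- ids %in% members
      obs <- .gsea_es(stat_sorted, in_set, weight)
      null_es <- vapply(seq_len(nperm), function(b) {
        idx <- sample.int(N, K)
        flag <- logical(N)
        flag[idx] <- TRUE
        .gsea_es(stat_sorted, flag, weight)$es
      }, numeric(1))
      p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (nperm + 1)
      same_sign <- null_es[sign(null_es) == sign(obs$es)]
      nes <- if (length(same_sign)) obs$es / mean(abs(same_sign)) else NA_real_
      le <- if (obs$es >= 0) ids[seq_len(obs$peak)][in_set[seq_len(obs$peak)]]
            else ids[obs$peak:N][in_set[obs$peak:N]]
      data.frame(set = nm, size = K, ES = obs$es, NES = nes, p = p,
                 leading_edge = paste(le, collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  res$adj_p <- stats::p.adjust(res$p, method = "BH")
  res <- res[, c("set", "size", "ES", "NES", "p", "adj_p", "leading_edge")]
  rownames(res) <- NULL
  res
}
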