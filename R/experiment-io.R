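# Containers and tab-separated I/O for peptide/protein quantification tables.
#
# Dialect:
#  * peptide table: TSV with peptide_id, sequence, accessions (";"-joined),
#    sites (annotation string), psm_count, then one abundance column per
#    sample id;
#  * protein table: TSV with accession then per-sample abundance columns;
#  * design table: CSV with sample_id, group, block plus free covariates.
# Missing abundance is distinct from zero; zeros are treated as missing on
# read (an MS1 intensity scale has no true zeros).

.PEPTIDE_META_COLS <- c("peptide_id", "sequence", "accessions", "sites", "psm_count")

#' Construct an acetylome experiment container
#'
#' Bundles a peptide metadata table, peptide and protein abundance matrices
#' (rows = peptides/proteins, columns = samples) and the sample design table
#' into a validated `acetylome_experiment` object.
#'
#' @param peptides data.frame with columns `peptide_id`, `sequence`,
#'   `accessions` (semicolon-joined), `sites` (annotation string),
#'   `psm_count`
#' @param peptide_abund numeric matrix, rownames = peptide ids, colnames =
#'   sample ids; `NA` = missing
#' @param protein_abund numeric matrix, rownames = accessions, colnames =
#'   sample ids
#' @param design data.frame with `sample_id`, `group`, `block` and optional
#'   covariate columns
#' @return an object of class `acetylome_experiment`
#' @export
acetylome_experiment <- function(peptides, peptide_abund, protein_abund, design) {
  stopifnot(is.data.frame(peptides), is.matrix(peptide_abund),
            is.matrix(protein_abund), is.data.frame(design))
  missing_cols <- setdiff(.PEPTIDE_META_COLS, names(peptides))
  if (length(missing_cols)) {
    abort_("peptide table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(peptides$peptide_id)) {
    dup <- unique(peptides$peptide_id[duplicated(peptides$peptide_id)])
    abort_("duplicate peptide_id(s): %s", paste(utils::head(dup, 5), collapse = ", "))
  }
  for (col in c("sample_id", "group", "block")) {
    if (!col %in% names(design)) abort_("design table lacks column '%s'", col)
  }
  if (anyDuplicated(design$sample_id)) abort_("duplicate sample ids in design")
  sids <- as.character(design$sample_id)
  check_samples <- function(mat, what) {
    extra <- setdiff(colnames(mat), sids)
    miss <- setdiff(sids, colnames(mat))
    if (length(extra) || length(miss)) {
      abort_("%s abundance columns do not match design sample ids (extra: %s; missing: %s)",
             what,
             if (length(extra)) paste(extra, collapse = ", ") else "none",
             if (length(miss)) paste(miss, collapse = ", ") else "none")
    }
  }
  check_samples(peptide_abund, "peptide")
  check_samples(protein_abund, "protein")
  if (any(peptide_abund < 0, na.rm = TRUE) || any(protein_abund < 0, na.rm = TRUE)) {
    abort_("abundances must be nonnegative")
  }
  structure(list(
    peptides = peptides,
    peptide_abund = peptide_abund[, sids, drop = FALSE],
    protein_abund = protein_abund[, sids, drop = FALSE],
    design = design
  ), class = "acetylome_experiment")
}

#' @export
print.acetylome_experiment <- function(x, ...) {
  cat(sprintf("acetylome_experiment: %d peptides, %d proteins, %d samples (%d groups)\n",
              nrow(x$peptides), nrow(x$protein_abund), nrow(x$design),
              length(unique(x$design$group))))
  invisible(x)
}

# Parsed site tables for every peptide (list column equivalent), cached.
peptide_sites <- function(x) {
  lapply(x$peptides$sites, parse_site_annotation)
}

# Logical: which peptides carry >= 1 acetyl site on C or ambiguous K/C.
acetyl_cys_flag <- function(x) {
  vapply(peptide_sites(x), is_acetyl_cys_sites, logical(1))
}

#' Table of acetyl-cysteine sites in an experiment
#'
#' Expands peptide annotations into one row per acetyl site on C (or
#' ambiguous K/C), with a site key of `accession:residue+position`
#' (peptide-sequence key when the position is unknown). Peptides mapping to
#' multiple accessions yield one row per accession.
#'
#' @param x an `acetylome_experiment`
#' @return data.frame with `peptide_id`, `accession`, `residue`, `position`,
#'   `probability`, `psm_count`, `site_key`
#' @export
acetyl_site_table <- function(x) {
  sites <- peptide_sites(x)
  rows <- vector("list", nrow(x$peptides))
  for (i in seq_along(sites)) {
    s <- sites[[i]]
    s <- s[s$mod_kind == "acetyl" & (s$residue == "C" | s$residue == "K/C"), , drop = FALSE]
    if (nrow(s) == 0L) next
    accs <- strsplit(x$peptides$accessions[i], ";", fixed = TRUE)[[1]]
    g <- expand.grid(acc = accs, j = seq_len(nrow(s)), stringsAsFactors = FALSE)
    rows[[i]] <- data.frame(
      peptide_id = x$peptides$peptide_id[i],
      accession = g$acc,
      residue = s$residue[g$j],
      position = s$position[g$j],
      probability = s$probability[g$j],
      psm_count = x$peptides$psm_count[i],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(peptide_id = character(0), accession = character(0),
                      residue = character(0), position = integer(0),
                      probability = numeric(0), psm_count = integer(0),
                      stringsAsFactors = FALSE)
  }
  out$site_key <- make_site_key(out$accession, out$residue, out$position,
                                x$peptides$sequence[match(out$peptide_id, x$peptides$peptide_id)])
  rownames(out) <- NULL
  out
}

#' Read an experiment from peptide/protein/design tables
#'
#' Reads the tab-separated peptide and protein tables and the CSV design
#' table, matches abundance columns to design sample ids (erroring with the
#' offending ids on mismatch), preserves missing cells as `NA` and converts
#' zero intensities to missing.
#'
#' @param peptide_path,protein_path paths to TSV tables
#' @param design_path path to CSV design table
#' @return an `acetylome_experiment`
#' @export
read_experiment <- function(peptide_path, protein_path, design_path) {
  design <- utils::read.csv(design_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  design$sample_id <- as.character(design$sample_id)
  design$block <- as.character(design$block)
  pep <- utils::read.delim(peptide_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  prot <- utils::read.delim(protein_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  miss <- setdiff(.PEPTIDE_META_COLS, names(pep))
  if (length(miss)) abort_("peptide table lacks column(s): %s", paste(miss, collapse = ", "))
  pep$peptide_id <- as.character(pep$peptide_id)
  abund_cols <- setdiff(names(pep), .PEPTIDE_META_COLS)
  pa <- as.matrix(pep[, abund_cols, drop = FALSE])
  rownames(pa) <- pep$peptide_id
  if (!"accession" %in% names(prot)) abort_("protein table lacks column 'accession'")
  pr <- as.matrix(prot[, setdiff(names(prot), "accession"), drop = FALSE])
  rownames(pr) <- as.character(prot$accession)
  pa[!is.na(pa) & pa == 0] <- NA
  pr[!is.na(pr) & pr == 0] <- NA
  # validate annotations eagerly so malformed rows fail at read time
  for (i in seq_len(nrow(pep))) parse_site_annotation(pep$sites[i])
  acetylome_experiment(pep[, .PEPTIDE_META_COLS], pa, pr, design)
}

#' Write an experiment to a directory
#'
#' Writes `peptides.tsv`, `proteins.tsv` and `design.csv` in the dialect
#' read by [read_experiment()]; a write-then-read round trip reproduces the
#' records.
#'
#' @param x an `acetylome_experiment`
#' @param dir output directory (created if needed)
#' @return invisibly, the three file paths
#' @export
write_experiment <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pep_path <- file.path(dir, "peptides.tsv")
  prot_path <- file.path(dir, "proteins.tsv")
  des_path <- file.path(dir, "design.csv")
  pep <- cbind(x$peptides[, .PEPTIDE_META_COLS],
               as.data.frame(x$peptide_abund, check.names = FALSE))
  write_results_table(pep, pep_path)
  prot <- cbind(data.frame(accession = rownames(x$protein_abund),
                           stringsAsFactors = FALSE),
                as.data.frame(x$protein_abund, check.names = FALSE))
  write_results_table(prot, prot_path)
  utils::write.csv(x$design, des_path, row.names = FALSE, quote = FALSE)
  invisible(c(peptides = pep_path, proteins = prot_path, design = des_path))
}

#' Write a homogeneous result table as TSV
#'
#' Deterministic column order (as given), floats rendered at fixed precision
#' so the file re-reads to the same values; an empty record list yields a
#' header-only file.
#'
#' @param rows data.frame of result records
#' @param path output path
#' @param digits significant digits for numeric columns
#' @return invisibly, `path`
#' @export
write_results_table <- function(rows, path, digits = 15) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- format_num(out[[j]], digits = digits)
    }
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort_("cannot open '%s' for writing: %s", path, conditionMessage(e))
  })
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
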