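# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Site keys for acetyl-cysteine sites
#'
#' A site is keyed by `accession:residue+position`; sites whose protein
#' position is unknown are keyed by the peptide sequence instead, so they
#' participate in peptide-level (not positional) bookkeeping.
#'
#' @param accession protein accession(s)
#' @param residue residue letter, `"C"`, `"K"`, `"M"` or ambiguous `"K/C"`
#' @param position 1-based protein coordinate, `NA` if unknown
#' @param sequence peptide sequence, used as fallback key
#' @return character vector of site keys
#' @keywords internal
make_site_key <- function(accession, residue, position, sequence) {
  ifelse(is.na(position),
         paste0(accession, ":seq:", sequence),
         paste0(accession, ":", residue, position))
}

# Stop with a formatted message, no call echo.
abort_ <- function(...) stop(sprintf(...), call. = FALSE)

warn_ <- function(...) warning(sprintf(...), call. = FALSE)

# Run code under a seed without disturbing the caller's RNG stream.
with_seed_ <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Format numerics for deterministic, re-readable text tables.
format_num <- function(x, digits = 15) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else format(v, digits = digits, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}
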