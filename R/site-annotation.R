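# Modification-site annotation strings and modification mass bookkeeping.
#
# Annotations are bracketed, semicolon-separated residue+position tokens with
# an optional parenthesized localization probability, e.g.
# "[C150(50); C154(50)]", "[C393]", "[K/C411]", "[C]".

.MOD_DELTA_MASS <- c(
  acetyl          = 42.011,  # +C2H2O on C or K (thioester-linked on C)
  carbamidomethyl = 57.021,  # iodoacetamide cap on C
  oxidation       = 15.995   # on M
)

#' Monoisotopic delta mass of a supported modification
#'
#' Returns the monoisotopic mass shift, in Daltons at three-decimal
#' precision, for the three modifications considered in the workflow:
#' acetyl (42.011 Da on C or K), carbamidomethyl (57.021 Da on C) and
#' oxidation (15.995 Da on M).
#'
#' @param mod_kind one of `"acetyl"`, `"carbamidomethyl"`, `"oxidation"`
#' @return numeric scalar, Daltons
#' @examples
#' mod_delta_mass("acetyl")
#' @export
mod_delta_mass <- function(mod_kind) {
  if (length(mod_kind) != 1L || !mod_kind %in% names(.MOD_DELTA_MASS)) {
    abort_("unknown modification kind '%s'; supported: %s",
           paste(mod_kind, collapse = ","),
           paste(names(.MOD_DELTA_MASS), collapse = ", "))
  }
  unname(.MOD_DELTA_MASS[[mod_kind]])
}

.empty_sites <- function() {
  data.frame(residue = character(0), ambiguous = logical(0),
             position = integer(0), probability = numeric(0),
             mod_kind = character(0), stringsAsFactors = FALSE)
}

#' Parse a modification-site annotation string
#'
#' Parses annotations such as `"[C150(50); C154(50)]"` into one row per
#' site. Ambiguous `"K/C"` tokens yield a single site with
#' `residue = "K/C"` and `ambiguous = TRUE`; such sites count as
#' cysteine-acetylation candidates downstream. Position and localization
#' probability are optional (`NA` when absent). Methionine sites are
#' interpreted as oxidation, cysteine/lysine sites as acetyl.
#'
#' @param text annotation string; `""` or `NA` yields an empty site table
#' @return data.frame with columns `residue`, `ambiguous`, `position`,
#'   `probability`, `mod_kind`
#' @examples
#' parse_site_annotation("[C150(50); C154(50)]")
#' parse_site_annotation("[K/C411]")
#' @export
parse_site_annotation <- function(text) {
  if (length(text) != 1L) abort_("parse_site_annotation() expects a single string")
  if (is.na(text) || !nzchar(trimws(text))) return(.empty_sites())
  text <- trimws(text)
  if (!grepl("^\\[.*\\]$", text)) {
    abort_("malformed annotation '%s': expected a bracketed token list", text)
  }
  inner <- substr(text, 2L, nchar(text) - 1L)
  if (!nzchar(trimws(inner))) return(.empty_sites())
  tokens <- trimws(strsplit(inner, ";", fixed = TRUE)[[1]])
  rx <- "^(K/C|C/K|[CKM])([0-9]+)?(\\(([0-9]+\\.?[0-9]*)\\))?$"
  rows <- lapply(tokens, function(tok) {
    m <- regmatches(tok, regexec(rx, tok))[[1]]
    if (length(m) == 0L) abort_("malformed site token '%s'", tok)
    res <- m[2]
    if (res == "C/K") res <- "K/C"
    pos <- if (nzchar(m[3])) as.integer(m[3]) else NA_integer_
    prob <- if (nzchar(m[5])) as.numeric(m[5]) else NA_real_
    if (!is.na(pos) && pos < 1L) abort_("malformed site token '%s': position must be >= 1", tok)
    if (!is.na(prob) && (prob < 0 || prob > 100)) {
      abort_("malformed site token '%s': probability outside [0, 100]", tok)
    }
    data.frame(residue = res, ambiguous = (res == "K/C"), position = pos,
               probability = prob,
               mod_kind = if (res == "M") "oxidation" else "acetyl",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Format a site table back into an annotation string
#'
#' Inverse of [parse_site_annotation()]: `parse(format(x))` is the identity
#' on well-formed site tables.
#'
#' @param sites data.frame as returned by [parse_site_annotation()]
#' @return annotation string (`""` for an empty table)
#' @export
format_site_annotation <- function(sites) {
  if (is.null(sites) || nrow(sites) == 0L) return("")
  toks <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    tok <- s$residue
    if (!is.na(s$position)) tok <- paste0(tok, s$position)
    if (!is.na(s$probability)) tok <- paste0(tok, "(", as.character(s$probability), ")")
    tok
  }, character(1))
  paste0("[", paste(toks, collapse = "; "), "]")
}

# Does this parsed site table mark the peptide as an acetyl-cysteine peptide?
# Ambiguous K/C sites count as cysteine candidates.
is_acetyl_cys_sites <- function(sites) {
  nrow(sites) > 0L &&
    any(sites$mod_kind == "acetyl" & (sites$residue == "C" | sites$residue == "K/C"))
}
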