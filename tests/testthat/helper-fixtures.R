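# Fixtures built in code: a small hand-checkable experiment and utilities
# shared across test files.

toy_design <- function() {
  data.frame(sample_id = c("A_1", "A_2", "B_1", "B_2"),
             group = c("A", "A", "B", "B"),
             block = c("b1", "b2", "b1", "b2"),
             stringsAsFactors = FALSE)
}

# Three peptides: an acetyl-C peptide on PROT1, an unmodified Cys peptide on
# PROT1, and a shared (two-protein) peptide without cysteine.
toy_experiment <- function(pep_abund = NULL, prot_abund = NULL) {
  design <- toy_design()
  peptides <- data.frame(
    peptide_id = c("pep1", "pep2", "pep3"),
    sequence = c("ACDEFK", "GCHIKL", "MNPQRS"),
    accessions = c("PROT1", "PROT1", "PROT1;PROT2"),
    sites = c("[C393]", "", ""),
    psm_count = c(10L, 5L, 2L),
    stringsAsFactors = FALSE)
  if (is.null(pep_abund)) {
    pep_abund <- matrix(c(10, 10, 12, 14,
                          40, 42, 44, 46,
                          50, 48, 44, 40),
                        nrow = 3, byrow = TRUE,
                        dimnames = list(peptides$peptide_id, design$sample_id))
  }
  if (is.null(prot_abund)) {
    prot_abund <- matrix(c(100, 100, 100, 100,
                           50, 48, 44, 40),
                         nrow = 2, byrow = TRUE,
                         dimnames = list(c("PROT1", "PROT2"), design$sample_id))
  }
  acetylome_experiment(peptides, pep_abund, prot_abund, design)
}

# Simple two-group scenario without injected effects, for null simulations.
null_spec <- function(n_proteins = 100, peptides_per_protein = 4,
                      residual_sd = 0.4, seed = 11,
                      groups = c(A = 3L, B = 3L)) {
  scenario_spec(name = "null", n_proteins = n_proteins,
                peptides_per_protein = peptides_per_protein,
                cys_peptide_fraction = 0.4, acetyl_site_fraction = 0.5,
                groups = groups, effect_model = list(type = "none"),
                residual_sd = residual_sd, missing_rate = 0, seed = seed)
}

expect_no_na <- function(x) expect_false(anyNA(x))
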