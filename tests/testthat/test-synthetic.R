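# Synthetic-acetylome generator: structure, determinism, noise calibration,
# preset contents.

test_that("generated proteomes have the requested structure", {
  spec <- scenario_spec(name = "t", n_proteins = 10, peptides_per_protein = 5,
                        cys_peptide_fraction = 0.6, n_acetyl = 8,
                        groups = c(A = 2L, B = 2L), seed = 3)
  pr <- generate_proteome(spec)
  expect_equal(nrow(pr$peptides), 50L)
  expect_equal(length(unique(pr$accession_of)), 10L)
  expect_false(anyDuplicated(pr$peptides$peptide_id) > 0)
  # acetyl sites only on cysteine-containing sequences
  expect_true(all(grepl("C", pr$peptides$sequence[pr$acetyl_idx], fixed = TRUE)))

  spec2 <- scenario_spec(name = "t", n_proteins = 5, peptides_per_protein = 4,
                         cys_peptide_fraction = 1, n_acetyl = 5,
                         groups = c(A = 2L, B = 2L), seed = 3)
  pr2 <- generate_proteome(spec2)
  expect_true(all(grepl("C", pr2$peptides$sequence, fixed = TRUE)))
})

test_that("infeasible scenarios are rejected", {
  expect_error(scenario_spec(name = "bad", n_proteins = 10,
                             peptides_per_protein = 2,
                             cys_peptide_fraction = 0, n_acetyl = 5,
                             groups = c(A = 2L, B = 2L)),
               "infeasible")
  expect_error(scenario_spec(name = "bad", n_proteins = 10,
                             peptides_per_protein = 2, missing_rate = 1,
                             groups = c(A = 2L, B = 2L)),
               "missing_rate")
  expect_error(scenario_spec(name = "bad", n_proteins = 10,
                             peptides_per_protein = 2, groups = c(A = 0L)),
               "group")
})

test_that("the same seed reproduces byte-identical tables", {
  a <- simulate_experiment(preset_scenario("smoke"))
  b <- simulate_experiment(preset_scenario("smoke"))
  expect_identical(a$experiment$peptide_abund, b$experiment$peptide_abund)
  expect_identical(a$truth, b$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_experiment(a$experiment, d1)
  write_experiment(b$experiment, d2)
  expect_identical(readLines(file.path(d1, "peptides.tsv")),
                   readLines(file.path(d2, "peptides.tsv")))
})

test_that("noise-free effects are exact and proteins are peptide sums", {
  spec <- scenario_spec(name = "t", n_proteins = 20, peptides_per_protein = 4,
                        cys_peptide_fraction = 0.5, n_acetyl = 10,
                        acetyl_placement = "per_protein",
                        groups = c(A = 2L, B = 2L),
                        effect_model = list(type = "group_log2fc",
                                            log2fc = c(B = 1),
                                            n_affected = 10L, scope = "acetyl"),
                        residual_sd = 0, missing_rate = 0, seed = 9)
  sim <- simulate_experiment(spec)
  x <- sim$experiment
  aff <- sim$truth$peptide_id[sim$truth$class == "affected"]
  a_mean <- rowMeans(x$peptide_abund[aff, c("A_1", "A_2")])
  b_mean <- rowMeans(x$peptide_abund[aff, c("B_1", "B_2")])
  expect_equal(unname(b_mean / a_mean), rep(2, length(aff)))
  # protein abundance equals the sum of member peptides
  members <- x$peptides$peptide_id[x$peptides$accessions == "P00001"]
  expect_equal(colSums(x$peptide_abund[members, , drop = FALSE]),
               x$protein_abund["P00001", ])
})

test_that("residual noise magnitude matches the specified sd", {
  spec <- scenario_spec(name = "t", n_proteins = 500, peptides_per_protein = 4,
                        cys_peptide_fraction = 0.3, n_acetyl = 0,
                        groups = c(A = 1L), residual_sd = 0.35,
                        missing_rate = 0, seed = 21)
  pr <- generate_proteome(spec)
  x <- simulate_quant(pr, spec)
  dev <- log2(x$peptide_abund[, 1]) - log2(pr$base)
  expect_lt(abs(sd(dev) - 0.35) / 0.35, 0.05)
})

test_that("missing values are injected at the requested rate", {
  spec <- scenario_spec(name = "t", n_proteins = 500, peptides_per_protein = 4,
                        cys_peptide_fraction = 0.3, n_acetyl = 0,
                        groups = c(A = 2L, B = 2L), residual_sd = 0.2,
                        missing_rate = 0.1, seed = 22)
  x <- simulate_quant(generate_proteome(spec), spec)
  rate <- mean(is.na(x$peptide_abund))
  expect_lt(abs(rate - 0.1), 0.01)
})

test_that("preset structures encode the study conditions", {
  spec <- preset_scenario("dtt_ablation")
  expect_equal(spec$n_acetyl, 300L)
  expect_equal(spec$effect_model$n_labile, 267L)
  expect_equal(spec$effect_model$log2fc_labile, 2)
  expect_equal(spec$effect_model$log2fc_reverse, -1.2)
  expect_equal(spec$residual_sd, 0.4)
  expect_equal(unname(spec$groups), c(3L, 3L))
  expect_equal(spec$seed, 1L)
  tr <- generate_proteome(spec)$truth
  expect_equal(sum(tr$class == "tcep_labile"), 267L)
  expect_equal(sum(tr$class == "dtt_up"), 33L)

  spec <- preset_scenario("acoa_dose")
  expect_equal(spec$effect_model$intensity_fold, c(3.7, 8.6))
  expect_equal(spec$effect_model$expansion_pct, c(13, 60))
  expect_equal(spec$effect_model$exemplar_folds$gdh_like, c(4.5, 36))
  tr <- generate_proteome(spec)$truth
  expect_identical(attr(tr, "intensity_fold"), c(3.7, 8.6))
  expect_identical(attr(tr, "expansion_pct"), c(13, 60))

  expect_error(preset_scenario("bogus"), "dtt_ablation")
})

test_that("ground truth partitions the generated acetyl sites", {
  for (name in c("dtt_ablation", "acoa_dose", "cold_bat", "smoke")) {
    pr <- generate_proteome(preset_scenario(name))
    expect_equal(nrow(pr$truth), length(pr$acetyl_idx))
    expect_false(anyDuplicated(pr$truth$site_key) > 0)
    expect_no_na(pr$truth$class)
  }
})
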