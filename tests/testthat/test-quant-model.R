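# Annotation parsing, modification masses, and table I/O.

test_that("annotation parsing handles the canonical forms", {
  s <- parse_site_annotation("[C150(50); C154(50)]")
  expect_equal(s$residue, c("C", "C"))
  expect_equal(s$position, c(150L, 154L))
  expect_equal(s$probability, c(50, 50))
  expect_equal(s$mod_kind, c("acetyl", "acetyl"))

  s <- parse_site_annotation("[C393]")
  expect_equal(nrow(s), 1L)
  expect_equal(s$position, 393L)
  expect_true(is.na(s$probability))

  s <- parse_site_annotation("[K/C411]")
  expect_true(s$ambiguous)
  expect_equal(s$residue, "K/C")
  expect_equal(s$position, 411L)

  expect_equal(nrow(parse_site_annotation("")), 0L)
  expect_equal(nrow(parse_site_annotation(NA_character_)), 0L)

  # position-free and methionine tokens
  s <- parse_site_annotation("[C]")
  expect_true(is.na(s$position))
  expect_equal(parse_site_annotation("[M87]")$mod_kind, "oxidation")
})

test_that("malformed annotations fail naming the token", {
  expect_error(parse_site_annotation("[X150]"), "X150")
  expect_error(parse_site_annotation("[C150(abc)]"), "C150")
  expect_error(parse_site_annotation("C150"), "bracket")
  expect_error(parse_site_annotation("[C150(150)]"), "probability")
  expect_error(parse_site_annotation("[C0]"), "position")
})

test_that("parse and format are mutually inverse on generated annotations", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(1:4, 1)
    toks <- vapply(seq_len(n), function(i) {
      res <- sample(c("C", "K", "M", "K/C"), 1)
      pos <- if (runif(1) < 0.8) sample(1:500, 1) else NA
      prob <- if (runif(1) < 0.6) sample(c(50, 33.3, 87.5, 100), 1) else NA
      paste0(res, if (!is.na(pos)) pos,
             if (!is.na(prob)) paste0("(", prob, ")"))
    }, character(1))
    txt <- paste0("[", paste(toks, collapse = "; "), "]")
    parsed <- parse_site_annotation(txt)
    expect_identical(format_site_annotation(parsed), txt)
    expect_identical(parse_site_annotation(format_site_annotation(parsed)), parsed)
  }
})

test_that("modification delta masses are the stable positive constants", {
  expect_identical(mod_delta_mass("acetyl"), 42.011)
  expect_identical(mod_delta_mass("carbamidomethyl"), 57.021)
  expect_identical(mod_delta_mass("oxidation"), 15.995)
  expect_error(mod_delta_mass("phospho"), "unknown")
  # acetyl = +C2H2O from monoisotopic atomic masses, independent of the
  # stored constant
  atomic <- c(C = 12, H = 1.0078250319, O = 15.9949146221)
  expect_equal(round(2 * atomic[["C"]] + 2 * atomic[["H"]] + atomic[["O"]], 3),
               mod_delta_mass("acetyl"))
})

test_that("experiment I/O round-trips and preserves missingness", {
  sim <- simulate_experiment(preset_scenario("smoke"))
  x <- sim$experiment
  dir <- withr::local_tempdir()
  write_experiment(x, dir)
  y <- read_experiment(file.path(dir, "peptides.tsv"),
                       file.path(dir, "proteins.tsv"),
                       file.path(dir, "design.csv"))
  expect_equal(nrow(y$peptides), nrow(x$peptides))  # no silent row drops
  expect_identical(y$peptides$sites, x$peptides$sites)
  expect_equal(y$peptide_abund, x$peptide_abund, tolerance = 1e-12)
  expect_equal(y$protein_abund, x$protein_abund, tolerance = 1e-12)
  expect_identical(y$design$group, x$design$group)
})

test_that("zero intensities read as missing and mismatched samples error", {
  sim <- simulate_experiment(preset_scenario("smoke"))
  x <- sim$experiment
  dir <- withr::local_tempdir()
  x$peptide_abund[1, 1] <- 0
  write_experiment(x, dir)
  y <- read_experiment(file.path(dir, "peptides.tsv"),
                       file.path(dir, "proteins.tsv"),
                       file.path(dir, "design.csv"))
  expect_true(is.na(y$peptide_abund[1, 1]))

  # an abundance column absent from the design must be reported
  des <- x$design[-1, ]
  utils::write.csv(des, file.path(dir, "design2.csv"), row.names = FALSE)
  expect_error(read_experiment(file.path(dir, "peptides.tsv"),
                               file.path(dir, "proteins.tsv"),
                               file.path(dir, "design2.csv")),
               x$design$sample_id[1], fixed = TRUE)
})

test_that("duplicate peptide ids are rejected", {
  x <- toy_experiment()
  pep <- x$peptides
  pep$peptide_id[2] <- "pep1"
  expect_error(acetylome_experiment(pep, x$peptide_abund, x$protein_abund,
                                    x$design),
               "duplicate")
})

test_that("result tables round-trip through write_results_table", {
  dir <- withr::local_tempdir()
  # header-only for an empty record list
  empty <- data.frame(analyte_id = character(0), log2FC = numeric(0),
                      p = numeric(0))
  p0 <- file.path(dir, "empty.tsv")
  write_results_table(empty, p0)
  expect_identical(readLines(p0), "analyte_id\tlog2FC\tp")

  set.seed(3)
  res <- data.frame(analyte_id = paste0("a", 1:100),
                    log2FC = rnorm(100), t = rt(100, 4),
                    p = runif(100), adj_p = runif(100))
  p1 <- file.path(dir, "res.tsv")
  write_results_table(res, p1)
  back <- utils::read.delim(p1, stringsAsFactors = FALSE)
  expect_equal(back, res, tolerance = 1e-12)

  suppressWarnings(
    expect_error(write_results_table(res, file.path(dir, "no/such/dir/x.tsv")),
                 "cannot open"))
})
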