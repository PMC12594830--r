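# Peptide-to-protein normalization, the two-part split, consensus
# correlation, moderated contrasts, and BH combination.

test_that("peptide/protein ratios follow the definition", {
  x <- toy_experiment(
    pep_abund = matrix(c(50, 50, 50, 50,
                         100, 100, 100, 100,
                         30, 30, 30, 30),
                       nrow = 3, byrow = TRUE,
                       dimnames = list(c("pep1", "pep2", "pep3"),
                                       toy_design()$sample_id)),
    prot_abund = matrix(c(100, 100, 100, 100,
                          60, 60, 60, 60),
                        nrow = 2, byrow = TRUE,
                        dimnames = list(c("PROT1", "PROT2"),
                                        toy_design()$sample_id)))
  nm <- peptide_to_protein_normalize(x)
  # pep3 maps to two proteins -> one analyte per assignment
  expect_equal(nrow(nm$ratios), 4L)
  expect_equal(unname(nm$ratios["pep1@PROT1", ]), rep(0.5, 4))
  # peptide identical to its protein -> exactly 1.0 everywhere
  expect_equal(unname(nm$ratios["pep2@PROT1", ]), rep(1, 4))
  expect_equal(unname(nm$ratios["pep3@PROT2", ]), rep(0.5, 4))
})

test_that("analytes without a protein row are dropped loudly", {
  x <- toy_experiment()
  x$protein_abund <- x$protein_abund["PROT1", , drop = FALSE]
  expect_warning(nm <- peptide_to_protein_normalize(x), "PROT2")
  expect_false("pep3@PROT2" %in% rownames(nm$ratios))
  expect_true("pep3@PROT1" %in% rownames(nm$ratios))
})

test_that("missing abundances propagate through normalization", {
  x <- toy_experiment()
  x$peptide_abund["pep1", "A_1"] <- NA
  nm <- peptide_to_protein_normalize(x)
  expect_true(is.na(nm$ratios["pep1@PROT1", "A_1"]))
})

test_that("the variance split sends all-1.0 rows to the nonvariant part", {
  x <- toy_experiment(
    pep_abund = matrix(c(50, 51, 52, 53,
                         100, 100, 100, 100,
                         30, 30, 30, 30),
                       nrow = 3, byrow = TRUE,
                       dimnames = list(c("pep1", "pep2", "pep3"),
                                       toy_design()$sample_id)),
    prot_abund = matrix(c(100, 100, 100, 100,
                          30, 30, 30, 30),
                        nrow = 2, byrow = TRUE,
                        dimnames = list(c("PROT1", "PROT2"),
                                        toy_design()$sample_id)))
  parts <- split_by_variance(peptide_to_protein_normalize(x))
  expect_true("pep2@PROT1" %in% rownames(parts$nonvariant$values))
  # the nonvariant part carries log2 of the original peptide abundances
  expect_equal(unname(parts$nonvariant$values["pep2@PROT1", ]),
               rep(log2(100), 4))
  # one deviating cell keeps a row in the variant part
  expect_true("pep1@PROT1" %in% rownames(parts$variant$values))

  # degenerate input: empty matrix -> two empty parts
  x0 <- x
  x0$peptides <- x$peptides[0, ]
  x0$peptide_abund <- x$peptide_abund[0, , drop = FALSE]
  p0 <- split_by_variance(peptide_to_protein_normalize(x0))
  expect_equal(nrow(p0$variant$values), 0L)
  expect_equal(nrow(p0$nonvariant$values), 0L)
})

paired_design <- function(n_blocks = 3) {
  data.frame(sample_id = c(paste0("A_", 1:n_blocks), paste0("B_", 1:n_blocks)),
             group = rep(c("A", "B"), each = n_blocks),
             block = rep(paste0("b", 1:n_blocks), 2),
             stringsAsFactors = FALSE)
}

test_that("consensus correlation recovers degenerate and null cases", {
  design <- paired_design()
  # duplicate samples identical per block, zero noise -> rho at the clip
  set.seed(5)
  blockvals <- matrix(rnorm(200 * 3), 200, 3)
  y <- cbind(blockvals, blockvals)
  colnames(y) <- design$sample_id
  rownames(y) <- paste0("a", 1:200)
  expect_gt(consensus_correlation(y, design)$rho, 0.95)

  # independent duplicates -> rho ~ 0
  y2 <- matrix(rnorm(1000 * 6), 1000, 6,
               dimnames = list(paste0("a", 1:1000), design$sample_id))
  expect_lt(abs(consensus_correlation(y2, design)$rho), 0.05)

  # no replicated blocks -> rho 0 with warning
  d2 <- design
  d2$block <- seq_len(nrow(d2))
  expect_warning(ce <- consensus_correlation(y2, d2), "block")
  expect_identical(ce$rho, 0)
})

test_that("an injected within-block correlation of -0.1 is recovered", {
  design <- paired_design()
  rho <- -0.1
  set.seed(8)
  n <- 2000
  y <- matrix(NA_real_, n, 6, dimnames = list(paste0("a", 1:n), design$sample_id))
  for (b in 1:3) {
    a <- rnorm(n)
    y[, b] <- a
    y[, 3 + b] <- rho * a + sqrt(1 - rho^2) * rnorm(n)
  }
  est <- consensus_correlation(y, design)$rho
  expect_lt(abs(est - rho), 0.05)
})

test_that("the moderated t matches the closed-form pooled t on one analyte", {
  design <- paired_design()
  y <- matrix(c(0.9, 1.0, 1.1, 1.9, 2.0, 2.1), 1,
              dimnames = list("a1", design$sample_id))
  fit <- moderated_contrast_fit(y, design, list("B-A"))
  expect_equal(fit$log2FC, 1)
  s2 <- (sum((c(0.9, 1, 1.1) - 1)^2) + sum((c(1.9, 2, 2.1) - 2)^2)) / 4
  t_hand <- 1 / sqrt(s2 * (1 / 3 + 1 / 3))
  expect_equal(fit$t, t_hand, tolerance = 1e-12)
})

test_that("moderated t equals ordinary t when all residual variances agree", {
  design <- paired_design()
  resid <- c(-0.2, 0.1, 0.1, -0.1, 0.2, -0.1)
  mu <- seq(0, 2, length.out = 40)
  y <- t(vapply(mu, function(m) resid + c(0, 0, 0, m, m, m), numeric(6)))
  dimnames(y) <- list(paste0("a", 1:40), design$sample_id)
  fit <- moderated_contrast_fit(y, design, list("B-A"))
  s2 <- sum((resid - rep(tapply(resid, design$group, mean), each = 3))^2) / 4
  t_ord <- fit$log2FC / sqrt(s2 * 2 / 3)
  expect_equal(fit$t, t_ord, tolerance = 1e-10)
  expect_true(is.infinite(attr(fit, "df_prior")))
})

test_that("forcing infinite prior df gives a pooled-variance z-style statistic", {
  design <- paired_design()
  set.seed(12)
  y <- matrix(rnorm(50 * 6), 50, 6,
              dimnames = list(paste0("a", 1:50), design$sample_id))
  fit <- moderated_contrast_fit(y, design, list("B-A"), prior_df = Inf)
  s2 <- rep(NA_real_, 50)
  for (i in 1:50) {
    r <- y[i, ] - rep(tapply(y[i, ], design$group, mean), each = 3)
    s2[i] <- sum(r^2) / 4
  }
  s0 <- exp(mean(log(s2)))
  expect_equal(fit$t, fit$log2FC / sqrt(s0 * 2 / 3), tolerance = 1e-10)
})

test_that("the fit agrees with limma at a shared correlation", {
  design <- paired_design()
  set.seed(42)
  y <- matrix(rnorm(200 * 6), 200, 6,
              dimnames = list(paste0("a", 1:200), design$sample_id))
  y[1:20, design$group == "B"] <- y[1:20, design$group == "B"] + 1
  X <- stats::model.matrix(~ 0 + factor(design$group))
  colnames(X) <- c("A", "B")

  mine <- moderated_contrast_fit(y, design, list("B-A"), rho = 0)
  lfit <- limma::eBayes(limma::contrasts.fit(
    limma::lmFit(y, X), limma::makeContrasts(B - A, levels = X)))
  expect_equal(mine$log2FC, unname(lfit$coefficients[, 1]), tolerance = 1e-10)
  expect_equal(mine$t, unname(lfit$t[, 1]), tolerance = 1e-8)
  expect_equal(mine$p, unname(lfit$p.value[, 1]), tolerance = 1e-8)
  expect_equal(attr(mine, "df_prior"), lfit$df.prior, tolerance = 1e-6)

  # whitening path: same consensus correlation plugged into both fits
  dc <- limma::duplicateCorrelation(y, X, block = design$block)
  rho <- dc$consensus.correlation
  mine2 <- moderated_contrast_fit(y, design, list("B-A"), rho = rho)
  lfit2 <- limma::eBayes(limma::contrasts.fit(
    limma::lmFit(y, X, block = design$block, correlation = rho),
    limma::makeContrasts(B - A, levels = X)))
  expect_equal(mine2$t, unname(lfit2$t[, 1]), tolerance = 1e-8)
})

test_that("analytes observed in under half a group are excluded", {
  design <- paired_design()
  y <- matrix(rnorm(2 * 6), 2, 6, dimnames = list(c("a1", "a2"), design$sample_id))
  y[1, c("A_1", "A_2")] <- NA  # 1 of 3 observed in group A
  fit <- moderated_contrast_fit(y, design, list("B-A"))
  expect_true(is.na(fit$log2FC[fit$analyte_id == "a1"]))
  expect_false(is.na(fit$log2FC[fit$analyte_id == "a2"]))
})

test_that("BH combination matches the hand-computed step-up", {
  a <- data.frame(analyte_id = c("x", "y"), contrast = "B-A",
                  log2FC = 0, t = 0, df_total = 4, p = c(0.01, 0.02))
  b <- data.frame(analyte_id = "z", contrast = "B-A",
                  log2FC = 0, t = 0, df_total = 4, p = 0.03)
  res <- adjust_and_combine(variant = a, nonvariant = b)
  expect_equal(res$adj_p, c(0.03, 0.03, 0.03))
  expect_true(all(res$adj_p >= res$p))
  expect_setequal(unique(res$part), c("variant", "nonvariant"))

  single <- adjust_and_combine(variant = a[1, ])
  expect_equal(single$adj_p, single$p)

  # sorted by p the adjusted values are nondecreasing
  set.seed(2)
  big <- data.frame(analyte_id = paste0("a", 1:50), contrast = "c",
                    log2FC = 0, t = 0, df_total = 4, p = runif(50))
  r <- adjust_and_combine(variant = big)
  expect_false(is.unsorted(r$adj_p[order(r$p)]))
})

test_that("null simulations keep the BH-significant fraction at bay", {
  sim <- simulate_experiment(null_spec(n_proteins = 250))
  fit <- fit_differential(sim$experiment, list("B-A"))
  frac <- mean(fit$adj_p < 0.05, na.rm = TRUE)
  expect_lte(frac, 0.05)
})

test_that("injected ratio-scale effects are recovered with small bias", {
  spec <- scenario_spec(
    name = "recov", n_proteins = 250, peptides_per_protein = 4,
    cys_peptide_fraction = 0.5, n_acetyl = 250,
    acetyl_placement = "per_protein",
    groups = c(TCEP = 3L, DTT = 3L),
    effect_model = list(type = "reducing_agent_ablation", n_labile = 225L,
                        n_reverse = 25L, log2fc_labile = 2,
                        log2fc_reverse = -1.2),
    residual_sd = 0.4, missing_rate = 0, seed = 31)
  sim <- simulate_experiment(spec)
  fit <- fit_differential(sim$experiment, list("TCEP-DTT"))
  res <- acetyl_site_results(sim$experiment, fit, "TCEP-DTT")
  m <- match(res$site_key, sim$truth$site_key)
  bias <- mean(res$log2FC - sim$truth$true_log2fc[m], na.rm = TRUE)
  expect_lt(abs(bias), 0.05)
})

test_that("moderation shrinks the spread of null t-statistics", {
  design <- paired_design()
  set.seed(77)
  n <- 400
  sds <- sqrt(1 / rgamma(n, shape = 2, rate = 2))
  y <- matrix(rnorm(n * 6, sd = rep(sds, 6)), n, 6,
              dimnames = list(paste0("a", 1:n), design$sample_id))
  fit <- moderated_contrast_fit(y, design, list("B-A"))
  t_ord <- vapply(seq_len(n), function(i) {
    r <- y[i, ] - rep(tapply(y[i, ], design$group, mean), each = 3)
    s2 <- sum(r^2) / 4
    (mean(y[i, 4:6]) - mean(y[i, 1:3])) / sqrt(s2 * 2 / 3)
  }, numeric(1))
  expect_lt(var(fit$t), var(t_ord))
})
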