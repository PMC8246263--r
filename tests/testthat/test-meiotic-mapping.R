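test_that("genotype encodings follow the inheritance models", {
  calls <- c("REF", "HET", "HOM")
  expect_identical(encode_genotypes(calls, "recessive"), c(0, 0, 1))
  expect_identical(encode_genotypes(calls, "dominant"), c(0, 1, 1))
  expect_identical(encode_genotypes(c("REF", "MISSING", "HOM"), "additive"),
                   c(0, NA, 2))
  expect_error(encode_genotypes(c("REF", "het"), "recessive"), "unknown genotype")
})

test_that("Wald p-values come from the chi-square(1) of the squared z", {
  expect_identical(wald_p(0, 2.5), 1)
  expect_equal(wald_p(1.959964, 1), 0.05, tolerance = 1e-6)
  # monotone in |z|
  p <- wald_p(c(0.5, 1, 2, 4), 1)
  expect_true(all(diff(p) < 0))
  expect_error(wald_p(1, 0), "positive")
  expect_error(wald_p(1, -2), "positive")
})

test_that("maximum-likelihood route matches an independent optimiser", {
  y <- c(0, 0, 1, 0, 1, 1, 1, 0)
  x <- c(0, 1, 0, 0, 1, 2, 2, 1)
  fit <- fit_logistic(y, x)
  expect_identical(fit$method, "IRLS")
  # frozen from the Newton-from-multiple-starts oracle (helper-oracles.R)
  expect_equal(fit$coef, 1.43812167, tolerance = 1e-6)
  expect_equal(fit$se, 1.15129542, tolerance = 1e-6)

  # uninformative symmetric design: zero coefficient, p = 1
  flat <- fit_logistic(c(0, 1, 0, 1), c(0, 0, 1, 1))
  expect_equal(flat$coef, 0, tolerance = 1e-8)
  expect_equal(flat$p, 1)
})

test_that("complete separation triggers a finite, flagged Firth fit", {
  y <- c(0, 0, 0, 1, 1, 1)
  x <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_logistic(y, x)
  expect_identical(fit$method, "Firth")
  expect_true(is.finite(fit$coef) && is.finite(fit$se))
  # for a saturated 2x2 design the Firth optimum is the 0.5-corrected
  # log odds ratio: 2*log(7); intercept log(1/7)
  expect_equal(fit$coef, 2 * log(7), tolerance = 1e-4)
  expect_equal(fit$intercept, log(1 / 7), tolerance = 1e-4)
})

test_that("small-sample fits agree with brute-force likelihood maximisation", {
  set.seed(33)
  n_checked <- 0
  for (case in 1:10) {
    n <- sample(6:12, 1)
    x <- sample(0:2, n, replace = TRUE)
    y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x))
    if (length(unique(y)) < 2 || length(unique(x)) < 2) next
    fit <- fit_logistic(y, x)
    oracle <- if (fit$method == "Firth") firth_grid_oracle(y, x)
              else ml_logistic_oracle(y, x)
    expect_equal(fit$coef, oracle$coef, tolerance = 1e-4)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 5)
})

test_that("degenerate designs are skipped with p recorded as 1", {
  const_y <- fit_logistic(c(0, 0, 0, 0), c(0, 1, 0, 1))
  expect_identical(const_y$method, "degenerate")
  expect_identical(const_y$p, 1)
  const_x <- fit_logistic(c(0, 1, 0, 1), c(1, 1, 1, 1))
  expect_identical(const_x$method, "degenerate")
  expect_error(fit_logistic(c(0, 1), c(0, 1, 1)), "lengths differ")
  expect_error(fit_logistic(c(0, 2, 1), c(0, 1, 1)), "binary")
})

test_that("pedigree mapping applies the per-pedigree Bonferroni threshold", {
  map <- tiny_map()
  set.seed(41)
  panel <- generate_allele_panel(60, map = map)
  ped <- breed_pedigree(panel, map, n_dams = 3, litter_sizes = c(7, 7, 7),
                        model = phenotype_model(NULL, background = 0))
  ped <- assign_phenotypes(ped)

  res <- map_pedigree(ped, alpha = 0.05)
  expect_equal(res$threshold, 8.3333e-4, tolerance = 1e-4)
  expect_equal(res$threshold, 0.05 / 60)
  # zero affected mice: every test degenerate with p = 1
  expect_identical(nrow(res$significant), 0L)
  expect_true(all(res$tests$p == 1))
  expect_true(all(res$tests$method == "degenerate"))

  strict <- map_pedigree(ped, alpha = 0.05, per_model_bonferroni = TRUE)
  expect_equal(strict$threshold, 0.05 / 120)

  # no scored G3 mice is an error
  unscored <- ped
  unscored$mice$phenotype[unscored$mice$generation == "G3"] <- "unscored"
  expect_error(map_pedigree(unscored), "no scored G3")
})

test_that("a planted fully penetrant recessive allele is mapped and the
          test reproduces by hand from the genotype table", {
  map <- tiny_map()
  cfg <- sim_config(map = map, n_alleles = 40, n_dams = 6,
                    litter_range = c(8, 8), background = 0)
  peds <- qualifying_causal_pedigrees(1, 1.0, cfg, min_hom = 8, seed = 55)
  ped <- peds[[1]]
  idx <- enuscreen:::scored_g3(ped)
  expect_gte(length(idx), 40)
  res <- map_pedigree(ped, alpha = 0.05, models = c("recessive", "dominant"))
  expect_true(enuscreen:::causal_flagged(res, ped, window_cM = 5))
  rec_sig <- res$significant[res$significant$model == "recessive", ]
  expect_gt(nrow(rec_sig), 0)

  # hand recomputation of the causal allele's recessive test from the
  # emitted genotype table, via the independent penalized-likelihood oracle
  causal <- ped$model$causal_allele
  y <- as.numeric(ped$mice$phenotype[idx] == "affected")
  xc <- encode_genotypes(ped$genotypes[ped$mice$mouse_id[idx], causal],
                         "recessive")
  row <- res$tests[res$tests$allele_id == causal &
                     res$tests$model == "recessive", ]
  oracle <- if (row$method == "Firth") firth_grid_oracle(y, xc)
            else ml_logistic_oracle(y, xc)
  expect_equal(row$estimate, oracle$coef, tolerance = 1e-3)
  p_hand <- pchisq((oracle$coef / oracle$se)^2, df = 1, lower.tail = FALSE)
  expect_equal(log10(row$p), log10(p_hand), tolerance = 0.02)
})

test_that("manhattan tables are ordered, finite and consistent with calls", {
  map <- tiny_map()
  cfg <- sim_config(map = map, n_alleles = 30, n_dams = 6,
                    litter_range = c(8, 8), background = 0)
  ped <- qualifying_causal_pedigrees(1, 1.0, cfg, min_hom = 8, seed = 77)[[1]]
  res <- map_pedigree(ped)
  tab <- manhattan_table(res, map)
  expect_identical(nrow(tab), nrow(res$tests))
  expect_true(all(is.finite(tab$neg_log10_p)))
  expect_true(all(tab$neg_log10_p[tab$significant] > -log10(res$threshold)))
  if (any(res$tests$p == 1)) expect_identical(min(tab$neg_log10_p), 0)
  ord <- order(match(tab$chrom, map$chrom), tab$pos_cM)
  expect_identical(ord, seq_len(nrow(tab)))
})
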