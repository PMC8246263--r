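test_that("penetrance is the affected fraction within a genotype class", {
  # 15 affected of 21 heterozygotes (a dominant allele)
  dom <- counts_pedigree(n_het = 21, het_affected = 15, n_ref = 10)
  p_het <- penetrance(dom, "A1", "HET")
  expect_equal(p_het$fraction, 15 / 21)
  expect_identical(c(p_het$n_affected, p_het$n_scored), c(15L, 21L))
  expect_identical(percent_round(p_het$n_affected, p_het$n_scored, 0), 71)

  # 6 affected of 6 homozygotes
  rec <- counts_pedigree(n_hom = 6, hom_affected = 6, n_ref = 12)
  expect_identical(penetrance(rec, "A1", "HOM")$fraction, 1)

  # zero affected of any n
  none <- counts_pedigree(n_hom = 9, hom_affected = 0, n_ref = 3)
  expect_identical(penetrance(none, "A1", "HOM")$fraction, 0)

  # undefined class warns and returns NaN
  expect_warning(undef <- penetrance(none, "A1", "HET"), "undefined")
  expect_true(is.nan(undef$fraction))
})

test_that("screen percentage arithmetic reproduces printed ratios half-up", {
  expect_identical(percent_round(94, 1275, 1), 7.4)
  expect_identical(percent_round(20, 94, 1), 21.3)
  expect_identical(percent_round(12, 19, 0), 63)
  expect_identical(percent_round(15, 21, 0), 71)
  expect_identical(percent_round(6, 6, 0), 100)
  expect_true(is.na(percent_round(0, 0)))
  expect_identical(round_half_up(0.5), 1)
  expect_identical(round_half_up(7.35, 1), 7.4)
  expect_identical(round_half_up(-7.35, 1), -7.4)
})

test_that("pedigree classification counts are consistent on a simulated screen", {
  map <- tiny_map()
  cfg <- sim_config(map = map, n_alleles = 20, causal_fraction = 0.25,
                    background = 0.02,
                    penetrance_dist = function(n) rep(1, n))
  peds <- simulate_screen(40, cfg, seed = 14)
  res <- map_screen(peds, cfg)
  s <- classify_pedigrees(peds, res)
  expect_identical(s$n_pedigrees, 40L)
  expect_lte(s$n_mapped, s$n_affected)
  expect_lte(s$n_affected, s$n_pedigrees)
  expect_identical(s$n_mapped, s$n_mapped_recessive + s$n_mapped_dominant)
  expect_identical(length(s$affected_counts_mapped) +
                     length(s$affected_counts_unmapped), s$n_affected)
  expect_equal(s$pct_affected, percent_round(s$n_affected, 40, 1))
  if (s$n_mapped > 0) {
    expect_true(all(s$mapped$pedigree_id %in%
                      vapply(peds, function(p) p$pedigree_id, character(1))))
    # mapped pedigrees carry the minimal-p significant allele
    expect_true(all(s$mapped$p <= cfg$alpha / cfg$n_alleles))
  }
  expect_warning(empty <- classify_pedigrees(list()), "empty screen")
  expect_identical(empty$n_pedigrees, 0L)
  expect_identical(empty$pct_affected, 0)
})

test_that("penetrance distribution applies a strict >= 0.8 style threshold", {
  d <- penetrance_distribution(c(rep(0.9, 12), rep(0.5, 7)))
  expect_identical(c(d$n_ge, d$n_total), c(12L, 19L))
  expect_identical(d$pct, 63)
  expect_identical(penetrance_distribution(rep(1, 5))$fraction, 1)
  expect_identical(penetrance_distribution(rep(0.79, 5))$fraction, 0)
  expect_identical(penetrance_distribution(c(0.8, 0.79))$n_ge, 1L)
  expect_warning(w <- penetrance_distribution(c(0.9, NaN, 0.7)), "excluded")
  expect_identical(w$n_total, 2L)
})

test_that("Wilcoxon rank-sum matches enumeration and handles ties", {
  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$p, 1)
  expect_identical(same$method, "normal-approximation")

  small <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_identical(small$method, "exact")
  expect_equal(small$p, 2 / 6)

  # exact p equals full-permutation enumeration for combined n <= 10
  set.seed(61)
  for (case in 1:12) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    v <- sample(100, na + nb)  # no ties
    a <- v[1:na]; b <- v[-(1:na)]
    got <- wilcoxon_rank_sum(a, b)
    expect_identical(got$method, "exact")
    expect_equal(got$p, perm_wilcoxon_oracle(a, b), tolerance = 1e-12)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("saturation counting applies the damaging >= 2 HOM rule", {
  tab <- data.frame(
    gene_id = c("A", "B", "C"),
    effect_class = c("probably_damaging", "putative_null", "benign"),
    n_hom = c(2, 1, 5)
  )
  got <- saturation_count(tab, universe_size = 3)
  expect_identical(got$n_genes_covered, 1L)
  expect_equal(got$fraction, 1 / 3)
  expect_identical(saturation_count(tab[0, ], 10)$n_genes_covered, 0L)
  expect_error(saturation_count(tab, universe_size = 2), "smaller")

  # simulated screen: fraction matches an independent recount over the
  # emitted TSV tables
  map <- tiny_map()
  cfg <- sim_config(map = map, n_alleles = 15)
  peds <- simulate_screen(12, cfg, seed = 31)
  tab2 <- screen_allele_table(peds)
  universe <- nrow(tab2)
  got2 <- saturation_count(tab2, universe)

  tmp <- withr::local_tempdir()
  recount <- 0L
  for (p in peds) {
    d <- file.path(tmp, p$pedigree_id)
    write_pedigree_tables(p, d)
    mice <- read.delim(file.path(d, "mice.tsv"))
    al <- read.delim(file.path(d, "alleles.tsv"))
    gt <- read.delim(file.path(d, "genotypes.tsv"))
    scored <- mice$mouse_id[mice$generation == "G3" &
                              mice$phenotype %in% c("affected", "unaffected")]
    hom <- gt[gt$genotype == "HOM" & gt$mouse_id %in% scored, ]
    n_hom <- table(factor(hom$allele_id, al$allele_id))
    damaging <- al$effect_class %in% c("probably_damaging",
                                       "possibly_damaging", "putative_null")
    recount <- recount + sum(damaging & n_hom >= 2)
  }
  expect_identical(got2$n_genes_covered, recount)
})

test_that("power curves are reproducible, null-bounded and monotone", {
  map <- tiny_map()
  cfg <- sim_config(map = map, n_alleles = 20, n_dams = 6,
                    litter_range = c(8, 8))
  pc <- power_curve(c(0, 0.4, 1), replicates = 25, config = cfg, seed = 5)
  pc2 <- power_curve(c(0, 0.4, 1), replicates = 25, config = cfg, seed = 5)
  expect_identical(pc, pc2)
  # null penetrance: mapping probability within family-wise error noise
  expect_lte(pc$mapping_probability[pc$penetrance == 0], 0.1)
  # monotone in penetrance at fixed cohort size (paired seeds, MC error)
  expect_lte(pc$mapping_probability[1], pc$mapping_probability[3])
  expect_gte(pc$mapping_probability[3],
             pc$mapping_probability[2] - 3 * max(pc$mc_se, 0.05))
  expect_true(all(pc$mc_se >= 0 & pc$mc_se <= 0.5))
})
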