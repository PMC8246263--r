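#' Round half away from zero
#'
#' Reporting arithmetic for screen percentages: `round()` in R rounds half
#' to even, whereas printed screen ratios use conventional half-up
#' rounding, so 94/1275 reports as 7.4% at one decimal.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count pair, rounded for reporting
#'
#' @param numerator,denominator Counts.
#' @param digits Decimal places the report prints.
#' @return `100 * numerator / denominator`, half-up rounded; `NA` when the
#'   denominator is zero.
#' @export
percent_round <- function(numerator, denominator, digits = 1) {
  ifelse(denominator == 0, NA_real_,
         round_half_up(100 * numerator / denominator, digits))
}

#' Penetrance of an allele within a pedigree
#'
#' The fraction of scored G3 mice of the requested genotype class that are
#' affected — e.g. HOM penetrance for a recessive allele, HET penetrance
#' for a dominant one. Unscored and dead mice are excluded.
#'
#' @param pedigree An `enu_pedigree` with phenotypes assigned.
#' @param allele_id Allele to evaluate.
#' @param genotype_class `"HOM"` or `"HET"`.
#' @return List: `fraction` (`NaN` if no scored mouse has the genotype,
#'   with a warning), `n_affected`, `n_scored`.
#' @export
penetrance <- function(pedigree, allele_id, genotype_class = c("HOM", "HET")) {
  genotype_class <- match.arg(genotype_class)
  stopifnot(inherits(pedigree, "enu_pedigree"),
            allele_id %in% pedigree$alleles$allele_id)
  idx <- scored_g3(pedigree)
  gt <- pedigree$genotypes[pedigree$mice$mouse_id[idx], allele_id]
  in_class <- gt == genotype_class
  n_scored <- sum(in_class)
  if (n_scored == 0L) {
    warning("no scored G3 mouse with genotype ", genotype_class,
            " at ", allele_id, ": penetrance undefined")
    return(list(fraction = NaN, n_affected = 0L, n_scored = 0L))
  }
  n_aff <- sum(pedigree$mice$phenotype[idx][in_class] == "affected")
  list(fraction = n_aff / n_scored, n_affected = n_aff, n_scored = n_scored)
}

#' Classify pedigrees and summarize a screen
#'
#' Reproduces the screen-level bookkeeping: a pedigree is *affected* when
#' at least `min_affected` of its scored G3 mice are affected; an affected
#' pedigree is *mapped* when its mapping result contains at least one
#' Bonferroni-significant allele. A mapped pedigree counts once; the
#' minimal-p significant allele labels the locus and fixes the
#' recessive/dominant attribution (co-segregating passengers remain listed
#' in the mapping result). For mapped-recessive pedigrees the HOM
#' penetrance at the labeling allele is recorded. Percentages are reported
#' half-up at one decimal.
#'
#' @param pedigrees List of scored `enu_pedigree`.
#' @param results List of [map_pedigree()] results parallel to
#'   `pedigrees` (entries may be `NULL` for pedigrees that were not
#'   mapped, e.g. unaffected ones).
#' @param min_affected Affected-mouse threshold defining an affected
#'   pedigree.
#' @return A `screen_summary` list; see fields in the examples.
#' @export
classify_pedigrees <- function(pedigrees, results = NULL, min_affected = 2) {
  n_total <- length(pedigrees)
  if (n_total == 0L) {
    warning("empty screen: all counts zero")
    return(structure(list(
      n_pedigrees = 0L, n_affected = 0L, pct_affected = 0,
      n_mapped = 0L, pct_mapped = 0, n_mapped_recessive = 0L,
      n_mapped_dominant = 0L, n_recessive_penetrant = 0L,
      pct_recessive_penetrant = 0, affected_counts_mapped = integer(0),
      affected_counts_unmapped = integer(0),
      mapped = data.frame()), class = "screen_summary"))
  }
  if (is.null(results)) results <- vector("list", n_total)
  stopifnot(length(results) == n_total)

  n_aff_mice <- vapply(pedigrees, function(p) {
    sum(p$mice$generation == "G3" & p$mice$phenotype == "affected")
  }, integer(1))
  is_affected <- n_aff_mice >= min_affected

  mapped_rows <- list()
  is_mapped <- logical(n_total)
  for (k in which(is_affected)) {
    res <- results[[k]]
    if (is.null(res) || nrow(res$significant) == 0L) next
    is_mapped[k] <- TRUE
    sig <- res$significant
    top <- sig[which.min(sig$p), ]
    pen <- if (top$model == "recessive") {
      penetrance(pedigrees[[k]], top$allele_id, "HOM")
    } else {
      penetrance(pedigrees[[k]], top$allele_id, "HET")
    }
    mapped_rows[[length(mapped_rows) + 1L]] <- data.frame(
      pedigree_id = pedigrees[[k]]$pedigree_id, allele_id = top$allele_id,
      chrom = top$chrom, pos_cM = top$pos_cM, model = top$model,
      p = top$p, n_significant = nrow(sig), penetrance = pen$fraction,
      pen_affected = pen$n_affected, pen_scored = pen$n_scored,
      n_affected_mice = n_aff_mice[k], stringsAsFactors = FALSE
    )
  }
  mapped <- if (length(mapped_rows)) do.call(rbind, mapped_rows) else
    data.frame(model = character(0), penetrance = numeric(0))

  n_affected <- sum(is_affected)
  n_mapped <- sum(is_mapped)
  rec <- mapped[mapped$model == "recessive", , drop = FALSE]
  pen_dist <- if (nrow(rec)) {
    penetrance_distribution(rec$penetrance)
  } else list(n_total = 0L, n_ge = 0L, fraction = NaN, pct = NA_real_)

  structure(list(
    n_pedigrees = n_total,
    n_affected = n_affected,
    pct_affected = percent_round(n_affected, n_total, 1),
    n_mapped = n_mapped,
    pct_mapped = percent_round(n_mapped, n_affected, 1),
    n_mapped_recessive = sum(mapped$model == "recessive"),
    n_mapped_dominant = sum(mapped$model == "dominant"),
    n_recessive_penetrant = pen_dist$n_ge,
    pct_recessive_penetrant = pen_dist$pct,
    affected_counts_mapped = n_aff_mice[is_affected & is_mapped],
    affected_counts_unmapped = n_aff_mice[is_affected & !is_mapped],
    mapped = mapped
  ), class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("<screen_summary: %d pedigrees>\n", x$n_pedigrees))
  cat(sprintf("  affected (>=2 affected mice): %d (%.1f%%)\n",
              x$n_affected, x$pct_affected))
  cat(sprintf("  mapped: %d (%.1f%% of affected); %d recessive, %d dominant\n",
              x$n_mapped, x$pct_mapped, x$n_mapped_recessive, x$n_mapped_dominant))
  if (x$n_mapped_recessive > 0) {
    cat(sprintf("  mapped-recessive with penetrance >= 0.8: %d/%d (%.0f%%)\n",
                x$n_recessive_penetrant, x$n_mapped_recessive,
                x$pct_recessive_penetrant))
  }
  invisible(x)
}

#' Fraction of pedigrees with penetrance at or above a threshold
#'
#' @param penetrances Numeric vector of per-pedigree penetrance fractions;
#'   undefined (`NaN`/`NA`) entries are excluded with a warning.
#' @param threshold Inclusive penetrance cutoff.
#' @return List: `n_total`, `n_ge`, `fraction`, and `pct` (half-up at zero
#'   decimals, the precision penetrance percentages are printed at).
#' @export
penetrance_distribution <- function(penetrances, threshold = 0.8) {
  bad <- !is.finite(penetrances)
  if (any(bad)) {
    warning(sum(bad), " pedigree(s) with undefined penetrance excluded")
    penetrances <- penetrances[!bad]
  }
  n <- length(penetrances)
  n_ge <- sum(penetrances >= threshold)
  list(n_total = n, n_ge = n_ge,
       fraction = if (n) n_ge / n else NaN,
       pct = if (n) percent_round(n_ge, n, 0) else NA_real_)
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Compares per-pedigree counts (e.g. affected mice in mapped vs unmapped
#' pedigrees). Mid-ranks handle ties; the two-sided p-value is exact by
#' enumeration when the combined sample size is at most 25 and there are
#' no ties, otherwise a tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param a,b Non-empty numeric vectors.
#' @return A `wilcoxon_result`: `statistic` (rank sum of group `a`), `p`,
#'   `method`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b)) <= 25 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  structure(list(
    statistic = unname(ht$statistic) + length(a) * (length(a) + 1) / 2,
    p = min(ht$p.value, 1),
    method = if (exact) "exact" else "normal-approximation"
  ), class = "wilcoxon_result")
}

#' Saturation counting over a screen-wide allele table
#'
#' Counts genes interrogated by damaging variation in the genotype state
#' that matters: a gene is covered when at least one of its alleles has a
#' damaging predicted-effect class and was examined in at least `min_hom`
#' homozygous G3 mice. The returned fraction is coverage over a stated
#' gene universe.
#'
#' @param allele_table Data frame with columns `gene_id`, `effect_class`,
#'   `n_hom` (homozygous G3 mice examined).
#' @param universe_size Number of genes in the universe (>= distinct genes
#'   observed).
#' @param damaging_classes Effect classes counted as damaging.
#' @param min_hom Minimum homozygotes examined.
#' @return List: `n_genes_covered`, `universe_size`, `fraction`.
#' @export
saturation_count <- function(allele_table, universe_size,
                             damaging_classes = c("probably_damaging",
                                                  "possibly_damaging",
                                                  "putative_null"),
                             min_hom = 2) {
  n_distinct <- length(unique(allele_table$gene_id))
  if (universe_size < n_distinct) {
    stop("gene universe (", universe_size, ") smaller than observed gene set (",
         n_distinct, ")")
  }
  hit <- allele_table$effect_class %in% damaging_classes &
    allele_table$n_hom >= min_hom
  n_cov <- length(unique(allele_table$gene_id[hit]))
  list(n_genes_covered = n_cov, universe_size = universe_size,
       fraction = if (universe_size > 0) n_cov / universe_size else 0)
}

#' Screen-wide allele table for saturation counting
#'
#' Tallies, per allele, the number of scored homozygous G3 mice across the
#' screen's pedigrees.
#'
#' @param pedigrees List of scored `enu_pedigree`.
#' @return Data frame (`gene_id`, `effect_class`, `n_hom`), one row per
#'   allele.
#' @export
screen_allele_table <- function(pedigrees) {
  rows <- lapply(pedigrees, function(p) {
    idx <- scored_g3(p)
    geno <- p$genotypes[p$mice$mouse_id[idx], , drop = FALSE]
    data.frame(gene_id = p$alleles$gene_id,
               effect_class = p$alleles$effect_class,
               n_hom = colSums(geno == "HOM"),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Mapping power over a penetrance x cohort-size grid
#'
#' For each grid point, simulates pedigrees with one planted recessive
#' causal allele at the given HOM penetrance and cohort structure, runs
#' [map_pedigree()], and scores a success when the causal allele — or a
#' passenger within `window_cM` on the same chromosome — is Bonferroni
#' significant. Reports the Monte-Carlo success fraction and its standard
#' error.
#'
#' @param penetrance_grid Numeric vector of HOM penetrances.
#' @param n_dams_grid Integer vector of G2 dam counts (litters drawn from
#'   `config$litter_range`, so cohort size scales with dams).
#' @param replicates Replicates per grid point (>= 1).
#' @param config A [sim_config()]; `causal_fraction` is ignored (every
#'   replicate is causal).
#' @param seed Top-level seed; each grid point and replicate derives its
#'   own substream.
#' @param window_cM Linkage window crediting passengers of the causal
#'   locus.
#' @return Data frame: `penetrance`, `n_dams`, `mean_scored`,
#'   `mapping_probability`, `mc_se`, `replicates`.
#' @export
power_curve <- function(penetrance_grid, n_dams_grid = 3, replicates = 50,
                        config = sim_config(), seed = 1, window_cM = 5) {
  stopifnot(replicates >= 1)
  grid <- expand.grid(penetrance = penetrance_grid, n_dams = n_dams_grid,
                      KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hits <- logical(replicates)
    scored <- integer(replicates)
    for (r in seq_len(replicates)) {
      set.seed(pedigree_seed(seed + 7919 * g, r))
      ped <- simulate_causal_pedigree(grid$penetrance[g], config,
                                      n_dams = grid$n_dams[g])
      res <- map_pedigree(ped, config$alpha, config$models,
                          config$per_model_bonferroni)
      hits[r] <- causal_flagged(res, ped, window_cM)
      scored[r] <- res$n_scored
    }
    phat <- mean(hits)
    out[[g]] <- data.frame(
      penetrance = grid$penetrance[g], n_dams = grid$n_dams[g],
      mean_scored = mean(scored), mapping_probability = phat,
      mc_se = sqrt(phat * (1 - phat) / replicates), replicates = replicates
    )
  }
  do.call(rbind, out)
}

# One pedigree with a planted recessive causal allele (internal to
# power_curve and the acceptance checks).
simulate_causal_pedigree <- function(penetrance_hom, config = sim_config(),
                                     n_dams = config$n_dams,
                                     pedigree_id = "POW") {
  panel <- generate_allele_panel(config$n_alleles, config$effect_weights,
                                 config$map, prefix = paste0(pedigree_id, "_A"))
  idx <- sample.int(nrow(panel), 1)
  panel$causal[idx] <- TRUE
  model <- phenotype_model(panel$allele_id[idx], c(0, 0, penetrance_hom),
                           config$background, config$lethality)
  ped <- breed_pedigree(panel, config$map, n_dams,
                        litter_range = config$litter_range,
                        pedigree_id = pedigree_id, model = model)
  assign_phenotypes(ped)
}

# Success rule: causal allele or a same-chromosome passenger within
# window_cM is significant.
causal_flagged <- function(result, pedigree, window_cM = 5) {
  causal <- pedigree$model$causal_allele
  if (is.null(causal)) return(FALSE)
  sig <- result$significant
  if (nrow(sig) == 0L) return(FALSE)
  at <- pedigree$alleles[pedigree$alleles$allele_id == causal, ]
  any(sig$chrom == at$chrom & abs(sig$pos_cM - at$pos_cM) <= window_cM)
}
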