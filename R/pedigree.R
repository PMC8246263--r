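GENOTYPE_LEVELS <- c("REF", "HET", "HOM", "MISSING")
PHENOTYPE_LEVELS <- c("affected", "unaffected", "unscored")

#' Phenotype model for a pedigree
#'
#' Penetrance is the probability that a live G3 mouse of a given genotype at
#' the causal allele is scored affected. A recessive model has
#' `het == ref`, a dominant model `het == hom`. The background rate models
#' false-positive radiographic calls in mice whose genotype confers no
#' risk; each mouse is affected with probability
#' `max(background, penetrance[genotype])`. Homozygotes at the causal
#' allele die before scoring with probability `lethality` and are recorded
#' unscored.
#'
#' @param causal_allele Allele id of the causal ENU allele, or `NULL` for a
#'   null pedigree.
#' @param penetrance Numeric triple `(ref, het, hom)` in `[0, 1]`.
#' @param background Background affected probability in `[0, 1]`.
#' @param lethality Pre-scoring death probability for causal homozygotes.
#' @return A `phenotype_model` list.
#' @export
phenotype_model <- function(causal_allele = NULL,
                            penetrance = c(ref = 0, het = 0, hom = 0),
                            background = 0.005,
                            lethality = 0) {
  penetrance <- as.numeric(penetrance)
  if (length(penetrance) != 3L) stop("`penetrance` must be a (ref, het, hom) triple")
  probs <- c(penetrance, background, lethality)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  structure(
    list(causal_allele = causal_allele,
         penetrance = stats::setNames(penetrance, c("REF", "HET", "HOM")),
         background = background,
         lethality = lethality),
    class = "phenotype_model"
  )
}

#' Assemble a pedigree object from its component tables
#'
#' The pedigree is one G1 sire's family: the sire (heterozygous at every
#' panel allele), his G2 daughters by wild-type dams, and the G3 cohort
#' from G2 x G1 backcrosses. Cross-validates parentage and genotype
#' coverage.
#'
#' @param pedigree_id Pedigree label.
#' @param alleles Allele panel data frame (see [generate_allele_panel()];
#'   a `causal` column is optional).
#' @param mice Data frame with columns `mouse_id`, `generation` (G1/G2/G3),
#'   `sex` (M/F), `sire_id`, `dam_id` (NA for founders), `phenotype`
#'   (affected/unaffected/unscored), `alive` (logical; optional, default
#'   `TRUE`).
#' @param genotypes Character matrix `mice x alleles` over
#'   REF/HET/HOM/MISSING, with mouse ids as rownames and allele ids as
#'   colnames.
#' @param model A [phenotype_model()] (simulation truth; optional).
#' @return An `enu_pedigree` object.
#' @export
new_pedigree <- function(pedigree_id, alleles, mice, genotypes,
                         model = phenotype_model()) {
  if (anyDuplicated(alleles$allele_id)) stop("allele ids must be unique within a pedigree")
  if (anyDuplicated(mice$mouse_id)) stop("mouse ids must be unique")
  if (is.null(mice$alive)) mice$alive <- TRUE
  if (!all(mice$generation %in% c("G1", "G2", "G3"))) {
    stop("generation must be one of G1, G2, G3")
  }
  if (!all(mice$phenotype %in% PHENOTYPE_LEVELS)) {
    stop("phenotype must be one of ", paste(PHENOTYPE_LEVELS, collapse = ", "))
  }
  if (!identical(sort(rownames(genotypes)), sort(mice$mouse_id)) ||
      !identical(sort(colnames(genotypes)), sort(alleles$allele_id))) {
    stop("genotype matrix must cover exactly the pedigree's mice and alleles")
  }
  if (!all(genotypes %in% GENOTYPE_LEVELS)) {
    stop("illegal genotype symbol; allowed: ", paste(GENOTYPE_LEVELS, collapse = ", "))
  }
  genotypes <- genotypes[mice$mouse_id, alleles$allele_id, drop = FALSE]
  g3 <- mice$generation == "G3"
  known_parents <- c(NA, mice$mouse_id)
  if (!all(mice$sire_id %in% known_parents) || !all(mice$dam_id %in% known_parents)) {
    stop("parentage not closed: sire or dam id not among pedigree mice")
  }
  if (any(genotypes[mice$mouse_id[!g3], , drop = FALSE] == "HOM")) {
    stop("HOM genotypes may occur only in G3 (G1/G2 have a wild-type parent)")
  }
  structure(
    list(pedigree_id = pedigree_id, alleles = alleles, mice = mice,
         genotypes = genotypes, model = model),
    class = "enu_pedigree"
  )
}

#' @export
print.enu_pedigree <- function(x, ...) {
  tab <- table(factor(x$mice$generation, c("G1", "G2", "G3")))
  scored <- sum(x$mice$generation == "G3" &
                  x$mice$phenotype %in% c("affected", "unaffected"))
  aff <- sum(x$mice$phenotype == "affected")
  cat(sprintf("<enu_pedigree %s: %d alleles; G1=%d G2=%d G3=%d; %d scored, %d affected%s>\n",
              x$pedigree_id, nrow(x$alleles), tab[["G1"]], tab[["G2"]], tab[["G3"]],
              scored, aff,
              if (is.null(x$model$causal_allele)) "; null"
              else paste0("; causal ", x$model$causal_allele)))
  invisible(x)
}

#' Breed one screening pedigree
#'
#' Implements the screen's cross: the G1 sire is heterozygous at every
#' panel allele (all mutations in cis, inherited on one gamete from the
#' mutagenized G0); each G2 daughter receives one sire gamete simulated by
#' [simulate_gamete()] plus a wild-type maternal gamete (so G2 genotypes
#' are REF or HET); each G3 pup combines one gamete from its G2 dam with
#' one from the G1 sire, so homozygotes first appear in G3 and genotype
#' frequencies follow Mendelian backcross expectations.
#'
#' Phenotypes are left `unscored`; see [assign_phenotypes()].
#' Consumes the current R random stream.
#'
#' @param panel Allele panel data frame (see [generate_allele_panel()]).
#' @param map A [genetic_map()].
#' @param n_dams Number of G2 daughters (>= 1).
#' @param litter_sizes Integer vector of G3 litter sizes, one per dam;
#'   default samples each uniformly from `litter_range`.
#' @param litter_range Inclusive range litters default to.
#' @param pedigree_id Pedigree label.
#' @param model A [phenotype_model()] to attach.
#' @return An `enu_pedigree`.
#' @export
breed_pedigree <- function(panel, map = default_mouse_map(), n_dams = 6,
                           litter_sizes = NULL, litter_range = c(6, 8),
                           pedigree_id = "PED1",
                           model = phenotype_model()) {
  stopifnot(n_dams >= 1, nrow(panel) >= 1)
  if (is.null(litter_sizes)) {
    sizes <- seq(litter_range[1], litter_range[2])
    litter_sizes <- sizes[sample.int(length(sizes), n_dams, replace = TRUE)]
  }
  if (length(litter_sizes) != n_dams || any(litter_sizes < 1)) {
    stop("`litter_sizes` must give a positive count per dam")
  }
  loci <- panel[, c("chrom", "pos_cM")]
  n_al <- nrow(panel)
  sire_id <- paste0(pedigree_id, "_G1M")
  dam_ids <- sprintf("%s_G2F%02d", pedigree_id, seq_len(n_dams))
  n_g3 <- sum(litter_sizes)
  g3_ids <- sprintf("%s_G3_%03d", pedigree_id, seq_len(n_g3))

  geno <- matrix("REF", nrow = 1 + n_dams + n_g3, ncol = n_al,
                 dimnames = list(c(sire_id, dam_ids, g3_ids), panel$allele_id))
  geno[sire_id, ] <- "HET"
  dam_het <- matrix(FALSE, n_dams, n_al)
  for (k in seq_len(n_dams)) {
    dam_het[k, ] <- simulate_gamete(loci, map)
    geno[dam_ids[k], dam_het[k, ]] <- "HET"
  }
  g3_dam <- rep(seq_len(n_dams), litter_sizes)
  for (j in seq_len(n_g3)) {
    from_dam <- simulate_gamete(loci, map) & dam_het[g3_dam[j], ]
    from_sire <- simulate_gamete(loci, map)
    geno[g3_ids[j], ] <- c("REF", "HET", "HOM")[from_dam + from_sire + 1L]
  }

  mice <- data.frame(
    mouse_id = c(sire_id, dam_ids, g3_ids),
    generation = c("G1", rep("G2", n_dams), rep("G3", n_g3)),
    sex = c("M", rep("F", n_dams),
            sample(c("M", "F"), n_g3, replace = TRUE)),
    sire_id = c(NA, rep(NA, n_dams), rep(sire_id, n_g3)),
    dam_id = c(NA, rep(NA, n_dams), dam_ids[g3_dam]),
    phenotype = "unscored",
    alive = TRUE,
    stringsAsFactors = FALSE
  )
  new_pedigree(pedigree_id, panel, mice, geno, model)
}

#' Score phenotypes in a pedigree
#'
#' Applies the pedigree's [phenotype_model()] to the G3 cohort: causal
#' homozygotes are first removed (died before scoring) with the configured
#' lethality probability; each remaining live G3 mouse is scored affected
#' with probability `max(background, penetrance[genotype at causal])`
#' (background alone in null pedigrees). G1 and G2 mice stay unscored —
#' only G3 mice are screened.
#'
#' Consumes the current R random stream.
#'
#' @param pedigree An `enu_pedigree` with complete genotypes.
#' @return The pedigree with `phenotype` and `alive` filled for G3 mice.
#' @export
assign_phenotypes <- function(pedigree) {
  stopifnot(inherits(pedigree, "enu_pedigree"))
  model <- pedigree$model
  g3 <- which(pedigree$mice$generation == "G3")
  if (length(g3) == 0L) return(pedigree)
  p_aff <- rep(model$background, length(g3))
  if (!is.null(model$causal_allele)) {
    gt <- pedigree$genotypes[pedigree$mice$mouse_id[g3], model$causal_allele]
    if (model$lethality > 0) {
      dies <- gt == "HOM" & stats::runif(length(g3)) < model$lethality
      pedigree$mice$alive[g3][dies] <- FALSE
    }
    pen <- model$penetrance[gt]
    pen[gt == "MISSING"] <- 0
    p_aff <- pmax(p_aff, pen)
  }
  live <- pedigree$mice$alive[g3]
  scored <- ifelse(stats::runif(length(g3)) < p_aff, "affected", "unaffected")
  pedigree$mice$phenotype[g3] <- ifelse(live, scored, "unscored")
  pedigree
}

# Scored G3 cohort: indices into pedigree$mice
scored_g3 <- function(pedigree) {
  which(pedigree$mice$generation == "G3" &
          pedigree$mice$phenotype %in% c("affected", "unaffected"))
}
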