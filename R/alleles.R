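#' Predicted-effect classes for ENU alleles
#'
#' The damage annotation mirrors what exome sequencing plus effect
#' prediction (PolyPhen-style) reports for ENU-induced point mutations.
#'
#' @export
enu_effect_classes <- c("probably_damaging", "possibly_damaging", "benign",
                        "putative_null", "synonymous")

#' Default effect-class weights
#'
#' Simulation default for the multinomial mix of predicted effects among
#' transmitted nonsynonymous/synonymous ENU variants in a G1 sire's exome:
#' mostly benign missense and synonymous calls, a minority predicted
#' damaging, few outright nulls. A modeling choice, not measured data.
#'
#' @return Named probability vector over [enu_effect_classes].
#' @export
default_effect_weights <- function() {
  c(probably_damaging = 0.15, possibly_damaging = 0.12, benign = 0.38,
    putative_null = 0.05, synonymous = 0.30)
}

#' Generate a G1 sire's ENU allele panel
#'
#' Models the allele set that exome sequencing reveals in one G1 male:
#' `n` point mutations at loci uniform over the genetic map (chromosome
#' chosen proportional to its cM length), each in its own gene, with
#' predicted-effect classes drawn from `weights`.
#'
#' @param n Number of alleles (>= 1).
#' @param weights Named probability vector over [enu_effect_classes];
#'   must sum to 1 (tolerance 1e-6).
#' @param map A [genetic_map()].
#' @param prefix Label prefix for allele and gene ids.
#' @return Data frame with columns `allele_id`, `gene_id`, `chrom`,
#'   `pos_cM`, `effect_class`, `causal` (all `FALSE`; simulation truth is
#'   set by the screen simulator and hidden from mapping).
#' @export
generate_allele_panel <- function(n, weights = default_effect_weights(),
                                  map = default_mouse_map(),
                                  prefix = "A") {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer count")
  }
  if (is.null(names(weights)) || !setequal(names(weights), enu_effect_classes)) {
    stop("`weights` must be named by the five effect classes")
  }
  weights <- weights[enu_effect_classes]
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-6) {
    stop("`weights` must be non-negative and sum to 1")
  }
  stopifnot(inherits(map, "genetic_map"))
  chrom_idx <- sample.int(nrow(map), n, replace = TRUE,
                          prob = map$length_cM / sum(map$length_cM))
  pos <- stats::runif(n, 0, map$length_cM[chrom_idx])
  cls <- sample(enu_effect_classes, n, replace = TRUE, prob = weights)
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  data.frame(
    allele_id = ids,
    gene_id = sprintf("gene_%s", ids),
    chrom = map$chrom[chrom_idx],
    pos_cM = pos,
    effect_class = cls,
    causal = FALSE,
    stringsAsFactors = FALSE
  )
}
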