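#' Simulation configuration for a screen
#'
#' Bundles every tunable of the synthetic screen. Defaults are the
#' package's modeling choices for a spine-deformity-style radiographic
#' screen; see the methods vignette for the rationale behind each.
#'
#' @param map A [genetic_map()].
#' @param n_alleles ENU alleles per pedigree (exome panel size).
#' @param effect_weights Named weights over [enu_effect_classes].
#' @param n_dams G2 daughters per pedigree.
#' @param litter_range Inclusive range of G3 litter sizes per dam.
#' @param causal_fraction Fraction of pedigrees carrying a causal allele.
#' @param dominant_fraction Among causal pedigrees, fraction with a
#'   dominant (rather than recessive) phenotype model.
#' @param penetrance_dist Function `n -> n` penetrance draws in `[0, 1]`
#'   for causal genotypes (HOM for recessive, HET and HOM for dominant).
#' @param background Background affected rate (false-positive calls).
#' @param lethality Pre-scoring death probability of causal homozygotes.
#' @param alpha Pedigree-wise significance level for mapping.
#' @param models Inheritance models used for significance calling.
#' @param per_model_bonferroni If `TRUE`, the Bonferroni denominator is
#'   alleles x models rather than alleles.
#' @return A `sim_config` list.
#' @export
sim_config <- function(map = default_mouse_map(),
                       n_alleles = 60,
                       effect_weights = default_effect_weights(),
                       n_dams = 6,
                       litter_range = c(6, 8),
                       causal_fraction = 0.1,
                       dominant_fraction = 0.05,
                       penetrance_dist = function(n) stats::rbeta(n, 5, 2),
                       background = 0.005,
                       lethality = 0,
                       alpha = 0.05,
                       models = c("recessive", "dominant"),
                       per_model_bonferroni = FALSE) {
  probs <- c(causal_fraction, dominant_fraction, background, lethality)
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must lie in [0, 1]")
  stopifnot(inherits(map, "genetic_map"), n_alleles >= 1, n_dams >= 1,
            is.function(penetrance_dist), alpha > 0, alpha < 1)
  structure(
    list(map = map, n_alleles = as.integer(n_alleles),
         effect_weights = effect_weights, n_dams = as.integer(n_dams),
         litter_range = litter_range, causal_fraction = causal_fraction,
         dominant_fraction = dominant_fraction,
         penetrance_dist = penetrance_dist, background = background,
         lethality = lethality, alpha = alpha, models = models,
         per_model_bonferroni = per_model_bonferroni),
    class = "sim_config"
  )
}

#' Read a simulation configuration from YAML
#'
#' Recognized keys mirror the [sim_config()] arguments; `map_file` points
#' to a genetic-map TSV and `penetrance` is either a fixed value
#' (`{value: 0.9}`) or a Beta law (`{dist: beta, shape1: 5, shape2: 2}`).
#' Unspecified keys keep the package defaults.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$map_file)) args$map <- read_genetic_map(raw$map_file)
  for (key in c("n_alleles", "n_dams", "causal_fraction", "dominant_fraction",
                "background", "lethality", "alpha", "models",
                "per_model_bonferroni", "litter_range")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  if (!is.null(raw$effect_weights)) args$effect_weights <- unlist(raw$effect_weights)
  if (!is.null(raw$penetrance)) {
    pen <- raw$penetrance
    if (!is.null(pen$value)) {
      v <- pen$value
      args$penetrance_dist <- function(n) rep(v, n)
    } else if (identical(pen$dist, "beta")) {
      s1 <- pen$shape1; s2 <- pen$shape2
      args$penetrance_dist <- function(n) stats::rbeta(n, s1, s2)
    } else {
      stop("unrecognized penetrance specification in ", path)
    }
  }
  do.call(sim_config, args)
}

# Deterministic per-pedigree substream seed: pedigree k under top seed s is
# reproducible regardless of how many pedigrees are simulated.
pedigree_seed <- function(seed, k) {
  (((seed %% 2147483647) * 2654435761 + k * 40503) %% 2147483629) + 1
}

#' Simulate a whole screen of independent pedigrees
#'
#' Each pedigree draws its own allele panel and breeding realization. With
#' probability `causal_fraction` one panel allele (re-labeled to a damaging
#' effect class) is made causal: recessive pedigrees get penetrance
#' `(0, 0, f)`, dominant ones `(0, f, f)`, with `f` drawn from the
#' configured penetrance distribution. Remaining pedigrees are null —
#' affected calls arise only from the background rate. Pedigree `k` uses a
#' substream derived from `seed` and `k`, so it is reproducible
#' independently of `n`.
#'
#' @param n Number of pedigrees (0 allowed).
#' @param config A [sim_config()].
#' @param seed Integer top-level seed.
#' @return List of `enu_pedigree` with attribute `truth`: a data frame
#'   (`pedigree_id`, `causal_allele`, `mode`, `penetrance_hom`).
#' @export
simulate_screen <- function(n, config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"), n >= 0)
  peds <- vector("list", n)
  truth <- data.frame(pedigree_id = character(n),
                      causal_allele = rep(NA_character_, n),
                      mode = rep(NA_character_, n),
                      penetrance_hom = rep(NA_real_, n),
                      stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    set.seed(pedigree_seed(seed, k))
    pid <- sprintf("P%04d", k)
    panel <- generate_allele_panel(config$n_alleles, config$effect_weights,
                                   config$map, prefix = paste0(pid, "_A"))
    model <- phenotype_model(background = config$background)
    if (stats::runif(1) < config$causal_fraction) {
      idx <- sample.int(nrow(panel), 1)
      panel$causal[idx] <- TRUE
      # a causal allele is by construction function-altering
      if (panel$effect_class[idx] %in% c("benign", "synonymous")) {
        panel$effect_class[idx] <- "probably_damaging"
      }
      f <- min(max(config$penetrance_dist(1), 0), 1)
      dominant <- stats::runif(1) < config$dominant_fraction
      pen <- if (dominant) c(0, f, f) else c(0, 0, f)
      model <- phenotype_model(panel$allele_id[idx], pen,
                               config$background, config$lethality)
      truth$causal_allele[k] <- panel$allele_id[idx]
      truth$mode[k] <- if (dominant) "dominant" else "recessive"
      truth$penetrance_hom[k] <- f
    }
    ped <- breed_pedigree(panel, config$map, config$n_dams,
                          litter_range = config$litter_range,
                          pedigree_id = pid, model = model)
    peds[[k]] <- assign_phenotypes(ped)
    truth$pedigree_id[k] <- pid
  }
  attr(peds, "truth") <- truth
  peds
}

#' Map every pedigree of a screen
#'
#' @param pedigrees List of scored `enu_pedigree`.
#' @param config A [sim_config()] supplying `alpha`, `models` and the
#'   Bonferroni convention.
#' @return List of [map_pedigree()] results, named by pedigree id.
#' @export
map_screen <- function(pedigrees, config = sim_config()) {
  res <- lapply(pedigrees, map_pedigree, alpha = config$alpha,
                models = config$models,
                per_model_bonferroni = config$per_model_bonferroni)
  names(res) <- vapply(pedigrees, function(p) p$pedigree_id, character(1))
  res
}
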