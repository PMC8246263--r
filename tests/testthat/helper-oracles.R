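# Independent oracles and small fixture builders shared across the suite.
# The oracles deliberately avoid the package's fitting code paths.

tiny_map <- function() genetic_map(c("chr1", "chr2"), c(100, 80))

# Maximum-likelihood logistic fit by quasi-Newton optimisation from
# several starts, with standard errors from the numerical Hessian.
ml_logistic_oracle <- function(y, x) {
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    -sum(y * eta - log1p(exp(eta)))
  }
  best <- NULL
  for (s in list(c(0, 0), c(1, -1), c(-2, 2), c(2, 0.5))) {
    o <- optim(s, nll, method = "BFGS", hessian = TRUE,
               control = list(reltol = 1e-14, maxit = 500))
    if (is.null(best) || o$value < best$value) best <- o
  }
  se <- sqrt(diag(solve(best$hessian)))
  list(intercept = best$par[1], coef = best$par[2], se = se[2])
}

firth_pen_ll <- function(b0, b1, y, x) {
  eta <- b0 + b1 * x
  p <- plogis(eta)
  w <- p * (1 - p)
  X <- cbind(1, x)
  info <- crossprod(X * w, X)
  sum(y * eta - log1p(exp(eta))) + 0.5 * log(det(info))
}

# Firth-penalized likelihood maximized by coarse-to-fine grid search;
# standard error from a central-difference Hessian at the optimum.
firth_grid_oracle <- function(y, x) {
  g <- expand.grid(b0 = seq(-8, 8, length.out = 120),
                   b1 = seq(-12, 12, length.out = 120))
  g$v <- mapply(firth_pen_ll, g$b0, g$b1, MoreArgs = list(y = y, x = x))
  top <- g[which.max(g$v), ]
  span <- 0.4
  for (it in 1:7) {
    g <- expand.grid(b0 = seq(top$b0 - span, top$b0 + span, length.out = 60),
                     b1 = seq(top$b1 - span, top$b1 + span, length.out = 60))
    g$v <- mapply(firth_pen_ll, g$b0, g$b1, MoreArgs = list(y = y, x = x))
    top <- g[which.max(g$v), ]
    span <- span / 4
  }
  # Wald standard error convention: inverse Fisher information evaluated
  # at the penalized estimate (same definition the package documents)
  eta <- top$b0 + top$b1 * x
  p <- plogis(eta)
  w <- p * (1 - p)
  X <- cbind(1, x)
  se <- sqrt(diag(solve(crossprod(X * w, X))))
  list(intercept = top$b0, coef = top$b1, se = unname(se[2]))
}

# Exact two-sided rank-sum p by full enumeration of which ranks belong to
# group a; two-sided p doubles the smaller tail (capped at 1), matching
# the usual exact convention.
perm_wilcoxon_oracle <- function(a, b) {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_along(a)])
  combos <- combn(n, length(a))
  w_null <- apply(combos, 2, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(w_null <= w_obs), mean(w_null >= w_obs)))
}

# Exact probability that a G3 mouse carries discordant genotypes at two
# linked loci d cM apart, by enumeration over the three relevant meioses
# (sire -> dam, dam -> pup, sire -> pup), each an independent fair-coin
# strand pair recombining with Haldane probability r.
two_locus_discordance_oracle <- function(d_cM) {
  r <- 0.5 * (1 - exp(-2 * d_cM / 100))
  pr_pair <- function(b1, b2) if (b1 == b2) (1 - r) / 2 else r / 2
  total <- 0
  for (m1 in 0:1) for (m2 in 0:1)
    for (d1 in 0:1) for (d2 in 0:1)
      for (s1 in 0:1) for (s2 in 0:1) {
        g1 <- (m1 & d1) + s1
        g2 <- (m2 & d2) + s2
        if (g1 != g2) {
          total <- total + pr_pair(m1, m2) * pr_pair(d1, d2) * pr_pair(s1, s2)
        }
      }
  total
}

# A hand-built single-allele pedigree with prescribed scored-G3 genotype
# and phenotype counts, for penetrance and summary arithmetic.
counts_pedigree <- function(n_hom = 0, hom_affected = 0,
                            n_het = 0, het_affected = 0,
                            n_ref = 0, ref_affected = 0,
                            pedigree_id = "FIX") {
  allele <- data.frame(allele_id = "A1", gene_id = "gene_A1", chrom = "chr1",
                       pos_cM = 10, effect_class = "probably_damaging",
                       causal = TRUE, stringsAsFactors = FALSE)
  n_g3 <- n_hom + n_het + n_ref
  g3_gt <- rep(c("HOM", "HET", "REF"), c(n_hom, n_het, n_ref))
  g3_ph <- c(rep(c("affected", "unaffected"), c(hom_affected, n_hom - hom_affected)),
             rep(c("affected", "unaffected"), c(het_affected, n_het - het_affected)),
             rep(c("affected", "unaffected"), c(ref_affected, n_ref - ref_affected)))
  ids <- c("S1", "D1", sprintf("G3_%03d", seq_len(n_g3)))
  mice <- data.frame(
    mouse_id = ids,
    generation = c("G1", "G2", rep("G3", n_g3)),
    sex = c("M", "F", rep("F", n_g3)),
    sire_id = c(NA, NA, rep("S1", n_g3)),
    dam_id = c(NA, NA, rep("D1", n_g3)),
    phenotype = c("unscored", "unscored", g3_ph),
    alive = TRUE, stringsAsFactors = FALSE
  )
  geno <- matrix(c("HET", "HET", g3_gt), ncol = 1,
                 dimnames = list(ids, "A1"))
  new_pedigree(pedigree_id, allele, mice, geno,
               phenotype_model("A1", c(0, 0, 1), background = 0))
}

# Simulate pedigrees with a planted recessive allele until `n_keep` of
# them have at least `min_hom` scored causal homozygotes.
qualifying_causal_pedigrees <- function(n_keep, penetrance_hom, config,
                                        min_hom, seed, max_tries = 10 * n_keep) {
  kept <- vector("list", n_keep)
  found <- 0L
  for (try in seq_len(max_tries)) {
    set.seed(enuscreen:::pedigree_seed(seed, try))
    ped <- enuscreen:::simulate_causal_pedigree(penetrance_hom, config)
    idx <- enuscreen:::scored_g3(ped)
    gt <- ped$genotypes[ped$mice$mouse_id[idx], ped$model$causal_allele]
    if (sum(gt == "HOM") < min_hom) next
    found <- found + 1L
    kept[[found]] <- ped
    if (found == n_keep) break
  }
  kept[seq_len(found)]
}
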