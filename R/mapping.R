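#' Inheritance models for the association test
#'
#' Each model encodes REF/HET/HOM genotypes as a numeric risk predictor:
#' recessive `(0, 0, 1)`, dominant `(0, 1, 1)`, additive `(0, 1, 2)`.
#' Recessive and dominant are the screen's calling models; additive is an
#' optional extension excluded from default significance calling.
#'
#' @param name One of `"recessive"`, `"dominant"`, `"additive"`.
#' @return A list with `name` and the `encoding` map.
#' @export
inheritance_model <- function(name = c("recessive", "dominant", "additive")) {
  name <- match.arg(name)
  encoding <- switch(name,
    recessive = c(REF = 0, HET = 0, HOM = 1),
    dominant  = c(REF = 0, HET = 1, HOM = 1),
    additive  = c(REF = 0, HET = 1, HOM = 2)
  )
  list(name = name, encoding = encoding)
}

#' Encode genotype calls under an inheritance model
#'
#' `MISSING` propagates as `NA`, so the mouse drops out of that allele's
#' test; any other unknown symbol is an error.
#'
#' @param calls Character vector over REF/HET/HOM/MISSING.
#' @param model An [inheritance_model()] or its name.
#' @return Numeric vector with `NA` at missing calls.
#' @export
encode_genotypes <- function(calls, model) {
  if (is.character(model)) model <- inheritance_model(model)
  bad <- setdiff(unique(calls), GENOTYPE_LEVELS)
  if (length(bad)) stop("unknown genotype symbol(s): ", paste(bad, collapse = ", "))
  out <- unname(model$encoding[calls])
  out[calls == "MISSING"] <- NA_real_
  out
}

#' Two-sided Wald p-value
#'
#' Squares the z statistic `coef / se` and refers it to chi-square with one
#' degree of freedom. Clipped below at 1e-300 so -log10(p) stays finite in
#' Manhattan output.
#'
#' @param coef Coefficient estimate(s).
#' @param se Standard error(s), strictly positive.
#' @return p-value(s) in `(0, 1]`.
#' @export
wald_p <- function(coef, se) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("`se` must be finite and positive")
  pmax(stats::pchisq((coef / se)^2, df = 1, lower.tail = FALSE), 1e-300)
}

# Firth (Jeffreys-penalized) logistic regression for intercept + one
# predictor, by Newton iteration with step-halving on the penalized
# log-likelihood. Keeps estimates finite under (quasi-)complete separation.
# Wald standard errors use the inverse Fisher information X'WX evaluated
# at the penalized estimate.
firth_logistic <- function(y, x, max_iter = 100, tol = 1e-10) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  pen_ll <- function(beta) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    info <- crossprod(X * w, X)
    sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(info)$modulus
  }
  ll_old <- pen_ll(beta)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    info <- crossprod(X * w, X)
    inv <- solve(info)
    h <- rowSums((X %*% inv) * X) * w      # leverages of W^1/2 X
    score <- crossprod(X, y - p + h * (0.5 - p))
    step <- drop(inv %*% score)
    for (half in 0:20) {
      cand <- beta + step / 2^half
      ll_new <- pen_ll(cand)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
    }
    moved <- max(abs(cand - beta))
    beta <- cand
    ll_old <- ll_new
    if (moved < tol) break
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  w <- pmax(p * (1 - p), 1e-12)
  se <- sqrt(diag(solve(crossprod(X * w, X))))
  list(intercept = unname(beta[1]), coef = unname(beta[2]),
       se_intercept = unname(se[1]), se = unname(se[2]))
}

#' Logistic regression of a binary phenotype on a genotype encoding
#'
#' Fits phenotype ~ predictor by maximum likelihood (iteratively reweighted
#' least squares via [stats::glm.fit()]). When the fit fails to converge or
#' shows (quasi-)complete separation — inevitable under fully penetrant
#' recessive alleles — it refits with Firth's penalized likelihood and
#' flags `method = "Firth"`, so estimates stay finite and Wald p-values
#' usable. A constant phenotype or constant predictor is a degenerate
#' design: no test is performed and p is recorded as 1.
#'
#' Missing predictor values (MISSING genotypes) are dropped pairwise.
#'
#' @param phenotypes 0/1 (or logical) response vector.
#' @param predictor Numeric encoding from [encode_genotypes()].
#' @return List: `intercept`, `coef`, `se_intercept`, `se`, `p` (Wald, for
#'   the genotype coefficient), `method` (`"IRLS"`, `"Firth"` or
#'   `"degenerate"`), `n`.
#' @export
fit_logistic <- function(phenotypes, predictor) {
  y <- as.numeric(phenotypes)
  x <- as.numeric(predictor)
  if (length(y) != length(x)) stop("`phenotypes` and `predictor` lengths differ")
  keep <- !is.na(y) & !is.na(x)
  y <- y[keep]; x <- x[keep]
  if (!all(y %in% c(0, 1))) stop("`phenotypes` must be binary 0/1")
  degenerate <- list(intercept = NA_real_, coef = 0, se_intercept = NA_real_,
                     se = NA_real_, p = 1, method = "degenerate",
                     n = length(y))
  if (length(y) < 2L || length(unique(y)) < 2L || length(unique(x)) < 2L) {
    return(degenerate)
  }
  X <- cbind(1, x)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial())
  )
  beta <- fit$coefficients
  mu <- fit$fitted.values
  separated <- !fit$converged || any(!is.finite(beta)) ||
    max(abs(beta)) > 12 || any(mu < 1e-8) || any(mu > 1 - 1e-8)
  if (!separated) {
    w <- mu * (1 - mu)
    cov <- solve(crossprod(X * w, X))
    se <- sqrt(diag(cov))
    res <- list(intercept = unname(beta[1]), coef = unname(beta[2]),
                se_intercept = unname(se[1]), se = unname(se[2]),
                method = "IRLS")
  } else {
    res <- c(firth_logistic(y, x), method = "Firth")
  }
  res$p <- if (is.finite(res$se) && res$se > 0) wald_p(res$coef, res$se) else 1
  res$n <- length(y)
  res
}

#' Map a pedigree: per-allele association tests with Bonferroni control
#'
#' The automated meiotic-mapping test: for every ENU allele in the panel
#' and every inheritance model, the binary phenotype of scored G3 mice is
#' regressed on the genotype encoding; significance is assessed by Wald
#' tests against the pedigree-wise Bonferroni threshold
#' `alpha / n_alleles` (the number of ENU alleles tested in the pedigree;
#' optionally `alpha / (n_alleles * n_models)`). An allele is significant
#' when any calling model reaches the threshold.
#'
#' @param pedigree A scored `enu_pedigree`.
#' @param alpha Pedigree-wise significance level in (0, 1).
#' @param models Character vector of [inheritance_model()] names to fit.
#' @param per_model_bonferroni Use the stricter alleles x models
#'   denominator.
#' @return A `mapping_result`: list with `pedigree_id`, `tests` (data
#'   frame, one row per allele x model, ordered by genome position),
#'   `n_alleles`, `alpha`, `threshold`, and `significant` (subset of
#'   `tests`).
#' @export
map_pedigree <- function(pedigree, alpha = 0.05,
                         models = c("recessive", "dominant"),
                         per_model_bonferroni = FALSE) {
  stopifnot(inherits(pedigree, "enu_pedigree"), alpha > 0, alpha < 1)
  cohort <- scored_g3(pedigree)
  if (length(cohort) == 0L) {
    stop("pedigree ", pedigree$pedigree_id, " has no scored G3 mice")
  }
  y <- as.numeric(pedigree$mice$phenotype[cohort] == "affected")
  ids <- pedigree$mice$mouse_id[cohort]
  n_alleles <- nrow(pedigree$alleles)
  threshold <- alpha / (n_alleles * if (per_model_bonferroni) length(models) else 1L)

  rows <- vector("list", n_alleles * length(models))
  i <- 0L
  for (a in seq_len(n_alleles)) {
    calls <- pedigree$genotypes[ids, pedigree$alleles$allele_id[a]]
    counts <- table(factor(calls, GENOTYPE_LEVELS))
    for (m in models) {
      fit <- fit_logistic(y, encode_genotypes(calls, m))
      i <- i + 1L
      rows[[i]] <- data.frame(
        allele_id = pedigree$alleles$allele_id[a],
        chrom = pedigree$alleles$chrom[a],
        pos_cM = pedigree$alleles$pos_cM[a],
        model = m, estimate = fit$coef, se = fit$se, p = fit$p,
        method = fit$method, n_ref = counts[["REF"]],
        n_het = counts[["HET"]], n_hom = counts[["HOM"]],
        n_missing = counts[["MISSING"]],
        stringsAsFactors = FALSE
      )
    }
  }
  tests <- do.call(rbind, rows)
  tests$significant <- tests$p <= threshold & tests$method != "degenerate"
  tests <- tests[order(match(tests$chrom, sort(unique(tests$chrom))),
                       tests$pos_cM, tests$model), ]
  rownames(tests) <- NULL
  structure(
    list(pedigree_id = pedigree$pedigree_id, tests = tests,
         n_alleles = n_alleles, alpha = alpha, threshold = threshold,
         models = models, n_scored = length(cohort),
         n_affected = sum(y),
         significant = tests[tests$significant, , drop = FALSE]),
    class = "mapping_result"
  )
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf("<mapping_result %s: %d alleles x %d models over %d scored G3 (%d affected)>\n",
              x$pedigree_id, x$n_alleles, length(x$models), x$n_scored, x$n_affected))
  cat(sprintf("  Bonferroni threshold %.3g (alpha = %g)\n", x$threshold, x$alpha))
  if (nrow(x$significant)) {
    cat("  significant alleles:\n")
    print(x$significant[, c("allele_id", "chrom", "pos_cM", "model", "p")])
  } else cat("  no significant alleles\n")
  invisible(x)
}

#' Manhattan-plot table for a mapping result
#'
#' One record per allele per model with `-log10(p)` (finite, p clipped at
#' 1e-300), sorted by the map's chromosome order then ascending position.
#'
#' @param result A [map_pedigree()] result.
#' @param map A [genetic_map()] fixing chromosome order.
#' @return Data frame (`chrom`, `pos_cM`, `allele_id`, `model`,
#'   `neg_log10_p`, `significant`).
#' @export
manhattan_table <- function(result, map = default_mouse_map()) {
  stopifnot(inherits(result, "mapping_result"))
  t <- result$tests
  if (nrow(t) == 0L) stop("empty mapping result")
  ord <- order(match(t$chrom, map$chrom), t$pos_cM, t$model)
  t <- t[ord, ]
  data.frame(chrom = t$chrom, pos_cM = t$pos_cM, allele_id = t$allele_id,
             model = t$model, neg_log10_p = -log10(pmax(t$p, 1e-300)),
             significant = t$significant, stringsAsFactors = FALSE,
             row.names = NULL)
}
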