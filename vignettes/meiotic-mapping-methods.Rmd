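---
title: "Models and methods: simulating and mapping an ENU saturation screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and mapping an ENU saturation screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enuscreen)
```

## The screening design

An ENU saturation screen works on pedigrees. A mutagenized G0 male is
outcrossed; one of his sons — the G1 sire — inherits a few dozen
heterozygous ENU point mutations on the single gamete his father
contributed, so all his mutant alleles are in *cis*. The G1 sire is
outcrossed to wild-type females to produce G2 daughters (each REF or HET
at every allele), and the daughters are backcrossed to their own sire.
Homozygotes first appear in the resulting G3 cohort, which is screened
for a binary phenotype. Because only two meioses separate a G3 genotype
from the sire's haplotype, alleles within a few centimorgans co-segregate
strongly; the phenotype therefore maps to a locus by testing each
genotyped ENU allele for association — *automated meiotic mapping* — and
linked passenger alleles are expected to come along with the causal one.

`enuscreen` implements this design end to end: a generative simulator of
the breeding scheme and phenotype scoring, the per-allele association
test, and the screen-level bookkeeping used to report such a screen.

## Meiosis model

Gametes are simulated per chromosome: the transmitted strand starts as a
fair coin, the number of crossovers is Poisson with mean `length_cM/100`,
crossover positions are uniform, and the strand flips at each crossover.
This no-interference model is exactly the assumption under which the
Haldane map function

$$ r(d) = \tfrac12\left(1 - e^{-2d/100}\right) $$

converts distance to recombination fraction, so simulated recombinant
fractions converge to `haldane_rf()` by construction and the two are
mutually consistent (a property the test suite checks by Monte Carlo).
Interference models (e.g. Kosambi) and sex-specific maps are deliberately
out of scope, as are physical (bp) coordinates: every position in the
package is a continuous cM coordinate, 0-based at the chromosome start.

The default map ships in `inst/extdata/mouse_autosome_map.tsv`: 19
autosomes totalling about 1440 cM. The lengths are plausible round values
for the mouse genetic map and are a labelled modeling default, not
measured data; the X is excluded because the screened gene universe is
autosomal and X-linked inheritance is not modeled.

## Simulator defaults and what they emulate

Each tunable lives in `sim_config()`. The defaults were fixed once, to
emulate the statistical shape of a large radiographic spine screen:

* `n_alleles = 60` per pedigree — a placeholder for the panel a G1
  exome reveals; the Bonferroni denominator tracks whatever value is
  used, and no calibration in the package depends on 60.
* `n_dams = 6`, litters of 6–8 — roughly 42 G3 mice per pedigree,
  chosen to match the screen scale of ~54,500 mice over 1275 pedigrees
  (~43 per pedigree). Litter structure itself is not reported anywhere,
  so the dam/litter split is the package's choice.
* `causal_fraction = 0.1`, `dominant_fraction = 0.05` — most pedigrees
  carry no allele capable of producing the phenotype; among those that
  do, recessive alleles dominate (the screen's mapped set was 19
  recessive to 1 dominant).
* HOM penetrance of causal alleles drawn from Beta(5, 2) (mean ≈ 0.71)
  — penetrance varies across alleles, with a majority at or above 0.8,
  mirroring the reported 12/19 mapped-recessive pedigrees at ≥ 80%
  penetrance.
* `background = 0.005` — the false-positive rate of subjective
  radiographic scoring; not quantified in any screen we know of, so a
  small nonzero default.
* `lethality = 0` by default; setting it removes causal homozygotes
  before scoring, modeling perinatal-lethal alleles as a testable
  contrast.
* Effect-class weights (0.15, 0.12, 0.38, 0.05, 0.30) over
  probably/possibly damaging, benign, putative null, synonymous — a
  plausible PolyPhen-style mix for transmitted ENU variants; only the
  damaging-class membership matters downstream (saturation counting).

Sex is assigned fair-coin and carried through the tables but unused by
default; genotype missingness is representable (`MISSING`) but not
generated by default.

What the simulator does **not** emulate: genotyping error and exome
capture false negatives, germline mosaicism, ENU dose–response,
shared-environment or litter effects on phenotype, and any real
correspondence between simulated cM positions and mouse genome
coordinates. Green tests therefore certify the machinery under clean
Mendelian transmission with independent phenotype noise — not robustness
to the artifacts of real genotyping.

## The mapping test

For each allele and each inheritance model (recessive `(0,0,1)`,
dominant `(0,1,1)`, optionally additive `(0,1,2)`), the binary phenotype
of scored G3 mice is regressed on the encoded genotype and the
coefficient is assessed with a two-sided Wald test
(`z^2 ~ chi-square(1)`). The pedigree-wise threshold is Bonferroni:
`alpha / n_alleles`, the number of ENU alleles tested in that pedigree.
Dividing additionally by the number of models is available as a switch
(`per_model_bonferroni`) but off by default, matching the convention of
correcting for alleles only. The additive model is fitted on request but
excluded from default significance calling, since recessive and dominant
are the calling models of record for this design.

Numerical choices:

* **Separation.** A fully penetrant recessive allele with a clean
  background guarantees quasi-complete separation, where the
  maximum-likelihood estimate diverges. `fit_logistic()` first runs IRLS
  (`stats::glm.fit`); if the fit fails to converge, a coefficient
  exceeds 12 on the logit scale, or any fitted probability is within
  1e-8 of 0 or 1, it refits with Firth's Jeffreys-penalized likelihood
  (Newton iteration with step-halving) and flags `method = "Firth"`.
  Wald standard errors use the inverse Fisher information evaluated at
  the estimate, in both branches. Firth-based Wald tests are known to be
  conservative under severe separation; that conservatism is visible in
  the package's power curves and is accepted rather than patched.
* **Degenerate designs.** A constant phenotype (e.g. a pedigree with no
  affected mice) or constant predictor yields no test: the result is
  flagged `degenerate` with p = 1, never significant.
* **Missing genotypes** drop the mouse from that allele's test only.
* **p-value floor.** p is clipped at 1e-300 so `-log10(p)` stays finite
  in Manhattan tables.
* **Tie-breaks.** When several alleles are significant, the pedigree
  counts once and the minimal-p allele labels the locus; co-segregating
  passengers stay listed in the mapping result, because with one or two
  informative recombinants the labeling choice is genuinely ambiguous.

## Screen-level reporting

`classify_pedigrees()` applies the screen's definitions: *affected*
pedigree = at least two affected scored G3 mice; *mapped* = at least one
Bonferroni-significant allele; recessive/dominant attribution follows
the significant model; HOM penetrance is reported for mapped-recessive
pedigrees. Percentages are rounded half away from zero at the precision
screen reports print (one decimal for screen fractions, zero decimals
for penetrance percentages); the raw fractions are always retained.
Half-up rounding makes the worked examples well defined: 94/1275
reports as 7.4% and 20/94 as 21.3%. (Published screen reports print 7.3%
— an apparent truncation — and 20.6%, which matches no obvious
denominator; the package documents its own convention and reports the
recomputed values.)

`wilcoxon_rank_sum()` compares per-pedigree affected counts between
mapped and unmapped groups: mid-ranks for ties, exact enumeration when
the combined sample is ≤ 25 without ties, otherwise a tie-corrected
normal approximation with continuity correction. The exactness cutoff is
a package choice; the original analysis's variant is unknown.

`saturation_count()` implements the coverage rule — a gene counts as
interrogated when a damaging-class allele was examined in at least two
homozygous G3 mice — over a stated gene universe. It deliberately does
not attempt lethality-calibrated saturation estimation, which requires
real exome data and a curated essential-gene collection.

## Power analysis

`power_curve()` plants one recessive causal allele per replicate and
measures how often the causal locus (or a passenger within a
configurable window, default 5 cM) reaches significance. Monte-Carlo
standard errors accompany every estimate. Two regularities the test
suite verifies: power rises with penetrance at fixed cohort size, and
mapped replicates carry systematically more affected mice than unmapped
ones — the same contrast a real screen shows between its mapped and
unmapped pedigrees.

## Problem sizes and reproducibility

Every stochastic routine consumes R's seeded generator; the screen-level
drivers derive a deterministic substream per pedigree from the top-level
seed, so pedigree *k* is reproducible regardless of how many pedigrees
are simulated and outputs are byte-identical across reruns of the same
(config, seed). The shipped analyses use a 150-pedigree screen and
40–200 replicates per power point; calibration checks in the test suite
use 10,000–20,000 meioses for transmission ratios and recombination
fractions and 500 null pedigrees for family-wise error — sizes at which
three-standard-error bands are tight enough to detect real
miscalibration while each check stays a desk-scale computation.

## Known limitations

* Wald-on-Firth p-values are conservative under complete separation;
  small fully penetrant pedigrees near the Bonferroni boundary are
  under-called rather than over-called.
* The exact Wilcoxon path refuses ties; tied data always use the
  corrected normal approximation, which is approximate for tiny groups.
* The simulator's phenotype noise is i.i.d. per mouse; litter or dam
  effects would inflate the false-positive rate of a real screen in a
  way the FWER suite does not probe.
* Genetic-map defaults are stylized; nothing in the package should be
  read as mouse-genome coordinates.
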