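---
title: "Methods: parental allele tracing and IBD-aware genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parental allele tracing and IBD-aware genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdtrace)
```

## Model and assumptions

`ibdtrace` targets inbred, pedigree-recorded plant material: every line is
(nearly) homozygous, every traced line has two recorded parents genotyped
on the same biallelic SNP panel, and marker order is given by a genetic
map.  Under these assumptions parental origin is a deterministic
inference, not a statistical one:

* A SNP where the two parents carry *different homozygous* alleles is an
  **anchor**: the progeny allele identifies its source exactly.  A
  heterozygous or missing parent call makes a marker uninformative
  (ambiguous), not probabilistically informative — we do not model parent
  haplotypes.  A progeny call homozygous for an allele neither parent
  carries is a **conflict** (genotyping or pedigree error) and is excluded
  from anchoring, so one bad call can never seed a false segment.
* Between anchors, origin is constant unless a crossover intervened.  A
  run of non-anchor markers whose nearest anchors on both sides agree is
  therefore imputed to that source, at any distance but never across a
  chromosome boundary.  If the flanking anchors disagree, a recombination
  happened *somewhere* in the run; the run stays ambiguous and is reported
  as a breakpoint *interval*, never a point estimate.  Runs at chromosome
  ends (one-sided anchors) and anchor-free chromosomes stay ambiguous.
* Composition through the pedigree replaces SOURCE(parent) by the parent's
  own label at the same marker, ancestors first, stopping at founders and
  untraced ancestors.  A parent's unresolved (ambiguous or conflicting)
  label propagates as the parent's *self-class*: the child demonstrably
  inherited the physical segment from that parent even if the parent's own
  provenance is unclear.  Self-classes are used only downstream; the
  parent's own row is never rewritten for predicting its own performance.

### Allele effect estimation

For one trait in one environment, with training-line mean `mu`, the allele
effect estimate of ancestral source *j* at a marker is the raw class-mean
deviation `alpha_j = mean(y of carriers of j) - mu`.  Deliberately **no
shrinkage** is applied to `alpha` itself — each estimate is an independent
class mean, and regularization happens later in the ridge step.  The AEE
matrix replaces marker codes: `SOURCE(j) -> alpha_j`,
`AMBIGUOUS(j,k) -> (alpha_j + alpha_k)/2`, missing/conflict and sources
unseen in training map to 0, the neutral deviation, so predictions for
unknown material fall back toward the population mean.  Only training
lines ever contribute to `mu` or `alpha` (the evaluation code refits the
table inside every training split/fold), preventing test-set leakage.

### Ridge-regression BLUP

`ridge_fit()` solves `y = 1*beta + X*u + e` with `u ~ (0, sigma_u^2 I)`,
`e ~ (0, sigma_e^2 I)`.  Columns are centered internally; because the
centered `X X'` annihilates the intercept direction, the GLS intercept
equals the training mean and the BLUP effects equal the closed-form ridge
solution `(Xc'Xc + lambda I)^-1 Xc'(y - ybar)` at the REML optimum of
`lambda = sigma_e^2 / sigma_u^2`.

## Numerical choices

* REML is profiled onto `lambda` through the eigenvalue spectrum of the
  centered cross-product, computed on the cheaper side (`m x m` when
  `m < n`), with the zero-eigenvalue subspace handled in closed form; the
  1-D search runs on `log(lambda)` over `[1e-9, 1e9]` with tolerance
  `1e-8` (`stats::optimize`).  The spectral objective is checked against a
  dense determinant-based restricted likelihood in the tests.
* Raw marker coding is `{0, 1, 2}` dosage with heterozygote = 1; missing
  calls take the column mean (neutral after centering).
* Marker-based heritability is reported as
  `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)` with
  `sigma_g^2 = sigma_u^2 * mean(diag(Xc Xc'))` — the genomic variance on
  the phenotype scale.  No single convention is universal; this one is
  scale-invariant and reduces to the intuitive limits (≈1 for a noiseless
  additive trait, ≈0 for pure noise).
* Ambiguous labels store their two parent ids in sorted order; ties in map
  position are broken by list order, which is authoritative.
* `fit_aee` optionally zeroes alphas from classes smaller than `n_min`
  (default 1 = no threshold, matching the method's original usage).

## Open design points and how they were decided

* **Heterozygous progeny calls** are labeled MISSING rather than traced:
  the material is assumed inbred, so a het call carries no reliable origin
  signal.
* **Conflict handling during imputation**: conflicts are overwritten only
  when both flanking anchors agree (they sit inside an IBD run whose
  provenance is established); otherwise they remain conflicts.
* **Singletons** — one-marker islands whose both source neighbors carry
  the other parent — indicate double crossovers between adjacent markers
  or marker-order/genotyping problems.  They are *reported*
  (`singleton_report()`), never silently removed; `smooth_singletons =
  TRUE` relabels them ambiguous for sensitivity analysis.
* **Untraced ancestors** terminate composition and remain as labels; we do
  not infer genotypes for ungenotyped ancestors.
* **Phenotype preprocessing** defaults to the replicate mean; a
  `"shrunken"` mode (one-way random-effect shrinkage of replicate means
  toward the environment mean) is provided as a documented approximation
  to entry-mean BLUPs.
* The simulator config file consumed by the CLI is JSON, not YAML (no
  YAML parser in the supported dependency set).

## What the simulator emulates — and what it does not

`simulate_population()` generates a NAM-style panel: one hub founder
crossed to each other founder, `lines_per_family` RILs per cross produced
by Poisson/Haldane meiosis (no crossover interference) iterated through
`selfing_generations` rounds, residual heterozygosity resolved run-wise at
random so downstream code sees homozygous inbreds.  Defaults — hub + 5
founders, 40 RILs per family, 3 chromosomes of 120 cM with 60 evenly
spaced markers, F5 selfing, 12 QTL, target h² of 0.5 — are a deliberately
desk-scale rendition of a real soybean NAM resource (tens of families,
thousands of RILs, ~4.3k markers over 20 chromosomes, yield h² around
0.3–0.66); sizes were fixed once and are not tuned to test outcomes.

Two features matter most:

* **Narrow ancestral base.** Founder genomes are mosaics of
  `n_ancestral_haplotypes` (default 3) block haplotypes of
  `haplotype_block_cM` (default 25 cM).  Founders that picked the same
  ancestral haplotype in a block are identical by state across the whole
  block yet can carry different causal alleles there — precisely the
  confounding that motivates origin tracing.  With independent founders
  (a large pool) IBS relationships approximate IBD and raw-marker ridge
  regression is essentially unimpaired, which we verified directly during
  development.
* **Founder-specific QTL.** In the default mode each founder carries its
  own causal allele effect at each QTL; a line's genetic value sums the
  effects of its *true origins* at the QTL.  The `"biallelic"` mode ties
  effects to the SNP allele instead, making raw dosage a sufficient local
  statistic.

Not emulated: coalescent founder history, crossover interference,
segregation distortion, genotyping error beyond a uniform flip rate,
genotype-by-environment structure.  A green mechanism test therefore
establishes that the pipeline exploits founder-specific confounding in an
idealized pedigree — not that it reproduces any particular empirical
panel's numbers.

## What the tests establish

The acceptance suite (one test per criterion in
`tests/testthat/test-acceptance.R`) checks: the analytic linked-marker
worked example (base expectation 0.5 units; marker selection keeps 50% at
0.6 units; IBD-tracked intermating reaches `1 - c` = 0.99 units at 1 cM);
the exact weighted-sum identity `sum_j n_j alpha_j = 0`; equality of
traced origins with simulator ground truth outside true-breakpoint
uncertainty intervals and of the imputation with a brute-force
nearest-anchor oracle; equality of the ridge solution and REML objective
with dense closed-form oracles at `1e-8`; recovery of a unit variance
ratio within 20% over 200 simulations; the directional mechanism property;
and byte-identical CLI reruns under a fixed seed.

### A known red result

The mechanism criterion has two arms, evaluated with pooled 5-fold
cross-validation (the protocol that reduces sampling bias for yield-like
traits), identical folds in both arms:

* **Founder-specific QTL (green):** the AEE arm's accuracy exceeds the
  raw-marker arm's in ~78% of 50 seeded replicates (mean accuracy ratio
  ~1.11 under CV, ~1.23 under single 80/20 splits).
* **Biallelic null (red, documented):** the expectation that the two arms
  are statistically indistinguishable (accuracy-ratio CI covering 1) does
  *not* hold at desk scale: measured mean ratio 0.954, 95% CI
  [0.936, 0.971] over 50 replicates.  The deficit is **not** tracing
  error — rerunning the AEE arm on ground-truth origins reproduces it.
  It is sampling noise in the class means: with classes of ~20–100 lines,
  `alpha` is an estimate, and regressing on estimated features attenuates
  accuracy relative to exact dosages (an errors-in-variables effect).
  Conversely, in fully informative populations the AEE matrix acts as a
  marginal-effect-*weighted* dosage coding and can slightly *beat* flat
  ridge under sparsity.  Exact equivalence holds only asymptotically in
  class size; the assertion is kept as stated rather than widened, and
  this section is its analysis.

## Known limitations

* Tracing is deterministic; no hidden-Markov smoothing of sparse or noisy
  panels, so genotyping error shows up as conflicts/singletons rather
  than being absorbed.
* No statistical imputation of missing genotypes; missing stays missing.
* Allele effects are single-generation by default; composition to founder
  classes is available but founder-level AEE fitting inherits whatever
  class sizes the pedigree provides.
* BED export of cM maps uses marker indices (flagged in the track header)
  since BED is inherently base-pair-oriented.
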