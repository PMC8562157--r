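# ibdtrace

Parental allele tracing, identity-by-descent (IBD) segment compilation, and
IBD-aware ridge-regression BLUP genomic prediction for pedigreed inbred
lines (RIL families, NAM panels, backcross-derived cultivars).

## The problem

Genomic selection models built on raw biallelic SNP codes use
identity-by-state (IBS): two lines that carry the same nucleotide get the
same contribution, regardless of which ancestor the allele came from.  In
germplasm with a narrow genetic base, several founders routinely share long
identical haplotypes around a gene *without sharing the causal allele of
that gene*.  A marker effect pooled across families then conflates
different causal alleles, capping prediction accuracy and misleading
marker-assisted selection.

`ibdtrace` resolves this with pedigree information alone:

1. **Anchor markers** (`assign_anchor_markers()`): within each cross, SNPs
   at which the two parents carry different homozygous alleles identify the
   parental origin of the progeny allele unambiguously.
2. **Flanking imputation** (`impute_from_flanks()`): markers that could
   have come from either parent are assigned when their nearest anchors on
   both sides (any distance, same chromosome) agree; runs whose flanks
   disagree remain ambiguous — a recombination happened somewhere inside.
3. **Multi-generation composition** (`trace_to_founders()`): origin labels
   are pushed through the pedigree so each segment is attributed to its
   most distal traceable ancestor; a line's unresolved regions become its
   own ancestral class in its progeny.
4. **IBD segments & recombination** (`compile_segments()`,
   `count_recombinations()`, `intact_chromosome_stats()`,
   `export_segments_bed()`, `call_allele_by_flanks()`).
5. **Allele effect estimates**: for each marker and ancestral source *j*,

   α_j = ( Σ_i y_ij ) / n_j − μ

   the raw deviation of the carrier-class phenotype mean from the
   population mean μ, fit per trait × environment on training lines only
   (`fit_aee()`).  The numeric **AEE matrix** (`build_aee_matrix()`)
   replaces the 0/1/2 marker matrix: SOURCE(j) → α_j, ambiguous →
   (α_j + α_k)/2, missing/conflict/unseen → 0.
6. **Genomic prediction** (`ridge_fit()`): the mixed model
   y = 1β + Xu + e, u ~ (0, σᵤ²I), e ~ (0, σₑ²I), with REML estimation of
   λ = σₑ²/σᵤ² by spectral decomposition and 1-D likelihood search
   (`mixed.solve`-style), plus the evaluation protocol: 80/20 splits or
   k-fold CV, top-10% selection differential, marker-based heritability,
   and a two-arm raw-vs-AEE comparison on identical splits
   (`compare_methods()`).

A pedigreed meiosis simulator (`simulate_population()`) — Haldane
crossovers, iterated selfing, founders drawn as mosaics of a small
ancestral haplotype pool, founder-specific or biallelic QTL — provides
ground-truth origins, crossovers and phenotypes so that every stage is
testable without external data.

## Worked example

```r
library(ibdtrace)

cfg <- sim_config(seed = 42)            # NAM: hub + 5 founders, 40 RILs each,
sim <- simulate_population(cfg)         # 3 chromosomes x 60 markers, F5, h2 0.5

origins <- trace_generation(sim$genotypes, sim$pedigree, sim$map)
head(attr(origins, "summary"), 3)
#>        line n_source n_ambiguous n_conflict n_missing frac_unassigned
#> 1 RIL01_001      114          66          0         0       0.3666667
#> 2 RIL01_002      114          66          0         0       0.3666667
#> 3 RIL01_003      121          59          0         0       0.3277778

segs <- compile_all_segments(origins, sim$map)
intact_chromosome_stats(origins, sim$map)$fraction_intact
#> [1] 0.305

fit_aee(origins, sim$phenotypes, "trait1", "env1")
#> Allele effect table: trait 'trait1', environment 'env1'
#>   training lines: 200   mu = -1.191
#>   867 (marker, source) classes over 175 markers

cmp <- compare_methods(origins, sim$genotypes, sim$phenotypes,
                       "trait1", "env1", seed = 42, mode = "cv")
c(raw = cmp$raw$accuracy, aee = cmp$aee$accuracy, ratio = cmp$accuracy_ratio)
#>       raw       aee     ratio
#> 0.4704...  0.5037...  1.0709...
```

With founder-specific QTL (the default), the AEE arm predicts this
population more accurately than raw marker codes (here +7% accuracy; the
top-10% selected fraction yields a 31% larger observed mean).  Per-line
unassigned fractions of ~1/3 reflect the narrow simulated founder base —
regions where the two parents are identical by state stay ambiguous and
are averaged in the AEE matrix.

The analytic linked-marker scenario (selection on a SNP 1 cM from a gene in
a population where the favorable SNP allele tags the favorable gene allele
only 60% of the time):

```r
str(simulate_table4_scenario()[-1])
#> $ base_phenotype        : num 0.5
#> $ selected_fraction     : num 0.5
#> $ selected_phenotype    : num 0.6
#> $ ibd_tracked_phenotype : num 0.99
#> $ recombination_fraction: num 0.01
```

## Command line

```sh
inst/cli/ibdtrace simulate --out-dir sim --seed 7
inst/cli/ibdtrace trace    --genotypes sim/genotypes.tsv --pedigree sim/pedigree.csv \
                           --map sim/map.csv --out origins.tsv
inst/cli/ibdtrace segments --origins origins.tsv --map sim/map.csv --out-prefix seg --bed
inst/cli/ibdtrace aee      --origins origins.tsv --phenotypes sim/phenotypes.csv \
                           --trait trait1 --env env1 --out aee.tsv
inst/cli/ibdtrace compare  --origins origins.tsv --genotypes sim/genotypes.tsv \
                           --phenotypes sim/phenotypes.csv --trait trait1 --env env1 \
                           --seed 7 --mode cv --out report.json
```

All randomness is behind `--seed`; reruns are byte-identical.  Each run
writes a `.provenance.json` beside its outputs.

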