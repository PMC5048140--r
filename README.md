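# phylotai

Phylotranscriptomic analysis of ordered developmental transcriptomes:
expression-weighted gene-age and gene-diversity profiles, with the
preprocessing, population-genetic, cross-species and inferential machinery
needed to use them on real or simulated stage-resolved RNA-seq studies.

The package is aimed at evo-devo researchers testing hourglass-type
phylogeny–ontogeny correlations — for example, asking whether a
free-swimming larval stage such as the trochozoan trochophore expresses an
evolutionarily old, population-conserved transcriptome — and at
methodologists who want the statistical behaviour of these indices
(calibration, power, coverage) to be checkable on synthetic data with known
ground truth.

## The indices

For genes *i* = 1…*n* with weighted expression *e<sub>is</sub>* at
developmental stage *s* (read counts divided by CDS length, then
composition-corrected between stages by trimmed-mean-of-M-values scaling):

- **TAI** (transcriptome age index):
  TAI<sub>s</sub> = Σ<sub>i</sub> ps<sub>i</sub>·e<sub>is</sub> / Σ<sub>i</sub> e<sub>is</sub>,
  where ps<sub>i</sub> is the gene's phylostratum rank (1 = oldest lineage
  node; the maximum rank holds the species-specific "new genes"). Lower
  TAI = older transcriptome.
- **TPI** (transcriptome polymorphism index):
  TPI<sub>s</sub> = 10³ · Σ<sub>i</sub> θ<sub>i</sub>·e<sub>is</sub> / Σ<sub>i</sub> e<sub>is</sub>,
  with θ<sub>i</sub> the per-site Watterson estimator
  θ = S / (H<sub>n−1</sub>·L) from population resequencing. Lower TPI =
  transcriptome dominated by population-conserved genes.
- **REL** (relative expression level): per phylostratum, the mean partial
  concentration f̄(ps, s) min–max normalized across stages to [0, 1].

Phylostrata come from homology hit tables (minimum qualifying rank;
`assign_phylostrata()`); θ from VCF + BED (`gene_snp_summary()`,
`theta_table()`); cross-species stage correspondence from reciprocal-best-
hit orthologs and Spearman correlation (`reciprocal_best_hits()`,
`stage_similarity()`). Uncertainty comes from a gene-resampling bootstrap
(`bootstrap_ci()`) and a per-stage permutation null with method-of-moments
gamma fits and a dependence-respecting combined pattern p-value
(`permutation_null()`).

## Worked example

The bundled six-gene fixture is small enough to check by hand:

```r
library(phylotai)
fx <- fixture_small()
lw <- length_weight(fx$counts, fx$genes)
tai(lw, fx$genes)
#> # TAI profile over 5 stages
#>   stage value
#> 1 s1     5
#> 2 s2     5.71
#> 3 s3     8.06
#> 4 s4     5.71
#> 5 s5     5
```

Stage s3 is dominated by a highly expressed species-specific gene (rank 11),
so its weighted mean age rises to 8.06; the other stages sit near 5. The
same values are recorded in `fx$manifest`, which was computed with pen and
paper when the fixture was authored.

A full synthetic study with a planted hourglass (old genes boosted 3-fold
at stage 6 of 11):

```r
cfg <- sim_config(n_genes = 2000, delta = 3, seed = 42)
sim <- simulate_dataset(cfg)
expr <- tmm_normalize(length_weight(sim$counts, sim$genes))
bootstrap_ci(expr, sim$genes, "TAI", n_boot = 1000, seed = 42)
#> # TAI profile over 11 stages
#>    stage value ci_low ci_high
#>  1 s1     5.58   5.27    5.88
#>  ...
#>  6 s6     4.54   4.22    4.88   <- minimum at the planted phylotypic stage
#>  ...
#> 11 s11    7.18   6.82    7.51

permutation_null(expr, sim$genes, "TAI", n_perm = 1000, seed = 42)
#> Permutation null for TAI profile
#>   stages: 11, permutations per stage: 1000
#>   combined p (empirical, two.sided): 0.000999
```

The profile dips exactly at the planted stage, the bootstrap band excludes
the early- and late-stage values there, and the combined pattern p-value is
at the resolution floor of 1000 permutations (1/1001). `autoplot()` on any
profile, REL table or similarity grid gives the corresponding ggplot.

File-based workflows go through `run_config()` / `run_pipeline()`, which
read counts, gene tables, hit tables, lineage maps, VCF + BED and a second
species' data, and write every profile, null-model report and filter log to
an output directory, echoing the full configuration and seed.

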