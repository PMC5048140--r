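---
title: "Methods: expression-weighted age and polymorphism profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-weighted age and polymorphism profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylotai)
```

## The model

A stage-resolved transcriptome is summarized by expression-weighted means
of a per-gene evolutionary covariate. With weighted expression
$e_{is}$ of gene $i$ at stage $s$,

$$\mathrm{TAI}_s = \frac{\sum_i ps_i\, e_{is}}{\sum_i e_{is}}, \qquad
\mathrm{TPI}_s = 10^3\,\frac{\sum_i \theta_i\, e_{is}}{\sum_i e_{is}},$$

where $ps_i$ is the phylostratum rank of gene $i$ (1 = oldest node of the
focal lineage, maximum rank = species-specific genes) and $\theta_i$ is the
per-site Watterson estimator of nucleotide diversity. Both indices are
convex combinations of the covariate, hence bounded by its observed range,
and depend only on within-stage expression *composition*: multiplying a
stage column by any positive constant leaves them unchanged. That
invariance is what makes between-stage normalization a second-order
concern for the indices themselves while still mattering for anything that
compares absolute levels (the duplicate filter, the similarity grid).

Relative expression levels decompose the same signal by stratum: the
partial concentration $f_{is} = e_{is} / \sum_j e_{js}$ sums to 1 within a
stage; per phylostratum the gene-mean $\bar f(ps, s)$ is min–max
normalized across stages to $[0,1]$. A stratum with constant $\bar f$ has
no dynamics to normalize and its row is reported as `NaN`, deliberately
distinct from a row sitting at its minimum.

## Preprocessing

`e_{is}` defaults to length-weighted, TMM-scaled values:

1. **Length weighting** divides counts by CDS length (bp), making values
   proportional to transcript-molecule counts rather than to sequenceable
   positions.
2. **TMM scaling** corrects the RNA composition effect between stages. The
   implementation follows the published algorithm: M-values (log2 ratios of
   library-size-normalized proportions) doubly trimmed at 30% and A-values
   at 5%, averaged with inverse delta-method binomial weights; genes with a
   zero in either compared library are excluded; a comparison whose
   M-values are all below $10^{-6}$ in absolute value yields a factor of
   exactly 1. The reference stage is the one whose upper-quartile
   proportion is closest to the mean upper quartile. Factors are rescaled
   to geometric mean 1 — the convention of the algorithm's reference
   implementation, against which the test suite checks agreement to
   `1e-6` — with `scale = "reference"` available for a ref-stage-equals-1
   convention.
3. **Correlated-duplicate filter.** Short (default ≤ 500 bp), extremely
   highly expressed (default peak ≥ 10,000 in RPKM-scale units) genes whose
   stage profiles correlate above r = 0.99 usually reflect one repeated
   genomic element counted under several ids, and as a group can dominate
   the weighted transcriptome. Candidates are clustered by correlation
   edges; each connected component keeps one representative — the longest
   CDS, ties broken by smallest id. The candidacy thresholds are defaults
   derived from the range in which such elements have been observed
   (hundreds of bp, RPKM up to ~10^5), not sharp biological constants, and
   are exposed as arguments. Constant-expression genes have no defined
   correlation and are excluded from candidacy with a message.
4. **Sequence-redundancy filter** (for assemblies with duplicated gene
   models): components of the graph whose edges require ≥ 97% protein
   identity, ≥ 95% DNA identity and zero gaps in the aligned protein
   region, collapsed with the same representative rule.

Whether TMM is computed before or after length weighting is not a settled
convention; the pipeline length-weights first and then TMM-scales the
weighted matrix, and `tmm_factors()` accepts either input if a user wants
the other order.

## Watterson's theta

$\hat\theta = S / (H_{n-1} L)$ per site, with $S$ the number of sites at
which ≥ 2 distinct alleles are called among the sample, $n$ = 2 × the
number of resequenced diploid individuals, and $L$ the annotated gene
length. The whole-gene $n$ is used even at sites with missing genotypes
(the convention of standard population-genetics software operating on
inferred diploid sequences); per-site $n$ reduction would require
coverage-resolved data the VCF workflow does not assume. Multi-allelic
sites count once toward $S$. Using annotated length rather than
callable-site length biases $\hat\theta$ downward when coverage is
incomplete; with complete synthetic coverage the estimator is unbiased,
which the test suite verifies by simulation
($S \sim \mathrm{Poisson}(\theta H_{n-1} L)$). Genes without SNP data get
$\theta = 0$ and an explicit `no_snp_data` flag rather than `NA`, so TPI
remains computable while the flag preserves the distinction.

## Gene ages

A gene's phylostratum is the minimum rank among subject species with a hit
at e-value ≤ cutoff; genes with no qualifying non-self hit get the maximum
rank ("new genes"). The age-assignment cutoff defaults to `1e-3`, the
long-standing phylostratigraphy setting, and is exposed because the choice
is conventional, not derived. Relaxing the cutoff can only add qualifying
hits, so ranks are monotone non-increasing in the cutoff — a property the
tests assert on random tables. Hit rows naming species absent from the
lineage map are skipped with a warning by default (`"error"` mode
available): in practice such rows are database-version noise, but a strict
pipeline should be able to refuse them.

## Cross-species similarity

Orthologs are reciprocal best hits at e-value ≤ `1e-5` (best = lowest
e-value, then highest bit score, then smallest subject id — a total order,
so the map is deterministic and one-to-one). Stage similarity is Spearman's
$\rho$ across ortholog pairs, computed as Pearson on average-tied ranks
(exact under ties), on RPKM-like units so the two species' magnitudes are
comparable in rank space. Ortholog pairs silent across all stages in
either species are dropped first: all-tie vectors carry no rank
information and distort the remaining ranks. Per focal stage the
best-matching partner stage is the argmax, ties resolving to the earliest
developmental stage (logged), since an earlier tie is the conservative
claim about correspondence.

## Uncertainty

**Bootstrap.** Genes are resampled with replacement; one resample is
shared by all stages within a replicate, so the band reflects sampling
variation of the whole profile rather than of each stage separately
(per-stage independent resampling is a flag). Percentile intervals at
$(1\pm0.95)/2$; a resample that zeroes a stage's total expression is
redrawn (cap 100).

**Permutation test.** Within each stage the covariate is permuted across
genes, breaking the gene-to-expression pairing while keeping both
marginals; each stage's surrogate distribution is summarized by a gamma
fitted by the method of moments (shape $= m^2/v$, scale $= v/m$ on sample
moments), and the observed index gets a two-sided p-value under that gamma
(one-sided options available). The gamma approximation is accurate in the
range a 1000-permutation null can resolve; the tests check agreement with
empirical rank p-values within a factor of two down to p ≈ 0.01 on a
matched null at study scale (2000 genes).

**Combined pattern p-value.** The per-stage p-values are *not*
independent: every stage shares the same observed covariate pairing, and
expression weights are correlated along development. Combining them with
closed-form Fisher or Stouffer rules (both available) therefore overstates
significance — in the package's own null experiments the Fisher
combination rejected at roughly three times the nominal rate. The default
instead re-uses one permutation across all stages within each surrogate
replicate and refers the observed Fisher statistic
$X = -2\sum_s \log p_s$ to the empirical distribution of the surrogate
replicates' own $X$ values. This is a permutation test of the global null
using $X$ as its statistic: calibrated by construction, at the cost of a
resolution floor of $1/(n_\mathrm{perm}+1)$. Degenerate stages (constant
covariate) contribute $p = 1$ throughout by convention.

Because expression is already length-weighted, permuting gene length as a
separate component would not change the index; the permutation of the
covariate against the expression vector is the complete reduction of
"permute the per-gene components within each stage".

## The synthetic-data generator

`sim_config()` / `simulate_dataset()` emulate the structure of a
stage-resolved developmental study in a highly polymorphic marine
invertebrate with phylostratigraphic ages and population resequencing:

- ~11 phylostrata with a census peaked at the oldest stratum and a
  secondary bump at the youngest (the shape phylostratigraphic censuses
  show), 11 ordered stages, 10 resequenced individuals;
- CDS lengths lognormal (median 1.2 kb, floor 150 bp); per-bp baseline
  expression lognormal with sdlog 1.2 so a 1.2 kb gene has median depth
  ≈ 180 counts with the heavy right tail real libraries have; negative
  binomial counts with dispersion 0.1 (Poisson as a flag);
- per-gene θ log-uniform on 0.002–0.02 per site — the high diversity of
  broadcast-spawning marine invertebrates — increasing 0.08 log-units per
  rank so young genes are more polymorphic;
- the hourglass signal as two opposing waves: old strata (ranks 1–4)
  boosted up to δ-fold in a triangular window around the phylotypic stage,
  the two youngest strata ramping toward the terminal stages; δ = 1 is the
  exact null (age independent of expression);
- SNP genotypes with $E[S] = \theta H_{2N-1} L$ and allele counts drawn
  from the neutral frequency spectrum; a homology table from which age
  assignment recovers the generating ages exactly; a second species built
  by bounded adjacent rank swaps whose number grows with distance from the
  phylotypic stage, so Spearman similarity peaks there by construction.

What it does **not** emulate: genomic linkage between SNPs (sites are
independent given θ), coverage gaps and genotyping error, assembly
artifacts, many-to-many orthology, batch effects between stages, or
biological replicates within stages. Passing tests therefore demonstrate
the statistical behaviour of the estimators under a clean generative
model, not robustness to those real-data pathologies.

## Validation problem sizes

The test suite validates statistical behaviour at these scales (chosen as
the smallest sizes at which the properties are meaningfully testable):
type-I error of the combined test on 300 null datasets of 500 genes × 7
stages at 200 permutations (rejection rate at α = 0.05 within
[0.02, 0.09]); power and phylotype localization on 100 hourglass datasets
of 2000 genes at δ = 3 (combined p < 0.05 in ≥ 95%, argmin at the planted
stage in ≥ 90%); bootstrap coverage on 200 datasets of 300 genes × 5
stages against the analytic profile `true_tai()` (coverage in
[0.90, 0.99]); exact oracles everywhere a closed form or exhaustive
enumeration exists (4! permutation enumeration, Watterson closed forms,
hand-computed fixture manifest, TMM against an independent reference
implementation to 1e-6).

## Known limitations

- The empirical combined p cannot go below $1/(n_\mathrm{perm}+1)$;
  reporting very small pattern p-values requires raising `n_perm`.
- Gamma-fit per-stage p-values degrade beyond the range the permutation
  count resolves (factor-2 agreement holds to p ≈ 0.01 at study scale;
  far-tail extrapolation is a smooth approximation, not a guarantee).
- θ uses annotated gene length; with incomplete coverage it is a lower
  bound.
- The duplicate filter's candidacy thresholds are conventions; on data
  where repeated elements are long or modestly expressed they must be
  retuned.
- REL rows for single-gene strata are the min–max of one gene's
  concentration and correspondingly noisy.
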