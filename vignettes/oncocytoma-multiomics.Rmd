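---
title: "Multi-omics analysis of matched renal oncocytoma cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics analysis of matched renal oncocytoma cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncocytomics)
```

# The setting

Renal oncocytoma is a benign kidney tumor with two defining molecular
features: a strong accumulation of mitochondria, and the selective loss of
respiratory complex I (CI) caused by heteroplasmic mtDNA mutations. A
paired tumor/normal multi-omics study of such a cohort touches five data
modalities — proteome, metabolome, mtDNA variants, nuclear variants, and
copy-number segments — each with its own statistical pitfalls. This
package implements the full analysis for a matched design (every patient
contributes one tumor and one normal sample) and pairs it with a synthetic
cohort generator whose ground truth makes every stage testable by
parameter recovery.

This vignette documents the models, the tunable parameters and their
defaults, what the generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

# Shared statistical core

**Differential testing.** Each feature is tested with Welch's
(unequal-variance) two-sample t-test on log2 abundances, tumor versus
normal. The variance assumption was an open choice: with n = 6 per group,
Welch is the robust default and is what we use; a paired test across
patient pairs is exposed (`paired = TRUE`) but off by default, matching
the unpaired convention of the analysis this package systematizes.
Multiple testing uses Benjamini–Hochberg (`bh_adjust()`, a validating
wrapper over `stats::p.adjust`). The metabolome stage declares a
metabolite significant only when *both* `q <= 0.05` and nominal
`p < 0.01` hold — the two gates are individually configurable
(`fdr_level`, `p_cutoff`) because published practice is ambiguous about
which one is the operative filter; applying both is the conservative
reading. Degenerate rows (zero variance in both groups, equal means)
yield p = 1 by definition rather than an error; rows with fewer than two
valid values in a group are skipped and reported.

**Left-censored (MNAR) imputation.** Label-free proteomics loses
low-abundance proteins below the detection limit, so missingness is
missing-not-at-random. `impute_gaussian()` uses the conventional
downshifted-Gaussian replacement: per sample column with mean m and
standard deviation s, missing cells are drawn from
N(m − 1.8 s, (0.3 s)²). The pair (0.3, 1.8) follows the long-standing
defaults of the mainstream proteomics software stack and is exposed in
`run_config()`. Observed cells are never altered, and the draw is
deterministic given a seed.

**Permutation p-values.** All permutation tests use the add-one estimator
p = (1 + #{null at least as extreme}) / (1 + n~draws~), which cannot
return zero and is the standard finite-sample-valid choice.

# Proteome stage

**Validity filtering.** Two published modes are implemented for a 6+6
design and generalized to the actual group size: `each_group_min3` keeps
features with at least three valid values per group (no imputation
implied); `one_group_full6` keeps features fully observed in at least one
group, with the other group's cells meant for imputation — this rescues
the most regulated proteins, whose abundance falls below detection in one
tissue entirely.

**Mitochondrial mass ratio.** Per patient and compartment,
`mito_mass_ratio()` computes the ratio of *summed raw intensities*
(tumor over normal). Sums are taken on the linear scale because the
quantity of interest is total protein mass, not a typical per-protein
fold; the estimate is scale-invariant per patient pair. The cohort mean
and SD are reported, which implies per-patient ratios are averaged
(rather than pooled across patients) — the choice consistent with
reporting a cohort SD. Features absent from the mitochondrial annotation
count as non-mitochondrial: the annotation is a positive list (MitoCarta
semantics, ~1158 entries at full scale).

**Compartment-stratified calls.** Because the mitochondrial compartment
shifts wholesale, a single global threshold would call half the organelle
"regulated". Features are therefore split into mitochondrial and
non-mitochondrial strata and a feature is called up (down) only when its
log2 fold change exceeds one stratum SD above (below) the stratum mean.
Under approximate normality this flags about 31.7% of features two-sided;
the property suite checks that. A stratum with zero SD yields no calls.

**OXPHOS summaries.** `oxphos_complex_summary()` reports median log2 fold
changes per respiratory complex, separately for structural subunits and
assembly factors (disjoint sets — assembly factors are not part of the
final complex). The qualitative verdict `CI_down_rest_up` is attached
when the CI subunit median is negative while all other quantified
complexes are positive: the selective CI-loss signature.

# Enrichment stage

`enrichment_score()` implements the weighted Kolmogorov–Smirnov-like
running sum: walking down the ranking, hits add `|s|^w / N_R` and misses
subtract `1/(N − n_hits)`; the ES is the signed maximum deviation, and an
exact tie between the positive and negative extreme resolves to the
positive one (deterministic, and identical between the reference
running-sum and the O(k) permutation path). Ranking ties are broken by
feature id. The default weight is 1 (the classic GSEA default), with
weight 0 giving the unweighted KS statistic.

`gsea_run()` uses *gene-set* permutation — random member sets of equal
size drawn from the ranking — rather than phenotype permutation, because
a 6+6 cohort admits only 924 distinct phenotype relabelings, too few for
stable tail estimates. NES normalizes ES by the mean |null ES| of the
same sign; the nominal p is one-sided within the same-sign null (so its
smallest attainable value is about 2/n~perm~), and the FDR q compares the
observed NES against the pooled normalized null, as in the classic
procedure. Sets with fewer than 5 quantified members are excluded
(`min_size = 5`); significance defaults to p ≤ 0.01 and FDR ≤ 0.15, with
the laxer FDR ≤ 0.25 gate available through `run_config()`. Agreement of
the ES with the independent `fgsea` implementation is checked in the test
suite; NES/FDR values are validated by calibration and power properties,
not by matching any published table, which would require the original
spectra.

# mtDNA stage

Heteroplasmic fractions are `HF = alt/(alt+ref)` with Wilson score 95%
intervals (cross-checked against `prop.test`). Origin classification
declares a variant somatic when the normal-tissue HF is below the
detection limit (default 0.005) or the variant is absent there, germline
when present in both tissues with |HF~t~ − HF~n~| ≤ 0.10, and
unclassified otherwise; the concordance tolerance and detection limit are
defaults of this package, since only the concordance itself is published.

Functional annotation translates protein-gene substitutions in frame
under the **vertebrate mitochondrial genetic code** (AGA/AGG stops, ATA
Met, TGA Trp; from `Biostrings::getGeneticCode("2")`), classifying them
as synonymous, non-synonymous, or stop-gain; tRNA/rRNA/D-loop positions
are labelled by interval, and positions outside all intervals are
`other_noncoding`, not an error. The packaged gene map and reference
sequence (`toy_mt_gene_map()`, `toy_mt_genome()`) are **synthetic**: the
map mimics the human mtDNA layout on the 16,569 bp coordinate system
(D-loop with HV1/HV2, two rRNAs, tRNAs, 13 protein genes, one on the
light strand) but with simplified bounds, and the sequence is a
seed-deterministic random string. They exercise the same coordinate,
strand and codon arithmetic as the real annotation; analyses of real
cohorts should supply the genuine gene map and sequence in the same
tabular form.

Prioritization applies the published in-silico criteria in order:
haplogroup-defining variants are excluded outright (haplogroup
*prediction* is out of scope — the site list is an input, which the
generator also emits); remaining variants are prioritized when nucleotide
variability < 0.0026 **and** the disease score exceeds the class
threshold — 0.43 for protein-coding changes (applied to stop-gains as
well, a package choice since no separate stop-gain threshold is
published), 0.35 for tRNA, 0.60 for rRNA. The rule is monotone: lowering
variability or raising the score can never un-prioritize a variant.
Disease scores and variabilities are input annotations from external
databases; the package validates and applies the thresholds, it does not
compute the scores.

The mtDNA copy ratio per pair is `(mt/nuclear coverage)_tumor /
(mt/nuclear coverage)_normal`. The generator's preset centers it on 1.79
(SD 0.64), the figure-legend value, which we take as canonical over the
rounded "1.6-fold"/"1.8-fold" textual mentions.

# Nuclear stage

The substitution spectrum collapses the 12 substitution types onto the
six pyrimidine-reference classes (strand-symmetric by definition; no
transcription-strand variant is attempted), with indels counted and
skipped. Ti/Tv is `(C>T + T>C)` over the four transversion classes and is
undefined (an error) without transversions. Class enrichment uses an
exact two-sided binomial test per class against baseline probabilities —
uniform 1/6 by default, configurable, since the baseline behind published
enrichment p-values is unstated; matching those exact p-values is
explicitly not a goal. The non-silent burden excludes silent variants and
reports per-patient counts and the cohort median.

The CNV gene-dose test asks whether proteins encoded in lost segments are
less abundant than chance: observed = mean log2 fold change over
quantified loss genes; null = means of equal-size random gene draws
without replacement; one-sided ("lower") permutation p. Loss segments
follow the BED convention (0-based, half-open) and genes are assigned by
midpoint overlap.

# Metabolome stage

Raw peak areas are normalized by tissue mass and then by internal
standards (one value per metabolite and sample; only first-transition
areas are modelled, so no multi-transition logic exists anywhere).
Fold changes are formed after flooring: values below the limit of
quantification are raised to the floor before group means, so a
metabolite undetectable in normal tissue yields a finite, meaningful
ratio against background — the convention behind the reduced-glutathione
fold. Flooring can only move a fold toward 1 (raising sub-LOQ normal
values increases the normal mean), and equals the plain ratio when
nothing is below the floor; both facts are property-tested. When both
group means sit at the floor the fold is 1 with a `censored` flag. The
default floor policy is a per-metabolite LOQ supplied with the data (the
generator emits one); the fallback is the smallest positive observed
value. Down-regulation is reported both as a ratio < 1 and in the signed
convention (−1/ratio) used by publication tables.

# The synthetic cohort generator

The generator defines the study conditions; its defaults are the
cohort-level quantities the analysis should recover, not tuning knobs.

* **Proteome** (`gen_proteome`): 6 pairs, 2000 proteins, 25%
  mitochondrial. Log2 baselines are N(25, 2²) with per-cell noise SD 0.5.
  Each patient draws a mitochondrial mass factor log-normal with mean
  2.22; the natural-scale SD is 0.4, deliberately smaller than the
  published cohort SD of 1.63 so that 20-cohort recovery tests are stable
  rather than dominated by six-patient sampling noise. The
  non-mitochondrial factor is log-normal mean 0.97, SD 0.06. Forty
  designated CI subunits receive the depletion factor 0.35 *instead of*
  the mass factor; CI assembly factors (a disjoint synthetic group) ride
  the mass boost. Because the depleted CI subunits still hold ~8% of
  mitochondrial baseline abundance, the recovered cohort mito ratio sits
  ~7% below 2.22 — inside the 15% recovery band and an expected property
  of the preset, not a defect. MNAR missingness removes cells with
  logistic probability 1/(1+exp(−(t − x))) where t is the 10% intensity
  quantile; a threshold quantile of 0 disables censoring for null-case
  tests. CI subunits are a named synthetic gene group, not real gene
  symbols; the annotation table ships with the cohort object.
* **Metabolome** (`gen_metabolome`): 159 metabolites, 29 of which carry
  the published signed fold changes; all others are null. Multiplicative
  log-normal noise with CV 20% — the within-cohort dispersion is not
  published, and 20% is a typical targeted-MRM tissue CV; it is exposed
  in the config. Reduced glutathione is generated below its LOQ in
  normals (0.3 × floor) with a tumor mean of 5413 × floor, so the floored
  fold recovers the published value. With 130 null metabolites and the
  p < 0.01/q ≤ 0.05 gate, about 1.2 false positives per cohort are
  *expected*; the recovered significant count therefore fluctuates
  between 29 and ~32 with majority vote 29 — the analysis cannot and
  should not hide BH's designed false-discovery allowance.
* **mtDNA** (`gen_mt_variants`): 54 germline events (59.26%
  haplogroup-defining; the non-haplogroup remainder split 6
  non-synonymous / 8 synonymous / 8 non-coding, the self-consistent
  integer counts), 195 somatic events (35 synonymous / 63 non-synonymous
  / 19 stop-gain / 78 non-coding), positions drawn so the annotator
  reproduces each intended class. Somatic HFs are uniform on
  [0.006, 0.069] except one homoplasmic non-synonymous variant; 54/63
  somatic non-synonymous variants exceed the disease-score threshold and
  49 of those fall below the variability cutoff. Allele depths are
  binomial at Poisson coverage (mean 2000×). Coverage summaries realize
  per-pair copy ratios log-normal with mean 1.79, SD 0.64.
* **Nuclear** (`gen_nuclear_variants`): per-patient non-silent counts
  log-normal around median 78 (log-SD 0.55, giving the published-order
  spread), silent variants at the 799:798 ratio, non-silent classes at
  760:19:11:8, substitutions multinomial over the printed six-class
  spectrum (total 4283), rendered on a random strand.
* **CNV** (`gen_cnv`): the default loss pattern mirrors the reported
  cohort (X loss in four patients, partial chr1 in two, one patient with
  additional losses), on a coarse per-chromosome grid; affected proteins
  get −0.5 log2 added to the tumor cells of affected patients.

Every generator is bit-reproducible given a seed, and each returns a
truth object covering every generated feature exactly once.

**What the generator does not emulate.** Intensities are log-normal with
homoskedastic log-scale noise — no peptide-level structure, no shared
batch effects, no correlation between proteins beyond the compartment
shifts; metabolite noise is independent across samples (no
patient-matched correlation); variant positions ignore mutational
hotspots and homopolymer context; coverage is summary-level (no reads);
CNV segments are whole- or half-chromosome blocks. Passing recovery
tests therefore demonstrates correctness of the estimators under the
stated sampling model, not robustness to the full messiness of real
LC-MS or WES data.

# Problem sizes and determinism

Recovery experiments use 20 replicate cohorts of the default preset
(6 pairs; 2000 proteins; 159 metabolites; 249 mtDNA variants), a size at
which every cohort-level estimator's Monte-Carlo error is a few percent
— e.g. the copy-ratio grand mean over 120 pairs has standard error
0.64/√120 ≈ 0.059 — while the full suite runs in well under a minute.
Null-calibration properties use 50 replicates at reduced feature counts.
All randomized operations take an explicit seed (`withr::with_seed`), so
results are bit-reproducible; `scripts/acceptance.R` derives its 20
cohort seeds from the single `--seed` argument.

# Known limitations

* The GSEA FDR follows the classic pooled-normalized-null recipe and will
  differ in detail from any specific GSEA release; only its calibration
  is guaranteed here.
* `prioritize_mt` treats the disease score and variability as given;
  garbage annotations yield garbage prioritization.
* The compartment threshold rule is descriptive (mean ± SD), not an error
  rate: it flags tails of the empirical fold-change distribution.
* The kinetic metabolic-pathway simulation sometimes layered on top of
  such data (scaling enzyme V~max~ values by protein-abundance ratios) is
  out of scope here.
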