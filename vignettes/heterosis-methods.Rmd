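---
title: "Methods: quantifying and mapping heterosis in common-reference panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and mapping heterosis in common-reference panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(heterosisr)
```

## The design and the model

A common-reference hybrid panel crosses a set of inbred accessions to one
shared reference line, producing F1 hybrids whose genetic differences are
entirely attributable to the variable parent. `heterosisr` models two such
overlapping panels (one per reference line), each with the variable-parent
set in common, replicate-level phenotypes for parents and hybrids, and
biallelic SNP genotypes for the parental accessions.

Heterosis statistics are defined per hybrid and trait from genotype means:
the mid-parent value $P_{MPV} = (P_1 + P_2)/2$, relative mid-parent
heterosis $MPH = 100\,(F_1 - P_{MPV})/P_{MPV}$, absolute mid-parent
heterosis $MPH_{ABS} = F_1 - P_{MPV}$, and better-parent heterosis
$BPH = 100\,(F_1 - P_{best})/P_{best}$. Under purely additive gene action
the F1 genotypic value equals the mid-parent value, so $MPH_{ABS}$
isolates non-additive (dominance/overdominance) contributions — which is
why the association scan maps $MPH_{ABS}$ rather than $MPH$.

Variance decomposition uses replicated genotypes: $V_G$ is the variance
among genotype means, $V_E$ the mean of within-genotype sample variances
(both with $n-1$ divisors), $H^2 = V_G/(V_G+V_E)$ and
$CV_G = 100\sqrt{V_G}/\bar{x}$. The $V_E$ divisor is not uniquely pinned
down by the verbal definition "mean of the sum of squares within
genotypes"; we use the unbiased within-genotype sample variance, and an
ANOVA expected-mean-squares estimator of $V_G$ is available via
`heritability(method = "anova")` for comparison. Traits measured as pooled
single observations have no within-genotype replication, so $H^2$ is
reported as undefined rather than guessed.

## The association scan

The scan fits, per trait, the mixed model
$y = X\beta + g + e,\; g \sim N(0, \sigma^2_g K),\; e \sim N(0, \sigma^2_e I)$
once without any SNP, then tests each SNP by generalized least squares
with the variance components held fixed — the standard two-stage
("population parameters previously determined") approximation. Fitting
uses one eigendecomposition of $K$; the variance ratio
$\lambda = \sigma^2_g/\sigma^2_e$ maximises the restricted likelihood over
a 61-point $\log_{10}$ grid on $[10^{-5}, 10^5]$ with golden-section
refinement between the bracketing grid points. This is deterministic and
needs no seed. When a trait carries no kinship structure the optimiser
lands at the grid edge and the fit is flagged (`boundary = TRUE`).

Two binary encodings connect genotypes to the two halves of the genetic
model:

* **dominant** — samples are hybrids, the predictor is 1 where the hybrid
  is heterozygous (variable parent differs from the reference parent) and
  0 otherwise; regressing $MPH_{ABS}$ on it estimates the dominance
  effect $d$;
* **additive** — samples are the parental accessions, the predictor is 1
  for reference-allele homozygotes and 0 otherwise; regressing parental
  means on it estimates $2a$. The literature states this encoding in both
  orientations; they differ only in the sign of the effect, and
  `encode_additive(orientation =)` provides both.

For the dominant scan, each hybrid inherits its variable parent's kinship
row: all hybrids share the reference genome, so their relatedness is
driven by the variable parent. This choice is configurable by passing any
kinship matrix keyed by hybrid id.

MAF filtering removes SNPs with MAF strictly below 0.05 (a SNP at exactly
0.05 is kept), computed over the samples entering the model (parents for
both encodings, since hybrids' heterozygosity is a deterministic function
of parental alleles). Missing genotype calls are mean-imputed per SNP
inside the scan only, never in files. Benjamini–Hochberg q-values are
computed within each (trait, model, population) scan — never pooled across
traits — via `stats::p.adjust`; the fixed-threshold report flags
$-\log_{10}(p) > 4$ with a strict inequality.

### Quality of the two-stage approximation

An exact mode (`scan_gls(exact = TRUE)`) re-estimates the variance
components per SNP. Under null or polygenic architectures the two agree
very closely (the test suite bounds $|\Delta(-\log_{10} p)|$ at 0.2 on a
200-hybrid panel and observes far less). At a strong single causal locus
the two-stage scan is *conservative*: the null model, fitted without the
SNP, absorbs part of the QTL signal into $\sigma^2_g$, deflating the
causal SNP's test statistic relative to the exact fit. This is the
expected behaviour of this family of approximations and does not affect
ranking in our power checks.

## The synthetic panel generator

`sim_config()` + `simulate_panel()` emulate the study design the package
targets: by default 100 inbred accessions genotyped at 1,000 biallelic
SNPs over 5 chromosomes, crossed to two reference lines (`Col`, `Ler`) to
give two populations of 100 hybrids sharing the variable-parent set, with
10 replicates per genotype and eight directly measured traits (estimated
seed number, NS, is derived from SY and SW with `add_seed_number()`, at
`NS = 10^6 · SY / SW` for SY in g/plant and SW in mg/1000 seeds).

Choices a scientist should know about:

* **Allele frequencies** are drawn independently per SNP from
  `maf_range = c(0.05, 0.5)` — no linkage disequilibrium. This is the
  simplest null that exercises every stage; pseudo-overdominance
  (complementation of linked loci masquerading as overdominance) cannot
  arise without LD and is out of the generator's scope.
* **Genetic architecture**: each trait receives by default five additive
  loci ($a = 0.06 \times$ baseline) and two dominance loci
  ($d = 0.08 \times$ baseline). Genotypic values follow the classical
  single-locus decomposition $(+a, d, -a)$ for reference-homozygote /
  heterozygote / alternate-homozygote, summed over loci. Overdominance is
  representable by $|d| > |a|$ at a locus.
* **Noise** is i.i.d. Gaussian per replicate with per-trait residual SDs
  calibrated so that population-level coefficients of variation land in
  the 10–40% range typical of developmental and yield traits in this kind
  of panel; no replicate-level dispersion figures are published for the
  motivating design, so this is a calibration to summary ranges, not to
  exact values. `target_h2` instead rescales the noise to hit a requested
  broad-sense heritability given the realised genotypic variance. There
  are no block, maternal/cytoplasmic or GxE effects: block effects are
  unidentifiable from published summary statistics, and the two real
  populations' environmental differences are exactly what the
  cross-population module measures rather than simulates.
* **Growth curves** are logistic in time with genotype-specific rate and
  asymptote (log-normal variation, CV 0.1), per-plant establishment-onset
  jitter (SD 1 day) and a hybrid onset advance of 3 days, matching the
  observed 2.5–5-day earlier detection of hybrid seedlings. The default
  asymptote (450 mm²) and 17-day series mirror rosette imaging up to the
  day leaves start to overlap.

Everything is deterministic given the configuration (including the seed);
the test suite asserts byte-identical regeneration.

What passing tests on this generator do **not** show: robustness to LD
structure, to non-Gaussian or heteroscedastic noise, to shared-environment
(block) correlation, or to the genotyping error and missingness patterns
of real SNP arrays. They do show that every formula, filter and model in
the pipeline recovers a known truth under its own assumptions.

## Growth-curve normalisation

Establishment ($t_0$) is assigned per plant to the first day projected
leaf area exceeds 2 mm² (the stage at which cotyledons emerge); sub-daily
series are collapsed to daily maxima first, because the rule is phrased in
days. The plain first-crossing rule is used even for noisy, non-monotone
curves — a `confirm = k` option requires k consecutive days above the
threshold instead. The same 2 mm² threshold doubles as the camera
"visible plant" criterion in `establishment_fraction()` (configurable, as
the real detection limit of an imaging rig may differ). MPH over time is
computed from genotype-mean areas at shared offsets, either on raw
days-after-sowing or after re-indexing each plant to days since its own
$t_0$; the t0-normalised mode removes pure establishment-timing shifts
exactly (a property the tests check on noise-free curves), so remaining
MPH reflects growth-rate/size differences.

## Numerical and inferential conventions

* Spearman correlations use average ranks for ties and the two-tailed t
  approximation for p-values; matrix cells need at least 3 complete pairs
  (pairwise, not listwise, deletion). Matrix p-values are unadjusted by
  default; `bh_fdr()` can be applied to the long export if desired.
* Kinship is used directly as a similarity. In the genetic-distance
  analysis a *negative* MPH-vs-kinship coefficient therefore means more
  heterosis for more distant parents. Degenerate inputs (constant MPH)
  return an undefined coefficient with p = 1 by convention.
* The best-parent test defaults to Welch's two-sample t-test, since
  replicates of different genotypes are not naturally paired; a paired
  mode (pairing by replicate index) is also computed and reported, as the
  motivating analysis describes a paired test without stating the pairing.
  Identical replicate vectors return p = 1; noise-free constant separation
  returns p = 0.
* Mean $MPH_{ABS}$ inference on a common-reference panel must account for
  the shared reference parent: every hybrid's $MPH_{ABS}$ contains
  $-\tfrac12 \times$ the same reference-mean sampling error, so hybrid
  records are positively correlated and a naive one-sample t-test is
  anti-conservative. The validation suite uses a z statistic whose null
  variance includes the shared term.
* `MPH` is undefined (NA) when the mid-parent value is zero; $MPH_{ABS}$
  is still reported. Exact duplicates of a SNP column tie in the scan and
  are reported jointly rather than arbitrarily broken.

## Problem sizes used in validation

The packaged validation runs use panels of 100 accessions × 1,000 SNPs ×
10 replicates for type-I and power checks (50 seeded repetitions for
power), 100 × 10 for heritability recovery, 200 hybrids for the
approximation-quality bound, and an 8-sample toy for the brute-force GLS
oracle — sizes at which every property is stable across seeds while the
whole suite runs in well under a minute per check.

## Known limitations

* No LD, recombination (F1s only), epistasis, or epigenetic effects in
  the generator; no d/a ratio estimation (the dominant and additive scans
  select largely disjoint SNP sets, so the ratio is not meaningful
  per-SNP).
* The kinship constructions (VanRaden-style standardized, and IBS) are
  documented substitutes for whatever matrix an external study may have
  used; results depending on fine kinship structure should be checked
  against the user's own matrix via the `kinship` arguments.
* Real supplementary phenotype tables come in heterogeneous layouts;
  `read_trait_table(dialect =)` covers column renaming and missing-value
  tokens, and treats pooled measurements as single replicates with $H^2$
  undefined.
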