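---
title: "Methods: growth-pattern phenotyping and pattern-coded association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth-pattern phenotyping and pattern-coded association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eafg)
```

## The problem

Faces change fastest between early childhood and the end of adolescence, and
individuals differ not only in how large a facial measurement ends up but in
the *direction and shape* of its change over time. `eafg` turns longitudinal
facial photographs into distance phenotypes, summarizes each person's
history of a measurement as one of five ordinal growth patterns, and tests
single-SNP association with that pattern code. Every stage is also available
against synthetic cohorts with known ground truth, because real cohorts of
children's photographs plus genotypes are ethics-restricted and cannot be
redistributed.

## Distance phenotypes

Each photo contributes 19 named 2D landmarks plus the left and right iris
centers. A measurement table (10 "horizontal" H1–H10 and 11 "vertical"
V1–V11 pairs) defines 21 Euclidean distances; each is divided by that
photo's interocular distance. The ratio cancels image scale and camera
distance, so phenotypes are invariant under translation, rotation and
uniform scaling (a property test applies random similarity transforms), and
the iris pair itself always equals exactly 1.

The exact landmark pairs behind the 21 published measurement names are not
enumerated in text form anywhere we could rely on, so the default table in
`default_measurement_table()` is a documented convention over standard
anthropometric points (eye corners and lids, nasion, pronasale, subnasale,
alae, lips, mouth corners, chin, hairline). A user with a different protocol
can load a replacement via `read_measurement_table()`; everything downstream
is driven by the table.

Coordinates are strictly planar. No lens, pose or perspective correction is
attempted; that matches the upstream measurement process this package
consumes (frontal, neutral-expression photographs).

## Measurement quality control

For each phenotype, all measurements — past and current photos pooled across
the cohort — are trimmed at the extreme 2% per tail (`trim_tails()`,
percentiles by linear interpolation, `stats::quantile` type 7). Values
*strictly* beyond the percentile are flagged, so boundary values survive and
at least 96% of records are always kept. Trimming flags single (person,
photo, phenotype) records, not whole photos. Two documented behaviors to be
aware of:

* trimming is **not idempotent** — re-running it on the kept values trims
  again;
* an alternative Tukey-fence mode (`method = "iqr"`, 1.5×IQR) is provided
  for comparison because "boxplot-based 2% trimming" conflates two methods;
  the explicit 2% percentile reading is the default.

## Growth trajectories and the five patterns

Records surviving QC are placed on relative age `t = age − current_age`
(current photo at `t = 0`; duplicate same-age photos are averaged). A
trajectory needs at least 3 observations including the current one;
otherwise it is reported as unclassifiable rather than failing the run. The
"non-linear model" is an ordinary least-squares quadratic — the lowest-degree
family whose endpoint slopes can realize all five shapes; with exactly three
points it interpolates.

Classification reads the fitted slopes `s = b1 + 2·b2·t` at the span's
endpoints. A slope is *flat* when the change it implies over the whole span
is below `eps_rel` (default 0.02) times the largest |fitted value| on the
span. Both slopes flat ⇒ CC; both non-flat ⇒ DD/DI/ID/II by sign; exactly
one flat ⇒ the sign of the fitted total change decides (flat total change ⇒
CC). Two consequences of this design are deliberate:

* a symmetric dip (decrease then full recovery) is **DI, not CC**, even
  though its net change is zero — the pattern taxonomy is about direction
  reversal, not net displacement;
* the flatness tolerance is relative to the measurement's magnitude, so
  classification is invariant to uniform positive rescaling (unit changes)
  but **not** to adding a large constant: a 2% band around a magnitude is
  only meaningful for positive, ratio-scale quantities like normalized
  distances.

`eps_rel = 0.02` is a tunable stand-in for the visual-inspection judgment
that originally defined the "constant" class; 2% of the measurement over a
~15-year span is our operationalization of "did not visibly change".

Patterns are coded DD=1, DI=2, CC=3, ID=4, II=5, and the code is treated as
a quantitative trait downstream. The code order is meaningful: on the
synthetic panel the mean fitted total change increases strictly from 1 to 5.

## Genotype quality control

`variant_stats()` computes call rate, genotype counts and MAF from called
genotypes only (missingness never imputes). `hwe_exact()` is a from-scratch
exact conditional Hardy–Weinberg test: given the minor-allele count, the
probability of each attainable heterozygote count is computed by the stable
ratio recurrence in log space, and the p-value sums all configurations no
more probable than the observed one (standard, not mid-p; a `midp` flag
exists because conventions differ). The test is validated exhaustively
against an independent enumeration oracle for every genotype triple up to
n = 50, and is conservative under simulated HWE, as exact tests are.

Filtering applies the boundary conventions literally: call rate **≥** 0.98,
MAF **≥** 0.10 (inclusive bounds), HWE p **>** 10⁻⁴ (strict). A SNP with
MAF exactly 0.10 is retained; one with HWE p exactly 10⁻⁴ is excluded.

## Association model

The pattern code is regressed on allele dosage (0/1/2) with intercept and
slope and *no covariates* (sex is deliberately absent: pattern distributions show no
sex difference in cohorts of this design). The Wald p uses the t
distribution with n − 2 df — the classic quantitative-trait `--assoc`
convention — and the likelihood-ratio statistic is `n·ln(RSS₀/RSS₁)` against
χ²₁. The two agree asymptotically (Spearman ρ > 0.99 under the null at
n = 272 in the test suite). Perfect fits are reported with the p-value
floored at the smallest positive double and flagged `degenerate`; monomorphic
dosages and constant phenotypes are flagged untestable rather than erroring.

The Bonferroni column is `p × 800,000` — the approximate genotyping-panel
size — and is intentionally *uncapped* so that null SNPs print values like
9.1E+03; published result tables use exactly this convention, and the
multiplier is configurable (the imputed-panel alternative, ~7.4M, can be
supplied). Tier boundaries are exact: `significant` iff p < 5×10⁻⁸,
`suggestive` iff 5×10⁻⁸ ≤ p < 10⁻⁵.

Tiered SNPs are grouped per chromosome by single linkage at a 500 kb window
(there is no canonical definition of "nearby"; the window is configurable). A
connected group is a *clustered locus* when some member has more than three
other tiered SNPs within the window — "more than three" is implemented
literally as ≥ 4 neighbors and is configurable — otherwise its members are
singletons sharing a group annotation. Replication selection requires
combined p < 10⁻⁵ and both cohort p < 0.05; beta-sign concordance across
the three analyses is reported alongside, not enforced.

An ordinal trait deserves an ordinal model; the linear coding is used
because it matches the classic quantitative-trait workflow this package
mirrors, and the latent-propensity
generator (below) is exactly the data-generating process under which a
linear dosage test of the code is well-posed.

## The synthetic-data module

The generator states a world matching the cohort design above and is used, not
tuned:

* **Cohorts** default to 172 (POP1) and 100 (POP2) individuals aged 18–20,
  each with 5–7 past photos (at least one per age band <5, 5–10, 10–15,
  15–20) plus a current photo.
* **Genotypes** are two independent allele draws per SNP at the specified
  MAF — HWE by construction — with independent missingness. SNPs are
  independent; linkage disequilibrium is not simulated.
* **Pattern codes** come from a latent propensity `Σ βⱼ·dosageⱼ + N(0,1)`
  cut at the empirical quantiles implied by per-phenotype marginal pattern
  frequencies. Default marginals are (0.1, 0.1, 0.1, 0.1, 0.6) — pattern 5
  dominant — with the eye-width phenotypes H1, H2, H4 reversed to pattern-1
  dominance, mimicking the published frequency structure qualitatively.
* **Trajectories** realize each code with a quadratic template over the
  person's photo span plus Gaussian noise (`noise_sd`, default 0.02
  normalized-distance units, a package-level choice of a plausible
  landmarking error, ~1–3% of typical measurement magnitudes). The DI/ID templates put their vertex at
  40% of the span from the present so that mean net change orders strictly
  across codes (−A < −5A/9 < 0 < 5A/9 < A); symmetric vertices would tie
  DI, CC and ID at zero. Default planted effects are ±0.8 per allele — at
  the default cohort sizes this gives planted signals that reliably clear
  the replication filter, which is what a positive-control panel is for.

What a green synthetic run does and does not establish: it shows the
pipeline recovers structure it is known to contain (planted codes from
noise-free trajectories with accuracy 1.0; planted effects inside their 95%
CIs with ≥ 90% coverage; same-marginal cohorts agreeing on ≥ 70% of modal
patterns) under the model's own assumptions — independent SNPs, Gaussian
noise, quadratic growth. It says nothing about landmark-detection error
structure, LD, population stratification or phenotype correlations in real
data.

Two honest calibration results from this stated world, measured during
development and deliberately *not* papered over:

* at measurement noise of 2% of the trajectory magnitude, classification
  accuracy is ~0.62, not ≥ 0.9: with only 6–8 photos, the quadratic's
  endpoint-slope noise (~0.008/yr) dwarfs the CC flatness band (~0.002/yr),
  so the constant class is essentially unrecoverable at that noise level.
  The suite asserts exact recovery at zero noise, ≥ 0.9 accuracy at 0.2%
  noise, and monotone degradation in between.
* a planted latent effect of 0.5 at MAF 0.4 clears the full replication
  filter in only ~53–77% of replicates (marginals-dependent) at n = 172+100;
  the power property is therefore asserted at the generator's default
  planted effect of 0.8, where selection is essentially certain.

## Numerical choices and degenerate inputs

* Percentile trimming uses strict inequalities at the boundaries.
* `hwe_exact` returns exactly 1 for monomorphic SNPs (single attainable
  configuration) and uses a `1 + 1e-10` relative slack when comparing
  configuration probabilities to the observed one, protecting ties against
  floating-point jitter.
* A quadratic fit requires ≥ 3 *distinct* relative ages; duplicates are
  averaged upstream, and an all-equal-age group is an assertion failure, not
  a silent NA.
* The flatness scale has a 10⁻⁸ floor so an all-zero trajectory classifies
  as CC instead of dividing by zero.
* Wald/LRT p-values are floored at the smallest positive double and flagged
  rather than reported as 0.
* Modal-pattern ties break toward the lower code and carry a tie flag.
* All randomness flows from one master seed through labelled sub-streams
  (`derive_seed`), so stages are independently reproducible and the whole
  pipeline is byte-identical under a fixed config + seed.

## Known limitations

Landmark detection itself (the image-processing step) is out of scope — the
package consumes coordinates. Genotype imputation, covariate adjustment,
mixed-model stratification control, gene annotation and regional plots are
likewise out of scope. The trait model treats an ordinal code as
quantitative; an ordinal-logit alternative would be the natural extension.
Cohort concordance is modal-pattern agreement only — a deliberate
operationalization of "the highest-frequency pattern replicated" — with a
per-phenotype chi-square distance reported for context but no formal test of
distribution equality.
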