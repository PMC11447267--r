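---
title: "Methods: sex-stratified EWAS of ART-conceived newborns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-stratified EWAS of ART-conceived newborns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Children conceived through assisted reproductive technologies (ART — in vitro
fertilization with or without intracytoplasmic sperm injection, with fresh or
frozen embryo transfer) show cord-blood DNA methylation differences relative
to naturally conceived children, and several of the health outcomes linked to
ART differ between boys and girls. `artewas` implements, as a tested and
reusable pipeline, a sex-stratified epigenome-wide association study (EWAS)
of array beta values together with a gene-level test of whether the ART
effect itself differs by sex. Because the motivating cohort data are
access-restricted, the package ships a synthetic cohort generator with known
ground truth; every stage of the pipeline is exercised and calibrated against
that generator.

# Per-CpG model

For each CpG $j$ and sex stratum, methylation beta values $y_{ij} \in [0,1]$
are modeled with a linear mixed model

$$ y_{ij} = \beta_0 + \beta_1 \,\mathrm{ART}_i + \gamma^\top x_i +
   u_{p(i)} + \varepsilon_{ij}, \qquad
   u_p \sim N(0, \sigma_u^2), \;\; \varepsilon \sim N(0, \sigma_e^2), $$

where $x_i$ holds maternal age, maternal smoking (four-level categorical,
reference "never"), maternal pre-pregnancy BMI and parity, and $u_{p(i)}$ is
a random intercept for the processing plate. Fitting is by REML through
`nlme::lme()`; the fixed-effect contrast $\beta_1$ (exposed minus reference;
positive = hypermethylated under ART) is tested with a two-sided Wald
statistic $\hat\beta_1/\widehat{se}$ referred to the standard normal. With
cohort-scale strata (hundreds to a thousand newborns) the normal and
$t$ references are practically indistinguishable; a `wald_ref = "t"` toggle
is provided for small strata. When only one plate level is present, or the
mixed fit fails, the model falls back to ordinary least squares on the same
design — in that case the estimate and standard error coincide with the
closed-form normal-equations solution, which the test suite asserts to six
significant digits.

The outcome is modeled on the beta scale (`transform = "beta"`, the
default). A `transform = "logit"` option fits logit(beta) instead (an
M-value-style analysis), which is also how the parameter-recovery checks
compare estimates against the generator's logit-scale truth without the
attenuation inherent in the beta scale.

Each model is complete-case: newborns missing any covariate in that model are
dropped from that model only. Probes with fewer than 10 usable observations,
a single exposure group, or a degenerate fit are reported with a
`skip_reason` and excluded from multiple-testing adjustment.

## Outlier masking

Before each fit, observations outside median $\pm k \cdot$ MAD are masked,
with $k = 5$ and MAD the *unscaled* median of absolute deviations from the
median (no 1.4826 consistency factor). Two deliberate conventions:

* **MAD = 0 masks nothing.** At a near-constant probe the literal rule would
  discard every value different from the median, which is not a defensible
  outlier definition; such probes are left intact.
* **The mask is recomputed within each analysis subset** (stratum and
  contrast), once per fitted model — a single-pass rule. Masking is *not*
  idempotent in general (re-masking the retained values can tighten the
  bounds), so the pipeline never iterates it.

Masking with $k=5$ on the unscaled MAD corresponds to roughly
$\pm 3.4\sigma$ under normality (masking $\approx 0.07\%$ of observations),
so null calibration is essentially unaffected.

## Multiple testing and contrasts

Benjamini–Hochberg q-values are computed within each stratum over exactly
the probes tested there, with a CpG-level significance threshold of
q < 0.01. Supported exposure contrasts: any ART vs natural conception,
fresh vs natural, frozen vs natural, ICSI vs natural, IVF vs natural,
ICSI vs IVF, and fresh vs frozen; the reference is the second-named group.
In the pipeline, subtype contrasts run only when both groups have at least
`min_subtype_n` (default 30) newborns, since tiny subtype groups yield
unstable fits and no power.

# ART-by-sex interaction

Three complementary views, mirroring how such interactions are usually
reported:

1. **Per-CpG interaction model.** The pooled-sexes mixed model adds sex and
   ART × sex fixed effects; the interaction coefficient is the difference in
   ART effects (boys minus girls).
2. **Per-gene sign counts.** For each gene, the signs of the per-CpG ART
   estimates are crossed with sex in a 2×2 table and tested with the
   Yates-corrected chi-square test of independence. An estimate of exactly 0
   counts as "+" (a probability-zero tie in continuous data, logged). A zero
   margin (e.g. all CpGs positive in both sexes) makes the test undefined
   and is reported as NA.
3. **Gene-level stacked test with block-wise permutation.** For genes with
   more than 20 CpGs with data, the gene's beta values are stacked in long
   format (one row per individual × CpG, individual covariates replicated).
   An OLS fit with CpG-specific intercepts plus covariates, ART, sex and
   ART × sex yields the interaction estimate and its naive t-statistic. The
   naive standard error ignores within-individual correlation, so inference
   is delegated entirely to a block-wise permutation: sex labels are permuted
   across individuals *within conception group*, each individual's whole
   block of rows moving together, and the statistic is recomputed; the
   empirical p-value uses the add-one rule $(1 + \#\{|T_b| \ge
   |T_{obs}|\})/(B+1)$. Gene-level empirical p-values are BH-adjusted at
   FDR 0.05.

Design choices made where the design was genuinely open:

* **Which labels move.** Permuting sex within conception strata preserves
  the ART margin and group sizes and targets the interaction (jointly with
  the sex main effect). This is an approximation to an exact interaction
  null; a Freedman–Lane variant (permuting individual-level residual blocks
  of the reduced model) is exposed via `scheme = "freedman_lane"`. The
  residual-block variant requires every individual to share the same
  observed CpG set — with MAD-masked cells the blocks are ragged and
  residual blocks are no longer exchangeable, so it errors and advises the
  label scheme. Neither scheme is asserted to be "the" original; both are
  calibrated under the null generator.
* **CpG-specific intercepts** in the stacked model remove between-CpG
  baseline differences that would otherwise dominate the stacked variance;
  `stack_model = "plain"` exposes the simple variant. With a single CpG the
  stacked fit reduces exactly to the plain interaction regression, which is
  tested.
* **Plate effects are omitted from the stacked model**; permutation blocks
  are individuals, so the permutation inference is robust to this omission.
* **B defaults to 999** permutations, minimum 99 enforced. The add-one rule
  bounds the smallest attainable empirical p at $1/(B+1)$; choose B
  accordingly for the FDR level in use.
* Internally the permutation loop residualizes the tested columns against
  the fixed design once per draw (a Frisch–Waugh–Lovell projection), which
  is algebraically identical to refitting the full OLS; the equivalence
  against `lm()` is asserted in the tests at $10^{-8}$.

# Distribution comparison and enrichment

The per-CpG mean difference (ART minus natural, within stratum, over
unmasked values) summarizes the genome-wide shift per sex; the girls' and
boys' difference vectors are compared with the two-sample
Kolmogorov–Smirnov test (exact sup-difference of the ECDFs, asymptotic
p-value). The per-probe pairing of the two vectors is ignored — the KS test
assumes independent samples — which follows the convention of reporting a
single distribution-level D between sexes and should be read descriptively.

Candidate-set enrichment (e.g. CpGs in genes linked to birthweight or
childhood cancer) is a one-sided Wilcoxon rank-sum test of the candidates'
$-\log_{10} p$ against the non-candidate background, accompanied by a
lambda ratio (median 1-df chi-square quantile of candidates over the
universe median) and QQ coordinates for both sets. This construction is this
package's formalization of "overrepresentation"; it is deliberately generic
and makes no claim to reproduce any specific published enrichment statistic.

# The synthetic generator

`generate_cohort()`, `generate_probe_annotation()` and
`generate_beta_matrix()` emulate the structure of a two-sex,
two-conception-group newborn cohort:

* roughly 1,000 newborns per sex with an ART fraction near one half, ART
  subdivided into fresh/frozen × IVF/ICSI subtypes plus an "unknown
  procedure" category with cohort-typical proportions;
* confounding of ART with maternal covariates: at `confounding = 1` ART
  mothers are on average 3.2 years older (with a tighter SD) and 23
  percentage points more often nulliparous, matching the direction and
  size of imbalance seen in registry-linked ART cohorts; `confounding = 0`
  makes ART independent of all covariates;
* baseline beta values from a bimodal mixture with modes near 0.15 and 0.85
  (logit-normal jitter, SD 0.5 on the logit scale), mimicking the
  methylated/unmethylated bimodality of array data;
* effects injected on the logit(beta) scale:
  $\mathrm{logit}(\beta_{ij}) = \mathrm{logit}(b_j) + \delta_{sex(j)}
  \mathrm{ART}_i + \gamma^\top x_i + u_{p(i)} + e_{ij}$, with plate SD 0.1
  and residual SD 0.4 on the logit scale, then mapped through the inverse
  logit so every value lies strictly in (0,1);
* small nonzero covariate effects by default (e.g. 0.005 logit units per
  year of maternal age) so that confounding adjustment is genuinely
  exercised rather than vacuously true.

Injecting on the logit scale guarantees the range constraint but means
beta-scale estimates are attenuated relative to the logit-scale truth;
recovery checks therefore either fit on the logit scale or compare against
a beta-scale oracle. A single seed drives everything; each generator
derives its sub-stream deterministically (cohort: seed, annotation:
seed + 1, matrix: seed + 2), so identical configurations are bit-identical.

What the generator does **not** emulate: probe-specific measurement error,
detection p-values, sex chromosomes, cell-type composition, spatial
correlation of neighboring CpGs beyond shared plate/individual effects, and
type I/II probe chemistry. Passing calibration and power suites therefore
demonstrates correctness of the statistical machinery under the stated
generative model, not robustness to every artifact of real array data.

# Calibration and test sizes

The test suite's calibration and power studies use sizes chosen to balance
Monte-Carlo resolution against a test suite that runs in minutes on a
single core:

* **Null calibration:** 20 seeds × 500 null probes at 200 newborns per sex
  (one stratum analyzed), pooled rejection rate at $\alpha = 0.05$ required
  to sit within binomial 99% bounds; BH discoveries at q < 0.01 across all
  seeds at most 3; gene-level empirical p-values from 200 replicate 25-CpG
  null genes, each drawn from its own independent cohort (B = 199), required
  to pass a KS test against uniform at the 1% level. The replicate genes must
  come from independent cohorts: genes sharing one cohort share its plate
  effects, which the stacked model deliberately omits, so their statistics
  are correlated and a KS test across them would over-reject even though
  each empirical p is marginally uniform (the label permutation is exact).
* **Recovery:** a logit-scale ART effect of 0.5 on 200 probes at 500 per
  arm, mean estimate within 10% of truth.
* **Power:** a 25-CpG gene with an interaction difference of 0.8 logit
  units among four null genes at 250 per sex × conception cell (B = 499)
  must reach gene-level q < 0.05 in at least 80% of 20 seeds.

`scripts/acceptance.R` re-runs scaled versions of these suites from scratch
and writes the resulting quantities as JSON.

# Degenerate inputs and numerical conventions

* Readers reject rather than coerce: out-of-range beta values error with
  probe/sample coordinates, unknown category labels error with row numbers,
  non-autosomal chromosomes are refused (the pipeline models autosomes
  only).
* Missing token is `NA` in all files; coordinates are 1-based, following
  array-manifest convention; multi-gene probes (`A;B`) count once in each
  listed gene in gene-level analyses and are flagged.
* Zero-margin contingency tables and all-missing vectors raise structured
  errors instead of returning NaN.
* REML (not ML) for variance components; fixed-effect estimates are
  insensitive to this in balanced designs, and it is the convention of the
  mixed-model practice this pipeline follows.

# Known limitations

* The Wald-normal reference is mildly anti-conservative in small strata;
  use `wald_ref = "t"` below a few hundred newborns per stratum.
* The stacked interaction estimate is a precision-weighted average over a
  gene's CpGs; a sign-balanced within-gene interaction pattern can cancel.
  The sign-count chi-square view is complementary precisely because it is
  scale-free per CpG.
* Empirical p-values are discrete on a $1/(B+1)$ lattice; BH over them is
  conservative for small B.
* No genomic-control correction, surrogate-variable adjustment, or robust
  variances; the generator's plate effect is the only batch structure
  modeled.
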