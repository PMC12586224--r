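---
title: "Methods: population tractography maps, passage fields and longitudinal models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population tractography maps, passage fields and longitudinal models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cctopo)
```

# The problem

Probabilistic tractography with a corpus-callosum (CC) seed and cortical
target regions yields, per scan and per hemisphere, a matrix of streamline
counts $p(v_i, b_j, s)$: how many sampled streamlines from CC voxel $v_i$
reached cortical area $b_j$ in scan $s$. Raw counts are not comparable across
voxels or scans (seeding density, local anisotropy and registration all scale
them), and single-scan, single-threshold maps are noisy. This package turns
a collection of such matrices into:

1. a **population map** $\dot P(v, b) \in [0, 1]$ per hemisphere — the
   fraction of (sample unit, threshold) pairs in which voxel $v$'s normalized
   connection probability to area $b$ exceeded the threshold;
2. **passage fields** — the bilateral CC cluster each cortical area projects
   through, with hole-free outer boundaries;
3. **symmetry fits** — voxelwise right-on-left regressions per area;
4. **longitudinal statistics** — linear mixed-effects (LME) models of field
   size and streamline density with sex/age fixed effects, subject random
   intercepts, and Benjamini–Hochberg (BH) false-discovery-rate control.

# The model, stage by stage

## Normalization

For each scan, each voxel's counts are divided by that voxel's total over all
target areas:

$$P(v_i, b_j, s) = \frac{p(v_i, b_j, s)}{\sum_j p(v_i, b_j, s)}.$$

The normalization is undefined at voxels whose total is zero. We set those
rows to zero and flag them (`zero_flags`), rather than dropping or imputing:
the map keeps its mass interpretation and downstream stages (notably the
symmetry regression) can exclude them explicitly.

## Multi-threshold binarization

$P$ is binarized at the five thresholds $\{0.100, 0.125, 0.150, 0.175,
0.200\}$ to avoid a single-threshold bias. The rule is strict: $\bar P = 1$
when $P > thr$, $0$ when $P < thr$, and — since strict inequalities leave a
gap — **equality maps to 0**, consistent with "1 only above the threshold".
Because ties occur in real data (normalized probabilities are rationals and
thresholds are decimals: $15/100 = 0.150$), thresholds are stored as scaled
integers and the comparison is evaluated on integer counts,
$p \cdot den > num \cdot \textstyle\sum_j p$, which is exact. No
floating-point tie can flip a voxel.

## Population averaging

$$\dot P(v, b) = \frac{1}{S}\frac{1}{M} \sum_{s=1}^{S} \sum_{m=1}^{M}
\bar P(v, b, s, thr_m),$$

with $S$ sample units and $M = 5$ thresholds. $\dot P$ is therefore an
integer multiple of $1/(S M)$, order-invariant over samples, and equal to the
exhaustive exceedance fraction (which the test suite checks against a double
loop oracle).

**Sample unit.** A longitudinal cohort pools repeated scans of the same
animals. The default treats *each scan* as one sample unit
(`sample_unit = "per_scan"`). The alternative (`"per_subject"`) first
averages the normalized maps within subject, then binarizes and averages
across subjects, so that heavily-rescanned animals do not dominate. Both
readings of "average over individuals" are defensible for an unbalanced
design; the choice is explicit, recorded in the manifest, and testable.

## Detectability

Three cut-offs classify each area from its population map pair:
`peak_high = 0.15` (a passage field has at least one voxel above this),
`peak_low = 0.08` (widespread-weak projections stay below this everywhere)
and `mean_min = 0.01` (minimum CC-wide mean for anything detectable). The
three cut-offs deliberately do not partition the plane — an area with a peak
between 0.08 and 0.15 falls through to `undetectable` — because the source
analysis used them as separate statements, not a single rule. All three are
exposed as criteria rather than reconciled silently.

## Bilateral parcellation

A voxel belongs to area $b$'s passage field when
$\dot P_L(v, b)\,\cdot\,\dot P_R(v, b) > 0.05^2 = 0.0025$. Requiring both
hemispheres suppresses unilateral noise. The inequality is strict, mirroring
the binarization convention; numerically, a relative guard of $10^{-9}$
excludes products that equal the threshold up to floating-point rounding
(population values are multiples of $1/(SM)$, so genuinely-above products
clear the guard by many orders of magnitude).

Boundaries are traced per 8-connected component (4-connected background, the
standard duality) with Moore-neighbourhood tracing, outer contours only:
interior holes produce no contour. The traced pixels are exactly the mask
pixels 4-adjacent to the component's outer background (grid edges count as
outside) — a set identity the suite verifies against an independent
flood-fill oracle on hundreds of random masks. All components of an area are
retained and reported (no largest-component rule is imposed).

**Per-scan field sizes.** Longitudinal field-size trajectories need a field
per scan. The default runs the full normalize–threshold–average pipeline
with $S = 1$ (that scan only) before the bilateral product; a
`per_age_group` mode instead pools all scans of an age into one population
map per age. The source procedure for age-resolved sizes is not documented;
both modes are provided and neither is claimed as "the" original procedure.

## Symmetry

For each area, voxels with a nonzero population value on either side (the
default inclusion rule; an all-voxels rule is available) enter an ordinary
least-squares regression of right on left with intercept. Adjusted $R^2$
uses $1 - (1 - R^2)(n-1)/(n-2)$ for the single predictor. An area is
*symmetric* when the slope lies in the closed band $1 \pm 0.5$ and adjusted
$R^2 > 0.7$ (floor strict, band endpoints inclusive — "$\pm$" reads as a
closed interval). Fits with fewer than 3 voxels or a constant predictor are
refused and reported as unfit, never silently fitted.

## Longitudinal statistics

Outcomes (field size in voxels; voxelwise or field-mean density) are
modelled as

$$y_{kt} = \beta_0 + \beta_{sex}\,\mathbb 1[\text{female}_k] +
\beta_{age}\,\text{age}_{kt} + u_k + \varepsilon_{kt},
\qquad u_k \sim N(0, \sigma_u^2),$$

fitted by maximum likelihood (`lme4::lmer`, `REML = FALSE`). Male is the
reference sex level; age is in months, linear and uncentered. Because age at
scan equals time since baseline, the age term is the longitudinal
trajectory, while the random intercept absorbs stable between-animal
differences — this is what makes the unbalanced design (different entry
ages, 1–4 scans per animal, dropout) usable without imputation.

**p-values.** The degrees-of-freedom convention for LME t-statistics is a
choice, not a given; we use the residual-df approximation
($df = n_{obs} - n_{fixed}$) and record `df_method = "residual"` in every
result. The type-I error calibration test (criterion 6) shows this is
accurate at the design sizes used here.

**FDR families.** BH correction is applied (a) across all areas jointly for
field-size models, one family per fixed term, and (b) across all voxels
within one area for voxelwise models, again per term. Family labels are
written into every report. Non-convergent voxel fits are excluded from the
family and counted, never imputed.

**Group swap.** `cc_group_swap()` relabels a chosen all-male subset as
female and re-runs the voxelwise sex analysis, reporting significant-voxel
counts and mean t for both labelings side by side. If a sex effect is
biological rather than a group/housing artefact, mislabelling dilutes it.

# The synthetic cohort generator

`cc_simulate_cohort()` emulates the study design the statistics are built
for: 66 subjects (46 male / 20 female) in three cohorts — A (22, entering at
12 months), B (12) and C (32, both entering at 6 months) — scheduled at ages
{6, 12, 18, 24} months with monotone per-interval dropout (default
probability 0.2 per interval; the first scheduled scan always happens).
These counts reproduce the emulated cohort structure; the dropout rate is a
realism choice, stated once here, that produces roughly the observed 2–3
scans per animal.

Expected counts are log-linear on smooth unimodal area templates:

$$\lambda(v, b \mid k, a) = r_b(v)\,
\exp\!\big(\beta_b (a - 6) + \gamma_b\,\mathbb 1[\text{female}] + u_k\big),$$

with the reference age at 6 months (study entry, so intercepts are
interpretable at baseline). Defaults plant negative age slopes
($-0.02/\text{mo}$) on frontal/limbic analogues (ORB, ACA, MO, RSP),
positive slopes ($+0.02/\text{mo}$) on somatosensory analogues (SSp-n,
SSp-bfd, PTLp), and a female excess ($+0.3$ log units) on the orbital-area
analogue — matching the directions the pipeline is meant to detect. The
48-area default world has 13 concentrated anterior–posterior-ordered passage
areas, 5 weak widespread areas and 30 background areas, with rates scaled so
the mean per-voxel streamline total is 5000 (a standard seeds-per-voxel
setting).

Counts are negative-binomial with variance $\mu + \phi\mu^2$
($\phi = 0.05$ by default), degenerating to Poisson at $\phi = 0$ and to
deterministic rounding under `noise_free`. Real probtrackx counts are
overdispersed in practice but no empirical dispersion is published; $\phi$
is a free parameter of the generator, not a claim about real data.
Left–right asymmetry multiplies right-hemisphere rates by
$(1+a)^{s(v)}$ with a smooth $s(v) \in [-1, 1]$, bounding the rate ratio in
$[1/(1+a),\, 1+a]$; $a = 0$ gives exactly shared rates.

**What a green test establishes — and what it does not.** The generator
produces the *structure* of the real data (unbalanced longitudinal counts,
topographic ordering, near-symmetry, planted effects) but none of its
*physics*: no diffusion signal, no fiber geometry, no registration error, no
spatially correlated noise, no scanner drift. Green acceptance criteria
certify that the pipeline's arithmetic, conventions and statistical
calibration are correct on data whose truth is known — they do not certify
the biological findings of any particular real dataset.

# Numerical choices

* Thresholds as scaled integers; binarization on integer counts (exact ties).
* Bilateral product with a $10^{-9}$ relative guard (exact-tie exclusion).
* Zero-total voxels flagged, zeroed, excluded from symmetry by default.
* BH q-values monotonized from the largest rank; flags come from the step-up
  decision, which the suite checks against a literal-definition oracle.
* LME fits that fail to converge are flagged/excluded, never imputed; the
  one-observation-per-subject limit reduces to OLS (tested).
* Determinism: every generator and pipeline artifact is a pure function of
  (inputs, config, seed); reruns are byte-identical (tested end to end).

# Scaling of the test suite

Simulation-heavy checks run at desk scale on one CPU: the end-to-end
determinism check uses a cohort scaled to ~5% of the full design on a
24×6 grid, and calibration simulations use 500/200/100 replicates as the
criteria state. Scaling down the cohort does not weaken what these
properties assert (identity, calibration, dilution); it only bounds runtime.

# Known limitations

* The pipeline starts at count matrices: no tractography, registration, or
  atlas handling is performed or emulated.
* The NIfTI-1 reader/writer is deliberately minimal (single-slice float32,
  little-endian) — an interchange convenience, not a general NIfTI library.
* Voxelwise LME treats voxels independently; no spatial model or
  autocorrelation correction is applied (matching the source analysis).
* The per-scan field-size mode with $S = 1$ uses a 5-threshold average of a
  single scan, so per-scan $\dot P$ takes only values $k/5$; field sizes are
  correspondingly quantized.
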