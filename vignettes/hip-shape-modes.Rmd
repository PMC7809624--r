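---
title: "Hip shape modes: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hip shape modes: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipmodes)
```

## The problem

Proximal femur shape is a heritable risk factor for hip osteoarthritis
and hip fracture. A standard way to quantify it from 2D hip DXA images is
a landmark-based statistical shape model (SSM): an expert places an
ordered set of 53 points outlining the femoral head, neck, trochanters
and shaft; generalized Procrustes analysis (GPA) removes location, size
and orientation; and principal component analysis of the aligned
configurations yields a small number of orthogonal "hip shape modes"
(HSMs), scored per subject in units of the training-sample standard
deviation.

A key analysis pattern in this field is *reference-model transfer*: a
shape model trained on one (typically adult) cohort is applied unchanged
to a second cohort, so that the second cohort's mode scores read as
deviations from the reference mean shape, in reference SD units, and
per-allele regression coefficients are directly comparable across
cohorts. This package implements that pipeline end to end — alignment,
model building, serialization, transfer scoring, candidate-SNP
association under several covariate models, and reconstruction of the
shape change implied by fitted effects — together with a fully seeded
synthetic-data generator, because the motivating cohort data (DXA scans
and genotypes) are access-controlled and no real data ship with the
package.

## Shape model

### Alignment

Each configuration $X_i \in \mathbb{R}^{53\times2}$ is reduced to a
*pre-shape*: the centroid is moved to the origin and the configuration is
scaled to unit centroid size ($\sqrt{\sum_l \|x_{il}-\bar{x}_i\|^2}=1$).
GPA then iterates two steps from the first shape's pre-shape: rotate
every pre-shape onto the current mean (closed-form 2D rotation
$\theta^\* = \operatorname{atan2}(\sum x y' - y x',\ \sum x x' + y y')$,
proper rotations only), and re-estimate the mean as the coordinate-wise
average re-normalised to unit size. Iteration stops when the mean moves
less than `tol` (default 1e-10, max 100 sweeps); the total Procrustes sum
of squares is non-increasing across sweeps. Reflections are never
allowed: left and right hips are not mixed, and mirroring, if needed,
must be done upstream.

The aligned frame is only defined up to one global rotation (initialised
from the first input shape). All downstream scores are invariant to this
frame; when two independently built models must be compared
vector-by-vector, `align_model_frame()` rotates one into the frame of
the other.

### Tangent coordinates and PCA

After rotation each pre-shape $p_i$ is *centrally projected* onto the
tangent hyperplane at the mean direction $\hat\mu$:
$q_i = p_i / \langle p_i, \hat\mu\rangle$, so that
$\langle q_i, \hat\mu\rangle = 1$ for every subject (Kendall
tangent-coordinate scaling). PCA is applied to the $q_i$ about their
sample average $c$ (the model `center`). This choice is deliberate and
load-bearing:

* the mode basis is exactly orthogonal to the mean direction, so no
  variance is parked in the direction that similarity alignment cannot
  distinguish from scale;
* training scores are exactly mean 0, SD 1 (SD uses denominator
  $n-1$; squared mode SDs equal the eigenvalues);
* linear reconstruction $c + \sum_k s_k\,\sigma_k m_k$ and projection
  are *exact* mutual inverses on the model span, at machine precision,
  which the test suite asserts at 1e-9.

With plain unit-size pre-shapes (no tangent scaling) those last two
properties fail at the order of the shape variance (~1e-3 here), because
re-normalisation moves reconstructed shapes off the model's affine span.
At the small shape variation typical of hip outlines the numerical
difference between the two conventions is otherwise negligible; we chose
the one under which the algebra is exact. The model stores both the
unit-size Procrustes mean (`mean_shape`, the rotation target) and the
tangent-plane average (`center`, the reconstruction base).

Mode signs follow a fixed convention (the largest-magnitude coefficient
of each mode vector is positive) so serialized models — structured JSON
with 17-significant-digit floats, hence bit-identical round trips — and
downstream betas are reproducible across runs. Ten modes are retained by
default, configurable.

### Reference-model transfer

`apply_shape_model()` aligns each new configuration *individually* to
the reference mean and standardises by the reference training SDs, never
the new cohort's. A new cohort's scores therefore have whatever mean and
spread they have — e.g. an adolescent cohort scored against an adult
model shows mean offsets of a couple of SD on some modes — which is the
analysis' point. The alternative reading (superimpose the new cohort by
its own GPA first, then rotate the block onto the reference) is
available as `method = "cohort_gpa"`; we default to individual alignment
because it makes each subject's score independent of cohort composition.

## Genetic association

Candidate SNPs pass quality control if minor allele frequency is at
least 1%, call rate at least 95%, and the exact Hardy–Weinberg test
gives p > 5e-7. The HWE test is the conditional exact test: given the
allele counts, the p-value sums the probabilities of all heterozygote
counts no more probable than the observed one; probabilities are
evaluated in closed form via log-gamma, and the suite checks every
configuration with n ≤ 50 against an independent recurrence oracle.
Hard-call dosage tables get their genotype counts tallied automatically;
fractional (imputed) dosages skip the HWE test with a warning.

Association uses ordinary least squares of one mode's scores on
(intercept, effect-allele dosage, covariates), with a two-sided Wald t
p-value on the residual degrees of freedom. Three covariate models are
fixed: model 1 = age + sex, model 2 = age + sex + height,
model 3 = age + sex + BMI (sex coded female = 0, male = 1; BMI derived
from height and weight when absent and cross-checked within
0.1 kg/m² when present). OLS substitutes for the original pipeline's
score test; at cohort sample sizes the two are indistinguishable, and
the package's acceptance surface is parameter recovery, not test-statistic
equality. Multiple testing uses a plain Bonferroni threshold
$\alpha/n_{tests}$; 0.05/8 = 0.00625, conventionally displayed as 0.006.
Look-up tables against a published adult panel flag, per SNP×mode row,
significance per timepoint, direction consistency with the adult beta,
and "weak evidence" (consistent direction with p < 0.1 at either
timepoint).

## Shape rendering

`mode_outline_pair()` reconstructs the outlines at ±c SD along one mode
(c = 2 by default, the conventional visualisation), solid for +, dashed
for −. `composite_effect()` reconstructs the outline implied by a set of
per-allele betas, each multiplied by an illustrative scale (default 20 —
per-allele effects of ~0.05 SD would otherwise be invisible). The scale
is recorded on the output so exaggerated outlines cannot be mistaken for
physical effect sizes. Our convention multiplies each beta by the mode
SD (betas are in SD units); the original plotting software's convention
is not documented, so ours is declared here and in the output metadata.

## Synthetic data: what it emulates, and what a green test proves

The generator builds a stylised but geometrically valid 53-point femur
outline (fixed coordinates, verified non-self-intersecting), a smooth
random orthonormal 10-mode basis orthogonal to the similarity subspace
at the template (so Procrustes alignment cannot absorb planted
variance), and cohorts in which

* true scores are $z_k = \text{offset}_k + \sum_j \beta_{jk} g_j + e_k$,
  with residual SD set so the total score SD is ≈ 1;
* landmarks are the template plus $\sum_k z_k \sigma_k m_k$ in the
  tangent plane, plus iid landmark noise, then a random rigid +
  positive-scale nuisance transform;
* genotypes are drawn in Hardy–Weinberg proportions at the configured
  effect-allele frequencies, and covariates from sex-stratified normal
  distributions matching a mid-adolescence DXA clinic
  (age 13.8 ± 0.2 y, height 163.5 ± 7.6 cm, weight 54.6 ± 10.9 kg,
  52% female; an "age18" preset mirrors the late-adolescence clinic);
* a truth ledger records every subject's true scores, genotypes and
  nuisance transform, bit-reproducibly from (config, seed).

Stated-world defaults: cohort n = 3550; three planted SNPs echoing
published adult loci (EAF 0.35 with betas −0.054 on mode 1 and −0.072 on
mode 5; EAF 0.24 with +0.05 on mode 1; EAF 0.38 with −0.063 on mode 2);
cohort mean offsets +2.3, +0.6, −1.2 on modes 1, 2, 5. Where no source
stated a value we chose once and documented here: total raw shape
variance 0.002 in pre-shape units (shape displacements a few percent of
configuration size); landmark noise SD 5e-4 pre-shape units (sub-pixel
digitisation error, ~1% of the shape variance); nuisance rotation ±10°,
scale ±10%, translation ±0.5 output units, mean centroid size 500
(pixel-like); height–weight correlation 0.5. The relative mode variances
(0.315, 0.19, 0.1509, 0.1198, 0.0951, 0.045, 0.033, 0.024, 0.016,
0.0112) put 60% of variance on modes 1 + 2 + 5 while keeping adjacent
eigenvalues ≥ ~20% apart, so that each eigenvector is identifiable from
a few-thousand-subject training set; a near-degenerate spectrum would
make per-mode recovery tests meaningless regardless of implementation
quality. Longitudinal cohorts share genotypes and a latent score
component sized so the cross-timepoint score correlation equals the
requested ρ exactly (genetic sharing included; for ρ below the planted
genetic covariance the latent weight floors at zero).

What the generator does *not* emulate: real DXA image noise structure,
growth-related non-linear shape change, scanner pixel-spacing artefacts,
relatedness and population structure, imputation uncertainty. A green
end-to-end test therefore establishes that the pipeline's algebra and
statistics are correct under the stated generative model — not that the
published cohort estimates would reproduce on real data, which are
access-controlled and out of scope.

## Numerical choices and degenerate inputs

GPA convergence is the Euclidean norm of the mean update, tol 1e-10,
max 100 sweeps (non-convergence returns a flagged result with a
warning). Zero centroid size, wrong point counts, non-finite
coordinates, dosages outside [0, 2], an effect allele matching neither
VCF REF nor ALT, constant dosages and collinear designs are hard errors
naming the offender. Tangent projection refuses configurations at ≥ ~84°
from the reference mean (inner product < 0.1) — far beyond any real hip
outline. Monomorphic SNPs get HWE p = 1. Ties in the HWE tail sum use a
1 + 1e-10 relative tolerance, the standard guard against floating-point
ties. `count_significant` treats missing timepoint p-values as
non-significant rather than dropping rows; unmatched look-up rows are
kept and flagged `missing`.

## Known limitations

2D landmarks only; no sliding semi-landmarks or missing-landmark
imputation; no genome-wide scanning, relatedness or ancestry adjustment;
no meta-analysis machinery; the cross-scanner aspect-ratio offset on
mode 1 discussed in the source literature is treated as a property of
the data, not corrected. The adult discovery estimates enter as a
shipped look-up fixture; the adult GWAS itself is not re-run.
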