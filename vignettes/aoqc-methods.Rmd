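---
title: "Grading AO-FIO image quality: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading AO-FIO image quality: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aoqc)
```

## The problem

Flood-illumination adaptive optics ophthalmoscopy (AO-FIO) resolves the
cone photoreceptor mosaic in the living retina, but image quality varies
widely — with defocus, fixation, media clarity, retinal disease and
position in the mosaic — and every quantitative cone metric depends on
first deciding which sampling windows are analyzable.  `aoqc` implements
a three-grade quality scale over 50 × 50 µm sampling windows
(65 × 65 px at the default pixel scale):

* **category 1** — more than 5% of the window is truncated (it overlaps
  the edge of the stitched mosaic); unusable because features are
  missing;
* **category 2** — at most 5% truncation, but cones cannot be resolved
  in at least one quadrant; unusable because of poor quality;
* **category 3** — cones visible in all quadrants; analyzable.

The boundary is strict on the truncation side: exactly 5% truncation is
*not* category 1.

Two automated graders are provided, together with the manual-grading
machinery (adjudication, Cohen's kappa, confusion matrices, subject-wise
cross-validation) needed to validate them, and a logistic-regression
analysis of the factors that drive poor quality.

## The LAPE focus operator

The energy-of-Laplacian (LAPE) focus measure treats sharpness as the
energy of the second spatial derivative.  A patch \(I\) is first
normalized for brightness — multiplicatively rescaled so the mean over
*imaged* (non-blank) pixels equals 0.5 — then convolved with the 5-point
discrete Laplacian

\[
L = \begin{pmatrix} 0 & 1 & 0\\ 1 & -4 & 1\\ 0 & 1 & 0 \end{pmatrix},
\]

and the score is the mean of the squared response over interior pixels,
scaled by a fixed calibration constant:

\[
\mathrm{LAPE}(I) = \frac{c}{|\Omega|} \sum_{(i,j)\in\Omega}
  \bigl[(L * \tilde I)_{ij}\bigr]^2 .
\]

Design choices a user should know about:

* **Kernel.** The 5-point Laplacian is the canonical kernel for this
  operator; the 8-neighbour variant is available via `kernel = "lap8"`.
* **Boundary rule.** The energy is accumulated over valid interior
  pixels only; no padding is invented, so scores are comparable across
  implementations that state the same rule.
* **Brightness normalization** is multiplicative mean-matching, the
  simplest reading of "normalized for brightness", and it makes the
  score exactly invariant to global illumination scaling.  The
  reference mean is computed over pixels \(> 0\): mosaic compositors
  write exact zeros outside coverage, and including them would make
  truncation *inflate* the score of whatever remains.
* **Calibration.** The operator's working range on calibrated AO-FIO
  patches is 0–75, but no published definition of the scaling exists.
  The package therefore fixes a single constant
  (`lape_calibration()`, default 750) chosen so that sharp, fully
  resolved synthetic mosaics score near the top of that range (raw
  interior energies of pristine fixtures measure about 0.026–0.096 per
  pixel across the 1–10° spacing range).  Only the *ordinal* behaviour
  of the score is meaningful across instruments; absolute values should
  not be compared against other implementations.

Under Gaussian defocus the score decreases monotonically on cone
mosaics, which is the property the classifiers exploit.

## Grade classifiers on the LAPE axis

Two multiclass schemes turn a score into a grade:

* **Linear-regression rounding** (`fit_linear_model()`): ordinary least
  squares of the numeric grade (1, 2, 3) on the score; prediction
  rounds the fitted value to the nearest grade (half-integers round
  half-up, a deterministic convention) and clamps to 1–3.  The score
  values where the fitted line crosses 1.5 and 2.5 are the implied
  category boundaries and are exposed as `implied_thresholds` —
  rounding a linear fit forces these boundaries to be symmetric about
  the score mean, which is worth remembering when comparing them with
  threshold pairs obtained any other way.
* **Random forest with probability-curve thresholds**
  (`fit_random_forest()`, 1,000 trees, ranger engine, probability
  mode): class probabilities are evaluated on the working grid 0 to 75
  in 0.1 steps (751 points), each class's curve is loess-smoothed
  (span 0.3 over the grid; the span is exposed because no standard
  value exists), and the two cut points are placed where the smoothed
  curves intersect — the first score where the grade-2 curve rises
  above grade 1's, and the last where grade 3's rises above grade 2's,
  keeping the three bands contiguous.  Scores exactly at a cut fall
  into the middle band, consistent with strict outer bands.

Training and validation are always split **by subject**, never by
patch: patches within an eye share optics and fixation, and a
patch-wise split would leak that correlation into the validation set.

### Planted-threshold simulation

`simulate_lape_scores()` draws class-conditional Gaussian scores
(sd 3, class mix 25/50/25 mirroring the clinical dominance of grade 2)
whose prior-weighted density crossings sit exactly at the planted cut
points: anchoring the grade-1 mean at 0 (truncated patches are the
darkest) and solving the two crossing equations gives means
(0, 16.75, 52.91) for the (8, 35) band.  Because the population-optimal
boundaries *are* the planted cuts, a well-calibrated classifier should
recover them; the test suite checks the forest to ±2 score units and
the linear model's implied boundaries to ±3.

## The compact CNN grader

The second automated grader is a small CIFAR-style convolutional
network implemented natively in R (batched im2col + BLAS matrix
multiplication, verified against finite-difference gradients):

* input 65 × 65 grayscale, per-patch z-scored; larger inputs are
  center-cropped, smaller ones reflection-padded (`condition_input()`,
  idempotent at the target size, odd deficits padded bottom/right);
* three convolution blocks (8, 16, 32 filters, 5 × 5 kernels, ReLU,
  2 × 2 max-pool), a dense ReLU layer of width 64 and a 3-way softmax
  (~50k parameters) — ample capacity for 3-way grading of 65 px
  patches while training on one CPU in minutes, and fully
  config-driven so alternatives swap without code change;
* SGD with momentum 0.9, learning rate 0.01, batch 32, inverse-
  frequency class weights (the clinical grade mix is 20/56/24), and a
  subject-wise monitoring slice recorded every epoch;
* fully deterministic under the config seed (no framework
  nondeterminism: all randomness flows through R's RNG).

## Agreement machinery

`adjudicate()` reduces multiple graders' labels to a reference
standard: unanimity or majority wins; a full three-way split falls to
the designated senior grader.  The clinical reference process resolves
such splits by facilitated discussion, which is not computable, so the
senior-grader rule is an explicit stand-in — `on_split = "flag"`
returns `NA` instead so such patches can be routed to manual review.

Cohen's kappa is unweighted by default (no weighting is standard for
this grading scale, despite its ordinal nature); linear weights are
available.  Identical constant raters are defined to agree perfectly
(kappa 1) rather than erroring on the degenerate chance term.

## Factors behind poor image quality

`fit_quality_logistic()` fits poor (grade 2, coded 1) versus
analyzable (grade 3) by maximum likelihood on the joint covariate set:
healthy-vs-diseased, eccentricity (degrees, pooled over meridians as a
single linear term), age, axial length, spherical equivalent, visual
acuity and fixation stability (BCEA63).  Truncated grade-1 patches
carry no usable features and are excluded.  Odds ratios are reported
with Wald 95% intervals.  Patches within a subject are treated as
independent — mirroring the plain clinical analysis — which understates
standard errors when within-subject correlation is present;
`cluster_se = TRUE` provides sandwich-by-subject errors as the
statistically safer alternative, off by default as a deliberate
fidelity/validity trade-off.

## The synthetic cohort generator

No AO-FIO dataset is publicly deposited, so validation runs on
synthetic mosaics with planted ground truth (`generate_patch()`,
`generate_cohort()`):

* **Cone placement**: hexagonal lattice at the requested spacing with
  ±20% uniform jitter and a minimum centre-to-centre distance of half
  a spacing — quasi-regular mosaics without a packing simulation.
  Spacing grows with eccentricity (≈ 2.8 + 0.5 µm/degree).
* **Cone rendering**: isotropic Gaussian reflexes, FWHM 0.6 × spacing,
  lognormal amplitudes with CV 0.2–0.45 (the Stiles–Crawford-driven
  variability of cone reflectance).
* **Defocus** is applied analytically — spot and PSF widths add in
  quadrature and the spot integral is preserved — so blur trades peak
  contrast for width exactly as a Gaussian optical model predicts.
* **Noise** is mild (σ 0.005–0.03 of full scale): each clinical
  acquisition averages 40 registered frames.
* **Truncation**: a blank strip from the left edge of the planted area
  fraction, entered through a 4-px vignetting taper; mosaic edges fade
  out rather than ending in a step.  Category-1 patches are also drawn
  defocused (PSF 1.5–3.5 µm): mosaic edges are edge-of-field optics.
* **Unresolvable quadrants**: cone amplitudes scaled by 0.05 and blur
  doubled in the degraded quadrant.  The contrast level at which a
  human grader stops calling cones resolvable is unknown, so the 0.05
  factor is exposed as configuration.  A global blur limit of 2.5 µm
  (Rayleigh-like, given the instrument's ~2 µm resolving limit) marks
  a patch unresolvable even with all quadrants intact.
* **Covariates**: subject biometry is drawn per study group
  (healthy / post-macular-surgery distortion / hydroxychloroquine
  toxicity) from the groups' published means and SDs; grade-1 hits
  occur at their marginal rate independently of covariates (truncation
  is a mosaic-geometry artifact), while grade 2 vs 3 follows the
  planted logistic model (defaults: disease OR 5.2, 1.03 per degree of
  eccentricity, 1.03 per year of age) with the intercept calibrated so
  the overall mix matches the requested proportions.

Category 2/3 blur ranges deliberately overlap (0.2–0.9 µm for grade 3;
1.0–2.5 µm, or > 2.6 µm without quadrant damage, for grade 2), which
reproduces the clinically observed overlap of focus scores between
those grades: a global score cannot tell "one dead quadrant, rest
sharp" from "uniformly mediocre", while an image-based classifier can.
That asymmetry — not any tuning — is why the CNN outperforms the
LAPE-threshold classifiers on held-out subjects.

**What the simulator does not emulate**: vessel shadows, rods and
retinal pigment epithelium texture, debris, wavefront-aberration
residuals, temporal frame sequences, and the instrument's true
(unpublished) LAPE scaling.  Passing recovery tests on these mosaics
therefore demonstrates that the *algorithms* are implemented correctly
and behave as designed, not that the specific clinical accuracy figures
would be reproduced on real data.

## Geometry

Retinal magnification uses Bennett's adjusted Littmann method,
\(q = 0.013063\,(AL - 1.82)\) mm/degree; the default pixel scale
50/65 ≈ 0.769 µm/px makes a 50 µm window exactly 65 px and is rescaled
per subject by \(q(AL)/q(24.0)\).  The boundary value \(AL = 1.82\) mm
is accepted (returning \(q = 0\)) and anything smaller is a domain
error.  The standard sampling grid is the foveal centre plus integer
eccentricities 1–10° on the four principal meridians (41 loci); each
locus contributes five overlapping windows (`Mid`, `TL`, `TR`, `BL`,
`BR`), the corner windows displaced diagonally by a configurable
offset, 25 µm by default (the displacement is not standardized; half a
window gives 25% area overlap with `Mid`).

## Numerical conventions and degenerate inputs

* Coordinates are 0-origin-at-top-left, row-major; lengths in µm.
* Blank (outside-mosaic) pixels are exact zeros; the blank threshold
  is configurable for formats with a noise floor.
* All-blank patches raise a degenerate-input error from the scorer —
  they should be caught by the truncation rule first.
* Rounding of half-integer grades in the linear classifier is half-up;
  max-pool ties take the first maximum; both fixed for determinism.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; identical seeds give bit-identical patches,
  cohorts, forests and networks.

## Problem sizes used in the validation suite

The shipped tests validate on desk-scale problems chosen to exercise
every code path with stable statistics: a 38-subject rendered cohort
(1,520 patches, balanced grade mix) for the classifier-ordering and CNN
recovery experiments; 3,000 simulated scores for threshold recovery;
100 replicates of a 200-subject metadata-only cohort (8,000 patches
each) for factor-model coverage; 10,000 labels for chance-level kappa.
The clinical-scale analysis (50 subjects, 10,250 patches, 41 loci per
eye) runs through exactly the same interfaces via `generate_cohort()`
and `pipeline_run()`.

## Known limitations

* The CNN architecture is a faithful compact stand-in, not a
  reproduction of any specific published network, and trained weights
  are not shipped.
* The linear classifier's implied boundaries are structurally
  symmetric about the mean score; comparing them with
  intersection-derived thresholds conflates two different estimators.
* Odds-ratio recovery assumes the logistic model that generated the
  data; on real cohorts, within-subject correlation calls for the
  cluster-robust option.
* LAPE values are calibration-relative; only orderings and
  band-relative comparisons transfer across instruments.
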