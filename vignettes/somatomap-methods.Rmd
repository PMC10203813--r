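---
title: "Methods: simulating and analysing active vs. passive digit maps in SI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing active vs. passive digit maps in SI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somatomap)
```

## The scientific question

Primary somatosensory cortex (SI) contains an ordered map of the hand: the
five digits D1 (thumb) to D5 (little finger) are represented along the
dorsomedial–ventrolateral axis. Digit maps can be measured with fMRI either
by *active* tasks (the participant moves one digit at a time) or *passive*
tasks (an experimenter stimulates each digit). `somatomap` implements, over
synthetic data with known ground truth, the complete comparison of the two:
where the digits sit (spatial overlap), how orderly the map is (somatotopic
index), how selective each digit's cortical territory is (neighbourhood
relationships), how distinct the multivoxel digit patterns are
(representational similarity analysis, RSA), and which simple input-level
manipulation — a global gain or inter-digit enslavement mixing — can account
for differences between tasks (a five-unit cortical model).

Every stage consumes data the generator in this package can produce, so the
whole pipeline is testable end to end without any acquisition: parameter
recovery, unbiasedness and ordering properties are all checked against the
generating model.

## The generative model

A cortical "sheet" is a set of nodes with positions $x \in [0,1]$ along the
dorsomedial–ventrolateral axis. Each digit $e$ has a Gaussian spatial field

$$f_e(x) = a_e \exp\{-(x - c_e)^2 / (2 w_e^2)\},$$

and the true mean activity pattern evoked by moving/stimulating digit $d$ is

$$\mu_d(x) = g \sum_e E_{de}\, f_e(x),$$

where $g$ is a task-level **gain** and $E$ a nonnegative, diagonally
dominant **enslavement** matrix mixing the pooled per-digit inputs (the
involuntary co-activation of non-target digits). Run-level beta estimates
add i.i.d. Gaussian noise per node; GLM residuals are drawn with the same
per-node variance so that residual-based prewhitening is consistent with the
beta noise; z-maps are the true patterns scaled by the nominal across-run
standard error ($\sigma/\sqrt{n_\text{runs}}$) plus unit sampling noise.
An optional *double thumb* adds a second D1 field beyond D5, a common
feature of real hand maps.

Defaults, and why:

* **centers** 0.1, 0.3, 0.5, 0.7, 0.9 — five equally spaced fields spanning
  the hand area.
* **field width** 0.07 axis units. No empirical value exists for the width
  of a single-digit field on this normalised axis; it was calibrated once so
  that the default cohort's neighbouring-digit Dice overlap is ≈ 0.3, the
  regime where all three overlap classes (same/neighbour/non-neighbour) are
  well separated, and then frozen.
* **noise_sd** 0.2 per run against unit field amplitude: with four runs per
  task this puts peak z-statistics around 10–15, typical of a strong 7T
  digit localiser.
* **gains** active 1.5 vs passive 1.0 in the default cohort, emulating the
  higher overall activity of active tasks.
* **cohort** 15 participants, four runs per task, 200 nodes. Participants
  share the group geometry with small jitter (centers ± 0.015, log-normal
  width/amplitude jitter of 10%) so group statistics have realistic
  between-participant variance.
* **travelling-wave localiser** 8 s blocks, five digits per 40 s cycle,
  five cycles, TR 2 s, forward and backward runs, BOLD noise SD 0.5
  (signal-to-noise 2 at unit response).

What the generator does *not* emulate: 2-D/folded surface geometry,
physiological (temporally correlated) noise, mechanoreceptor-level
transduction, and attention or reward effects. Passing tests therefore show
the *analyses* are correct and well calibrated under their stated
assumptions, not that real cortex behaves like the generator.

## Travelling-wave cluster localisation

The reference bank contains 20 models: an 8 s on / 32 s off boxcar shifted
by 2 s lags across the 40 s cycle, tiled over cycles, convolved with the
canonical double-gamma HRF. Convolution is circular (cycles repeat without
rest, so the steady state wraps). Each node is correlated with all 20
models; r-values are Fisher z-transformed *before* averaging (averaging raw
r is biased); the four lags per digit are averaged; backward runs reverse
the digit-to-lag mapping, not the lag order, and the two directions are
averaged — which cancels a common haemodynamic delay, as a shift test
verifies. The winner digit takes the node; exact ties (measure zero under
continuous noise) go to the lower digit. Per digit, one-sided p-values from
the normal approximation $z\sqrt{n-3}$ on the averaged z are
Benjamini–Hochberg corrected across nodes at $q < 0.01$; only winners
surviving FDR for their winning digit become cluster members. Because the
averaged-z statistic pools eight correlated correlations, its null variance
is below $1/(n-3)$ and the procedure is conservative — Monte-Carlo tests
confirm the false discovery proportion stays far below $q$.

## Spatial overlap

Digit z-maps are thresholded at $Z > 2$ (strict inequality) within the hand
mask, and overlap is quantified with the minimum-normalised Dice
coefficient $|A \cap B| / \min(|A|, |B|)$, which scores 1 when one
representation is contained in the other; the traditional
$2|A \cap B| / (|A| + |B|)$ is available as a variant and is never larger.
An empty thresholded map yields `NA`, not 0 — zero would assert evidence of
non-overlap from no data. Cells are grouped into same digit
(diagonal), neighbours (|digit difference| = 1) and non-neighbours (≥ 2,
with D1–D5 treated as non-neighbours in the main analysis), and the
same > neighbour > non-neighbour ordering is tested with one-sided paired
t-tests at a Bonferroni-adjusted α = .025 for the two planned comparisons.

## Somatotopic index

Each node's digit preference is the z-weighted mean of digit identity 1–5
(z of 3 for D2 and D3 and 0 elsewhere gives 2.5); negative z-values are
clamped to zero first, and all-zero nodes are excluded. Preference is
correlated with axis position using the Jammalamadaka–SenGupta circular
correlation, with circular means computed by the arctangent of summed sines
and cosines.

Angle mapping is the one genuinely open design choice. Digit identity maps
to $2\pi(d-1)/5$ — one digit step = 72°, so D5 is adjacent to a wrapped D1,
encoding the double-thumb topology that motivates circular statistics.
Positions map onto the D1..D5 *arc*, $2\pi \cdot 4/5$ over the observed
range, with the remaining fifth of the circle left as the wrap gap through
which a second thumb returns to D1. Mapping positions onto the full circle
instead makes both angle sets nearly uniform, their circular means
degenerate (near-zero resultant vectors with inconsistent directions), and
the correlation unstable — on canonical noise-free somatotopic data it even
flips sign. Under the arc mapping, noise-free recovery gives
$r_\text{circ} \approx 0.98$, and on double-thumb maps circular scoring
beats the Pearson correlation of raw index against position, which is the
stated reason for using circular statistics in the first place. Both
mappings and the negative-weight handling are implementation constants
documented here rather than user options, since all cross-task comparisons
use the same convention.

## Neighbourhood relationships

Within each localiser-defined cluster, per-digit activity versus rest is
averaged over runs and member nodes, then all cells of a participant (both
tasks) are shifted by subtracting the participant's minimum, in that order
— the shift precedes the ratios exactly as the analysis prescribes, and a
test asserts the pipeline order. Selectivity ratios per cluster are
(target − mean(neighbours)) / target and the non-neighbour analogue; edge
clusters C1 and C5 have a single neighbour, interior neighbours are
averaged *before* the ratio, and D1–D5 are non-neighbours by default (a
flag wraps them for the double-thumb variant). Inference is a 2
(neighbourhood) × 2 (task) repeated-measures ANOVA computed from paired
contrasts — exact for a 2×2 within design, and cross-checked in tests
against `aov()` with an error stratum — followed by four Wilcoxon
matched-pairs signed-rank tests (exact distribution for n ≤ 25, normal
approximation with continuity correction above) at Bonferroni-adjusted
α = .0125, plus Shapiro–Wilk screening (reported, never used to switch
tests) and a paired t-test of overall mean activity between tasks.

## Crossnobis RSA

Activity patterns are prewhitened with the inverse matrix square root of
the node-wise residual covariance, shrunk towards its diagonal with the
analytic Schäfer–Strimmer intensity (clamped to [0,1]; `lambda = 0`
disables shrinkage, and eigenvalues are floored at $10^{-10}$ of the
maximum to tolerate degenerate nodes). The cross-validated squared
Mahalanobis distance between digits $i,j$ averages
$(b_{iA} - b_{jA})\cdot(b_{iB} - b_{jB})$ over all unordered run pairs
$A \ne B$ and divides by the node count, making distances mask-size
invariant. Because the two factors carry independent noise the estimator is
unbiased — zero expectation for identical true patterns, negative values
possible — which the test suite verifies against a brute-force double-sum
oracle and a 1,000-simulation null.

Information content is the mean of the 10 inter-digit distances. Under pure
gain modulation distances scale as $g^2$ (patterns scale linearly, the
distance is quadratic): a doubled active gain exactly quadruples
information content while leaving the *shape* of the RDM — and therefore
typicality — untouched, reproducing in simulation the joint finding of
higher active information content with shared representational structure.
Typicality is the Pearson correlation (Spearman behind a flag) of a
participant's 10-vector with the leave-one-out group mean of normalised
RDMs; RDMs are normalised by the root-mean-square of their off-diagonal
before averaging (mean and max normalisation available) so dissimilar
participants do not dominate the mean. Participants whose within-task
typicality falls more than 3 SDs below the group mean are excluded and the
statistics recomputed. Note an arithmetic bound: the most extreme of $n$
values can lie at most $(n-1)/\sqrt{n}$ SDs below the mean, so the 3σ rule
cannot fire for $n \le 10$; at the default cohort size of 15 it can.

MDS is visualisation only: classical scaling of each participant's RDM
(negative entries clipped to zero for embedding only), Procrustes
rotation/reflection and translation — no scaling — onto the first
participant's configuration, then averaging, with output axes ordered by
between-digit variance. Five points embed exactly in four dimensions; the
2-D projection preserves most, not all, of the structure (fidelity
correlations ≈ 0.92 at k = 2 vs ≈ 0.999 at k = 4 on smooth cohorts).

## The five-unit cortical model

SI is reduced to five units, one per digit cluster, with lateral weights
$W$ (self-excitation on the diagonal, signed off-diagonal interactions) and
pooled peripheral input $u_d = g \cdot (E_{\cdot d} \odot s)$ for
stimulation of digit $d$, where $s$ are per-digit input magnitudes. The
source account gives no explicit unit equations, so the simplest form
consistent with "units exciting or inhibiting each other" is used: a linear
recurrent steady state $r = (I - W)^{-1} u$ (requiring spectral radius
< 1), with optional output rectification solved by damped fixed-point
iteration. In the linear regime superposition holds exactly, and a pure
gain change scales all responses — and hence predicts an RDM scale factor
of exactly $g^2$ — without changing the normalised response shape.

Fitting is bounded least squares on the selected free parameters
(L-BFGS-B, 20 seeded multi-starts by default, instability penalised), and
the hypothesis comparison fixes the passive fit and frees, in turn: the
gain scalar; a typical-enslavement mixing strength (plus gain); or the five
digit-specific input scales. On targets built with digit-specific
distortions (thumb input reduced, D2–D3 increased) the gain-only and
enslavement-only hypotheses are left with losses more than an order of
magnitude above the digit-specific fit, while a purely gain-scaled target
is fully explained by gain with the $g^2$ RDM ratio — the model-level
dissociation between univariate and multivariate task differences. The
"typical" enslavement matrix shipped with the package is a synthetic
stand-in built from qualitative constraints (thumb most independent, ring
and little finger least; coupling decays with distance); any measured
matrix can be supplied instead.

## Problem sizes and numerical choices

The test suite and analysis scripts use cohorts of 15 participants, 120–200
nodes, four runs per task, and 100-timepoint localiser runs; oracle
equivalence is checked on 100 random small instances at tolerances
$10^{-10}$ (crossnobis) and $10^{-12}$ (circular correlation); null
calibration uses 200–1,000 seeded simulations. All randomness descends from
explicit integer seeds (per participant and stage in the pipeline), and
reports are byte-identical across repeated runs of the same configuration.

## Known limitations

The 1-D sheet ignores cortical folding and geodesic area; noise is
temporally white, so prewhitening is exercised only spatially; the
localiser's block timing is idealised (no jitter, no rest); z-maps are
contrast-vs-rest (a digit-vs-other-digits contrast would be needed for a
loader of real GLM outputs); and the synthetic typicality (~0.4 under
default jitter and noise) is deliberately lower than the ~0.9 seen in
high-quality 7T cohorts — the generator trades realism of absolute values
for controllable ground truth on the properties the tests assert
(orderings, scalings, calibration).
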