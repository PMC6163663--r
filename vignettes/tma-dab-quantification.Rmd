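---
title: "Two-threshold DAB quantification and biomarker evaluation on tissue microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-threshold DAB quantification and biomarker evaluation on tissue microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmaquant)
```

## The measurement model

Tissue-microarray (TMA) cores stained with the DAB chromogen are bright
where there is no tissue (glass and unstained stroma), darker where
hematoxylin-counterstained tissue sits, and darker still where the
antibody has deposited brown DAB. `tmaquant` quantifies one core image
by converting it to an 8-bit intensity map and applying **two pixel
value thresholds**:

* `AmtT` — the number of pixels strictly darker than the tissue cutoff
  `t_tissue` (any non-background pixel);
* `AmtS` — the number of pixels strictly darker than the signal cutoff
  `t_signal` (DAB-positive pixels).

Because `t_signal <= t_tissue`, the signal mask nests inside the tissue
mask, and the per-core expression statistic is the area fraction

$$\mathrm{ratio} = \frac{\mathrm{AmtS}}{\mathrm{AmtT}} \in [0, 1].$$

"Strictly darker" reflects the physics of chromogenic slides: the
background is bright, so tissue is whatever falls below the cutoff. A
core with `AmtT = 0` carries no information and is flagged invalid
rather than given a ratio of zero; invalid cores are retained in the
quantification table and excluded from every downstream statistic.

Grayscale conversion defaults to the unweighted channel mean
(`mean_rgb`, rounded half-up), matching the plain 8-bit conversion of
common image-analysis tools; a BT.601 luma mode is available by flag.
Which convention the original macro-based workflows used is generally
not recorded, so the choice is surfaced as an explicit, persisted
parameter rather than hidden.

## Threshold training

One threshold pair is trained **per antibody** on a labelled training
subset (by default a seeded random draw of 10 high-risk and 10 low-risk
cores) and then applied unchanged to every core stained with that
antibody. Training is an exhaustive grid search over
`(t_tissue, t_signal)` with `t_signal <= t_tissue` at a 5-intensity-unit
step. For each candidate pair the training cores' ratios are regressed
by ordinary least squares on the binary group indicator, and the pair
maximising the **regression slope** — the between-group difference in
mean ratio, in ratio units — is selected; ties go to the lowest
`t_signal`, then the lowest `t_tissue` (a 1e-9 tolerance keeps the
tie-break stable against floating-point noise). The selected pair's
R² on the training cores is reported as `fit_score`.

Two design points deserve emphasis, because the obvious alternative
fails:

* **Why the slope and not R².** R² is scale-free. A candidate pair
  whose two cutoffs both fall inside a single intensity population
  (both inside the DAB class, or both inside the background tail)
  produces a ratio that is almost constant across cores; its tiny
  residual variation is pure counting noise, yet under max-selection
  across the ~1,400 candidate pairs such noise reaches R² of 0.5 and
  more against 20 training labels — comfortably beating genuinely
  informative pairs, whose R² is bounded near 0.25 by the biological
  within-group variation at realistic effect sizes. Selected that way,
  thresholds measure noise and cohort-level discrimination collapses to
  chance (we observed exactly this during development). The slope is
  measured in ratio units, so degenerate near-constant candidates score
  ~0.01 while informative pairs score ~0.15; selection becomes robust
  without any change to the regression model itself.
* **The tissue-validity floor.** A pair under which some training core
  has only a handful of "tissue" pixels produces a wildly unstable
  ratio for that core. Candidate pairs are therefore excluded when any
  training core's tissue count falls below `min_tissue_fraction`
  (default 5%) of its pixels — a lenient bound, given that a TMA core
  disc occupies roughly 60% of its exported image. This generalises the
  hard rule that pairs leaving a training core with zero tissue pixels
  are excluded. Set `min_tissue_fraction = 0` to keep every non-empty
  pair.

On noise-free three-class images the procedure provably returns a pair
from the optimal box between the class intensities with
`fit_score = 1`, and the test suite verifies this against brute-force
grid enumeration. With permuted labels the returned pair is unstable
across seeds and `fit_score` collapses — documented behaviour that the
suite also asserts.

## Statistical evaluation

Per marker, the evaluation of valid cores comprises:

* **Mann-Whitney U test** of HR vs LR ratios, with mid-ranks for ties.
  When $\binom{n_1+n_2}{n_1} \le 184{,}756$ (e.g. 10 + 10) the
  two-sided p is exact, by full enumeration of label assignments and
  doubling of the smaller tail (capped at 1) — the convention of common
  diagnostic software; otherwise a normal approximation with
  tie-corrected variance and a 0.5 continuity correction is used.
* **Empirical ROC** with HR as the positive class and "ratio greater
  than criterion" as the positivity rule; one operating point per
  distinct cutoff plus the trivial endpoints.
* **AUC** by the pair-counting (Mann-Whitney) identity with ties
  counted ½. Standard errors by **DeLong** placements (default) or the
  **Hanley–McNeil** closed form with intermediates $q_1 = a/(2-a)$,
  $q_2 = 2a^2/(1+a)$; the latter is retained because legacy software
  output may reflect it. At chance level with 10 + 10 observations the
  closed form evaluates to $\sqrt{1.75}/10 \approx 0.132$.
* **Youden operating point**: the cutoff maximising $J = se + sp - 1$,
  ties broken toward higher specificity, then higher criterion — in
  screening-adjacent use a more specific cutoff is the safer default.
* **Likelihood ratios** $LR^+ = se/(1-sp)$, $LR^- = (1-se)/sp$ at the
  Youden point, with boundary infinities flagged rather than raised,
  and **post-test probabilities** through pretest odds. A pretest
  probability must be supplied by the caller: none is baked in, because
  the appropriate figure depends on the clinical population and
  published pipelines of this kind do not state the one they used.
* **Logistic combination** of two (or more) markers by binomial
  maximum likelihood (IRLS via `stats::glm`, likelihood tolerance
  1e-8, 50 iterations), reporting the share of cores correctly
  classified at probability 0.5 and the AUC of the fitted
  probabilities. Quasi-separation is detected when any |coefficient|
  exceeds 20 (log-odds per unit ratio); the model is then flagged
  unconverged and coefficients are withheld rather than reported at a
  runaway optimum.

Cores are the default unit of analysis; `evaluate_marker(unit =
"patient")` first averages each patient's valid cores for a
conservative alternative, since cores within a patient are correlated.
No multiplicity correction is applied to the primary p-values across
markers (matching practice in this kind of evaluation study);
`marker_report_table(bonferroni = TRUE)` annotates Bonferroni
significance without altering them.

## The synthetic cohort generator

No public TMA image set with matched risk groups exists at the scale
this pipeline targets, so the package ships a generator that emulates
the cohort design statistically: `n_pairs` matched patient pairs (one
high-risk, one low-risk, sharing a simulated Gleason sum), several
tumour cores per patient, one image per core. Defaults mirror the
design the pipeline is meant for: 41 pairs (82 patients) by 4 cores,
256-pixel images with a 230-pixel core disc as a desk-scale stand-in
for 40x-scanned 0.6 mm cores.

Per-core ground truth is a DAB-positive area fraction drawn
hierarchically **on the logit scale** — patient effect
(`patient_sd = 0.6`) around the group mean, core effect
(`core_sd = 0.4`) around the patient — which keeps fractions in
\[0, 1\]. The group means (`dab_fraction_hr = 0.30`,
`dab_fraction_lr = 0.15`) and those spreads were fixed once so that the
theoretical per-core AUC,
$\Phi\!\big(\Delta_{\mathrm{logit}}/(\sigma\sqrt{2})\big) \approx 0.81$
with $\sigma^2 = 0.6^2 + 0.4^2$, sits at the magnitude a strong
immunohistochemistry marker reaches in practice. The hierarchy itself
is an assumption: real per-core signal distributions are not published
for this design, and logit-normal is the natural minimal choice.

Rendering uses three intensity classes — background 250, hematoxylin
tissue 150, DAB 60 (sd 3/10/10) — coloured by fixed hue templates
(hematoxylin-blue, DAB-brown) whose channel weights average to one, so
the unweighted grayscale mean of a noise-free pixel equals its class
intensity exactly and the ordering invariant
background > tissue > DAB survives conversion. DAB-positive pixels are
spatially clustered by thresholding a smooth random field inside the
tissue disc at exactly the target count, so the realised area fraction
matches the drawn truth to within one pixel; clustering makes images
look like stained tissue but cannot bias an area-based statistic.
Ground truth is written to a separate `truth.csv` and never enters the
inference path.

What the generator does **not** emulate: staining chemistry and its
artefacts (edge effects, uneven DAB deposition), optical blur,
out-of-focus cores, folded or torn tissue, and genuinely non-disc core
shapes. Passing tests therefore demonstrate that the measurement and
statistics machinery is correct and well calibrated under the stated
model — not that the pipeline is robust to every failure mode of real
slides.

## Numerical and reproducibility choices

* All randomness is seeded: the cohort is a pure function of its
  config; every core image has an explicit per-core seed and the
  renderer refuses to run on ambient RNG state. Datasets round-trip
  bytewise through PNG (TIFF on request).
* `run_pipeline()` consumes each stage's output through its declared
  file interface (CSV/JSON), so running the stages individually from
  the command line reproduces a `run-all` byte for byte; the run
  manifest echoes the full configuration and seeds.
* Exact Mann-Whitney enumeration is capped at
  $\binom{n_1+n_2}{n_1} = 184{,}756$; comparisons on mid-ranks use a
  1e-9 tolerance so tied doubles compare exactly.
* Degenerate inputs have defined behaviour throughout: empty cores are
  flagged; single-group inputs error; `sp = 1` or `sp = 0` flag
  infinite likelihood ratios; an infinite likelihood ratio posts a
  probability of 1 with a flag; all-identical samples give p = 1 at
  the null U.

## Problem sizes used in the shipped checks

The packaged demo configuration runs 6 pairs by 2 cores at 96 pixels
with two markers — small enough to finish in seconds while exercising
every stage. The test suite's calibration checks use 600 simulated
null cohorts of 164 cores per arm (the check's own Monte-Carlo error,
about 0.9%, then sits well inside the 5% ± 3% band it asserts), and the
effect-recovery checks use the full 41-pair by 4-core design with
binormal scores tuned to a theoretical AUC of 0.80. These sizes are the
package's own choices for tight, informative checks.

## Known limitations

* A single global threshold pair per antibody cannot adapt to
  core-to-core staining variation; that is inherent to the method being
  implemented, not to this implementation.
* Empirical AUC on cores ignores within-patient correlation; its SE is
  therefore optimistic when cores cluster strongly. Patient-level
  aggregation is provided as the conservative option.
* With 10 + 10 training cores the trained thresholds remain variable
  across training draws even with slope-based selection; at realistic
  effect sizes the resulting cohort-level AUC is nonetheless
  indistinguishable from the AUC at the generative thresholds in our
  checks, because the ratio at any class-respecting pair is a monotone
  transform of the underlying DAB fraction.
* Likelihood-ratio figures computed at the Youden point need not match
  ranges quoted from auxiliary cutoff tables elsewhere; where published
  summaries mix the two, the Youden-point values are the reproducible
  ones.
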