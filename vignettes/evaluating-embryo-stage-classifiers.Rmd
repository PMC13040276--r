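---
title: "Evaluating embryo stage classifiers: accuracy, agreement, and explanation overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating embryo stage classifiers: accuracy, agreement, and explanation overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryoxai)
```

## The problem

Time-lapse incubators image preimplantation embryos continuously, and both
clinical embryologists and convolutional networks are asked to label each
frame with a developmental stage: 2-cell, 3-cell, 4-cell, 5-cell, 8- or
9-cell, morula, blastocyst. A model can look good on accuracy alone while
behaving very differently from a human panel, so a credible evaluation
needs three axes at once:

1. **Accuracy** against a reference standard, overall and per stage, with
   confusion matrices to locate the errors;
2. **Agreement**, chance-corrected, between every pair of raters and
   models and across the human panel as a group;
3. **Interpretability**, both as expert judgement of where a saliency map
   (Grad-CAM) points, and as the spatial overlap between two independent
   explanation methods (Grad-CAM and LIME) for the same prediction.

`embryoxai` implements this battery as composable, tibble-first functions,
plus a synthetic-data module that generates rater tables and explanation
overlays with known ground truth, so every stage of the pipeline is
testable without clinical images or a trained network.

## Ordinal coding

Stages are coded 1–7 in developmental order, with the 8-cell and 9-cell
stages merged into one class (code 5), because these are graded as one
class in clinical practice and are frequently confused with each other.
`encode_stage()` normalizes short names (`t2` … `t9`, `tM`, `tB`), full
names, and numeric codes; `t8` and `t9` both map to 5.

```{r}
encode_stage(c("t2", "t8", "t9", "tM", "tB"))
```

## The synthetic rater model

Real per-frame labels from clinics are rarely shareable, so the generator
defines the study conditions explicitly. A `rater_profile()` has a
per-stage probability `a_s` of labelling a frame of true stage `s`
correctly. Errors follow a geometric decay over ordinal distance: the
probability of labelling stage `j != s` is proportional to
`rho^(|j - s| - 1)`. Small `rho` concentrates errors on ordinally adjacent
stages — the dominant error pattern for embryologists and networks alike.
The default `rho = 0.25` puts roughly 76–86% of the error mass on adjacent
stages, depending on the true stage's position in the coding; there is no
published generative model for this error structure, so the geometric
form is the package's own choice, selected as the simplest one-parameter
family with the right qualitative behavior.

Because the whole generator is a known probability model, two things are
available in closed form and are used as test oracles:

* the analytic confusion matrix `rater_confusion()`, against which
  empirical per-stage accuracy converges at the binomial rate; and
* the population quadratic-weighted kappa between two independent raters,
  `expected_pairwise_kappa()`, computed from the joint cell probabilities
  `P(i, j) = sum_s pi_s C1[s, i] C2[s, j]`.

The default study size mirrors the scale of a realistic independent test
set: 245 frames from 31 embryos over the 7 stages. Per-stage frame counts
of such test sets are rarely published, so the generator defaults to
equal counts (35 per stage); both are configurable.

## Agreement statistics

**Quadratic-weighted Cohen's kappa.** For raters on an ordinal scale the
package uses weights `w_ij = 1 - (i - j)^2 / (K - 1)^2` over the full
`K = 7` coding, `kappa = (p_o - p_e) / (1 - p_e)` with weighted observed
and chance agreement. A useful algebraic fact: the weight denominator
cancels between `1 - p_o` and `1 - p_e`, so the estimate is invariant to
it — computing every table on the full 7×7 coding changes nothing for
tables that use fewer categories, while keeping stage-specific subgroup
values comparable across stages. The standard error is the
Fleiss–Cohen–Everitt large-sample estimate; the 95% interval is Wald,
clipped to `[-1, 1]`; the p-value tests `H0: kappa = 0` with the
null-variance form. Published agreement tables rarely state which
interval method was used, so exact bit-matching of third-party intervals
is not a goal; the estimate itself is checked against a brute-force
evaluation of the defining formula to 1e-12 in the test suite.

**Stage-specific agreement** filters frames by *reference* stage while
leaving the raters' labels free over 1..7. Within such a subgroup one
category dominates by construction, chance agreement is high, and kappa
can legitimately come out negative — that behavior is intentional and
tested.

**Fleiss' kappa** summarizes a panel of three or more raters, with the
Fleiss–Nee–Landis asymptotic standard error used for both the interval
and the p-value. With two raters the package refuses and points to
Cohen's kappa.

**Cochran's Q and McNemar post-hocs.** Per-frame correctness of all
raters forms a frames × raters boolean grid; Q tests equality of the
marginal correctness rates (`df = raters - 1`). Two edge cases are
distinguished deliberately: a grid where every cell is identical carries
no information about rater differences *or* agreement structure and is a
degenerate error, while a grid whose columns are identical but whose rows
vary yields `Q = 0, p = 1`. Pairwise follow-ups use McNemar's test on the
discordant counts `(b, c)`: exact two-sided binomial when `b + c < 25`,
continuity-corrected chi-squared otherwise (no single variant is standard
in the applied literature; the exact test is preferable exactly where the
approximation is weakest). All pairs from one call form a single Holm
family.

**Proportion comparisons** use the Pearson chi-squared test without
continuity correction, matching the default output of the major
statistical packages for 2×2 proportion comparisons, with a Fisher exact
fallback whenever an expected *or observed* cell drops below 5 — the
observed-cell clause covers degenerate tables (e.g. one group all-good,
the other all-poor) where the asymptotic statistic is formally computable
but poorly calibrated.

**Wilcoxon matched-pairs signed-rank** drops zero differences, mid-ranks
ties, and uses the exact signed-rank distribution for 25 or fewer
non-zero differences without ties, otherwise the normal approximation
with tie and continuity corrections. The signed-rank sum `W` (positive
minus negative rank sums) and the median difference are reported
alongside the p-value, as agreement studies conventionally quote `W`.

## Explanation overlays and masks

**Grad-CAM rendering.** A ground-truth attention field in `[0, 1]`
(`attention_field()`: a radial disc or a clipped sum of Gaussian blobs)
is mapped through a jet-style scale — blue (240°) through cyan (180°),
green, yellow to red (0°) — and alpha-blended (default 0.5) over neutral
gray. Because gray is achromatic, blending preserves hue, which is what
makes the contributive region recoverable by segmentation afterwards.
Optional achromatic background noise exercises robustness without
touching hue.

**The relevance cutoff of 0.25** makes the truth mask and the hue
segmentation agree by construction: relevance maps to hue as
`240°(1 - v)`, so `v >= 0.25` is exactly the set of pixels with hue at or
below 180° — the point where the scale leaves blue. This is the boundary
the mask-extraction step is defined to recover: contributive hues span
cyan through red (default ranges `[0°, 180°]` and `[330°, 360°]` for the
red wrap), blue is non-contributive, and saturation/value floors (0.20 /
0.15) exclude the gray background. All thresholds sit in a `hue_config()`
and are overridable; 8-bit quantization moves hues near the boundary by
less than the round-trip tolerance.

**LIME rendering and filling.** Positive superpixel regions are drawn as
pure yellow boundaries (the boundary is etched inside the region by
erosion, so the filled result matches the region exactly). Extraction
detects yellow (hue 45–75°, saturated, bright), closes contour gaps up to
2 px with a morphological closing, fills every closed contour
(`EBImage::fillHull`), and merges everything into one mask — nested
contours therefore fill to the outer region. A boundary clipped by the
image border is not closable and stays unfilled; the generator keeps
regions inside the frame. An image with no yellow at all yields an empty
mask with a warning, not an error, since "no positive region" is valid
LIME output.

**IoU.** `iou()` counts intersection and union pixels; an empty union is
reported as IoU 0 with a degenerate flag rather than NA, consistent with
how stage-wise medians of 0% are conventionally reported. Stage-wise
summaries use the median of percent IoU with the distribution-free
order-statistic 95% interval (ranks from `Binomial(n, 1/2)`); below
`n = 6` no such interval with 95% coverage exists inside the sample and
the bounds are reported as undefined. Paired model comparisons per stage
reuse the package's own signed-rank test on frames scored under both
models. Each model's IoU pairs its own Grad-CAM with its own LIME output.

The round-trip guarantees — Grad-CAM render→extract IoU ≥ 0.95 and LIME
≥ 0.90 against the constructed truth across a fixed set of ten seeds —
are enforced in the test suite and recomputed by the acceptance script.

## Focus ratings

Experts rate each Grad-CAM image as "good", "intermediate" or "poor"
spatial focus. Panel consensus is majority vote with ties resolved toward
"intermediate" (panels describe consensus discussions, not algorithms, so
the rule is explicit and a strict-consensus alternative is provided).
`rating_proportions()` aggregates per model and stage;
`accuracy_by_focus()` crosses ratings with classification correctness,
flags cells below 5 frames as too small to test, and compares the
remaining rating groups with the package's proportion test. The simulator
draws ratings independently of correctness, making it a null model: the
test suite verifies that no spurious focus–accuracy association is
detected under that null.

## Pipeline and reproducibility

`run_pipeline()` executes ingest/simulate → encoding → accuracy and
confusion → the agreement battery → focus analysis → overlay rendering,
mask extraction and IoU, and returns a bundle with a provenance block
(config hash, seed, package version). One integer seed drives every
random draw through isolated RNG scopes; no global state is consumed or
left behind, and identical config plus seed gives byte-identical JSON
reports. Inside the pipeline, overlays are rendered at 112×112 for a
4-frames-per-stage subset by default — overlap statistics are
resolution-stable well below the full 224×224, and the smaller default
keeps a full run in seconds; both knobs are in the config, and the
renderer itself defaults to 224×224 (500×500 is supported for
source-resolution work).

Statistical problem sizes used by the test suite and acceptance script —
200 random tables for the formula oracles, 1,000 replicates for the
type-I-error checks, 5,040 rows for closed-form kappa recovery, 200
frames per stage for accuracy recovery — were chosen once as the smallest
sizes at which the Monte-Carlo bounds in use (3 standard errors) are
meaningful.

## What the synthetic data does and does not show

The generator reproduces the *structural* features the statistics react
to: ordinal adjacent-stage error concentration, per-stage accuracy
levels, panel-versus-model contrasts, and explanation pairs whose overlap
degrades by stage and model. It does not attempt embryo-image realism: no
cytoplasm texture, no fragmentation, no focal-plane stacks, and LIME
regions are geometric discs rather than true superpixels. Passing tests
therefore demonstrate that the statistical machinery is correct and that
mask extraction inverts the renderer's conventions — not that any
particular clinical claim holds, and not that the hue thresholds are
optimal for overlays rendered by other software (they are configurable
for that reason). Rater labels are also drawn independently across raters
given the true stage; real raters share systematic biases, which inflates
observed agreement relative to this model.

## Known limitations

* Kappa intervals are asymptotic (Wald); they degrade near the `[-1, 1]`
  boundary and for very small subgroups, which is precisely where
  stage-specific values are reported with wide intervals.
* The exact signed-rank path requires tie-free differences; heavily tied
  IoU distributions always take the corrected normal approximation.
* Contour filling assumes boundaries closable within the configured gap;
  pathologically fragmented boundaries fill partially.
* Masks of differing sizes are rejected rather than resampled; resampling
  is deliberately out of scope for the comparison path.
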