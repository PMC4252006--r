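---
title: "From DAB intensity to categorical pathology scores: methods and design notes"
author: "ihcscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From DAB intensity to categorical pathology scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcscore)
```

## The problem

Pathologists communicate immunohistochemistry (IHC) results on ordinal
scales — for HER2 the familiar 0/1+/2+/3+ grades — while image analysis
yields continuous staining intensities. `ihcscore` implements a statistical
bridge between the two: it models the distribution of DAB (3,3'-diamino-
benzidine) staining intensity in a calibration field as a mixture of three
Gaussian components (weak, moderate, strong staining) and places the
category boundaries where adjacent component densities cross. Unlike
membrane-completeness scorers, the approach uses intensity statistics only,
so it applies to nuclear markers (ER, PR, Ki-67, p53) as well as membrane
markers (HER2).

All intensities in this package live on the **white pixel intensity** scale
of a single deconvolved stain channel: 0–255 with 255 meaning no stain and
low values meaning dark, strong staining. Thresholds are written t0
(background cutoff), t1 (strong/moderate) and t2 (moderate/weak), with
0 < t1 < t2 < t0 ≤ 255.

## Stain separation

Brightfield stains attenuate light multiplicatively, so they add linearly
in optical density, OD = −log10(I/I0). Per pixel we solve

    M c = OD,

where the columns of M are unit-norm OD triplets of hematoxylin, DAB and a
residual channel (defaults: the published H-DAB vectors, H = (0.650, 0.704,
0.286), DAB = (0.268, 0.570, 0.776); the vendor software used in practice
does not publish its vectors, so M is a configuration item). The residual
column defaults to the per-channel complement sqrt(1 − h² − d²), which keeps
M well conditioned (condition number ≈ 4.7); a cross-product residual is
nearly collinear with hematoxylin and would amplify quantization noise
roughly 50-fold. Each stain concentration c is mapped back to white
intensity w = 255·10^(−max(c, 0)) — the exact inverse of the OD transform
for a single stain — so the channel histograms keep 0–255 semantics.

Numerical choices: the log guard is ε = 1/255 (one quantization step);
negative concentrations, which arise from noise, are preserved in the
concentration images for diagnostics and clipped only at the white-intensity
conversion.

## Background threshold t0

t0 separates stained from unstained pixels. The default is Otsu's method on
the 256-bin histogram: the integer threshold maximizing between-class
variance, computed exhaustively over all 255 candidate splits. Exact ties —
plateaus across empty bins — break toward the smallest threshold (a
relative tolerance of 1e-10 makes the tie rule robust to floating-point
noise). A fixed override (`t0 = 230`, a conventional cutoff for DAB images)
bypasses the computation. On whole-field histograms dominated by very dark
and very bright mass, Otsu may prefer to isolate the darkest pixels rather
than split stain from background; the fixed cutoff is the predictable
choice for calibration work, and is the default in the worked examples.

## The mixture model and the category thresholds

Positive-pixel intensities (values ≤ t0) are modeled as

    f(x) = Σ_s π_s N(x; μ_s, σ_s),  s = strong, moderate, weak,

with k = 3 components, matching the three-level clinical vocabulary. The
fit is maximum likelihood by expectation–maximization:

* **Initialization** is 1-D k-means seeded at the k evenly spaced data
  quantiles, then Lloyd iterations. This makes the default fit fully
  deterministic — no random restarts unless explicitly requested.
* **E step**: responsibilities r_is ∝ π_s N(x_i; μ_s, σ_s).
  **M step**: weighted means/variances and mixing fractions.
* **Convergence**: |Δ log-likelihood| < 1e-6 or 500 iterations. The
  log-likelihood is non-decreasing at every step and the trace is kept so
  tests can assert monotonicity.
* **Quantized data**: integer grey levels are collapsed to a weighted
  histogram before fitting; the weighted likelihood is identical to the
  pixel-level one and the fit cost becomes independent of field size.
* **Degeneracy guards**: σ is floored at 0.5 grey levels and a component
  whose weight falls below 1e-4 is re-seeded once at the data median; a
  second collapse aborts with a diagnostic. On quantized 0–255 data these
  floors prevent a component from locking onto a single bin.

The category thresholds are the crossings of *weight-scaled* adjacent
component densities, π_s N_s(x) = π_{s+1} N_{s+1}(x) — a quadratic in x
solved in closed form, taking the root strictly between the two means.
Whether the plotted, intersecting densities of a mixture should carry their
mixing weights is genuinely ambiguous in the field; we default to weighted
(the crossings of the curves a mixture plot actually shows, and the Bayes
boundary between components) and expose `weighted = FALSE` for the
unweighted variant. If extreme weight imbalance pushes both quadratic roots
outside the (μ_s, μ_{s+1}) interval, the responsibility-equality point is
found by bisection instead. Fits that violate t1 < t2 < t0 are rejected
with an error rather than silently reordered.

Both pixel intensities and per-cell mean intensities are accepted as
calibration input; the method is agnostic to which, and the choice is the
user's (per-cell means give somewhat tighter components).

## Categories, counting and the 0–3 score

Boundary convention, everywhere: **a value equal to a threshold belongs to
the stronger side** (strong ⇔ x ≤ t1, moderate ⇔ t1 < x ≤ t2, weak ⇔
t2 < x ≤ t0, negative ⇔ x > t0). This matches interval conventions such as
strong 0–85 / moderate 86–180 / weak 181–230 for integer data.

A nucleus is positive when its mean DAB white intensity is ≤ t0. Cell-level
category is the category of the cell's mean intensity — the minimal
aggregation rule that needs no membrane segmentation. Region summaries
report counts per category (negative + weak + moderate + strong = total,
always), percent positive, mean intensity (positive pixels only by default,
all pixels as an option) and the fraction-weighted score

    score = 1·f_weak + 2·f_moderate + 3·f_strong ∈ [0, 3].

Fractions are computed over positive cells by default (so an all-strong
region scores exactly 3); the all-cells denominator is available, in which
case the remainder is the negative fraction and the score is shrunk
accordingly. Mapping the continuous score onto 0/1+/2+/3+ grades requires
cut-points that are cohort conventions, not statistics; they are left to
the user.

## Nuclear segmentation

Segmentation is deliberately simple: Otsu on the hematoxylin white-intensity
image, foreground = darker side, 8-connected components, discard components
below `min_area` (default 20 px at typical 20× sampling). The underlying
component labelling delegates to EBImage with a diagonal-merge step to get
8-connectivity. This is a stand-in for the vendor segmentation used in
production pipelines: adequate for the well-separated nuclei the synthetic
generator produces, and not intended for touching-nuclei tissue.

## The synthetic data generator

There are no public image sets for this workflow, so the package ships a
ground-truthed generator used by every downstream test.

**Images.** Nuclei are non-overlapping ellipses (axes uniform on the radius
range, orientation uniform), placed by rejection sampling with bounding
circles kept ≥ 2 px apart so ground truth is unambiguous and 8-connected
components never merge. Negative cells carry hematoxylin only; positive
cells also carry DAB at a white intensity drawn from the generating
3-component mixture truncated to [1, t0] (calibration concerns positive
pixels below the background cutoff, and intensity 0 has unbounded optical
density). Pixels are composed through the same Beer–Lambert forward model
the separation module inverts, so at zero noise deconvolution recovers each
cell's assigned intensity to within integer rounding (±1 grey level — an
invariant under test). Optional pixel noise is i.i.d. Gaussian in RGB,
the simplest perturbation that propagates through deconvolution the way
sensor noise does.

Defaults are the calibration-field conditions used throughout the tests:
mixture π = (0.3, 0.4, 0.3), μ = (40, 130, 205), σ = (15, 25, 12) on the
white-intensity axis, t0 = 230, 35 % of cells DAB-positive (a typical
Ki-67-like baseline), hematoxylin white intensity N(160, 10), background
255. The default field is 450×450 px with 250 cells — deliberately smaller
than a real 2,000–10,000-cell field of view; parameter recovery there is
already tight, and the histogram-based EM makes larger fields cheap when
wanted. What the generator does **not** emulate: tissue texture, touching
or overlapping nuclei, membrane-localized staining, scanner optics. Passing
tests therefore validate the *statistical* pipeline, not robustness to
real-tissue segmentation failure modes.

**Time courses.** A decalcification study is emulated as
value(case, time, field) = baseline_case × effect(time) × (1 + N(0, CV)).
Defaults: 9 cases × 5 fields at 0/1/6/24 h; effects (1, 0.85, 0.80, 0.80) —
a 15 % loss appearing within the first hour and plateauing between 6 and
24 h, the typical ER decalcification pattern; field CV 5 %, inside the
0.2–11 % range typical of intra-tumor heterogeneity across fields of one
slide. The between-case
baseline SD (10 on a mean of 80) is not reported anywhere and was chosen
once as a realistic inter-tumor spread; because the statistical battery
normalizes to each case's time-zero mean, its exact value barely influences
the tests. Multiplicative (CV-style) field noise matches how heterogeneity
is reported in this literature.

## The statistical battery

Markers with approximately normal field distributions use one-way ANOVA,
confirmed by Welch's ANOVA on mid-ranks, with Tukey studentized-range
pairwise comparisons; non-normal markers (p53-like) use Kruskal–Wallis with
pairwise two-sided Wilcoxon rank-sum tests at the Bonferroni level α/m —
with four time points m = 6 and the level is 0.05/6 = 0.0083 as printed to
four decimals. Wilcoxon uses the exact null distribution when a pair's
combined n ≤ 20 and there are no ties, the tie-corrected normal
approximation with continuity correction otherwise. All tests are
two-sided. These are textbook procedures and delegate to R's `stats`
implementations; the package's contract is the battery's structure,
normalization and reporting, which the tests pin down (including the
detection of the drop-then-plateau pattern on 100 seeded synthetic
replicates). The analysis treats fields as independent within a time group
after baseline normalization; a mixed-effects treatment of the case/field
hierarchy is deliberately out of scope.

## Scanner comparison

For instrument comparison the package extracts normalized 256-bin
histograms of R, G, B and a monochrome channel (unweighted RGB mean by
default; Rec. 601 luminance optional) over a rectangle, integrates the
histogram mass over the category zones ([0, t1], (t1, t2], (t2, t0],
(t0, 255] — an exact partition), and computes the Pearson correlation and
per-grey-level mean mapping between two pre-aligned monochrome images.
Image registration itself is out of scope; inputs must be co-registered.

## Conventions and limitations

* Pixel coordinates are 0-based; polygons are (x, y) = (column, row) vertex
  lists; a pixel belongs to a region when its center (col + 0.5, row + 0.5)
  is inside under the even-odd rule, making rectangles half-open.
* Images are 8-bit per channel; 16-bit inputs are rejected rather than
  rescaled silently.
* k ≠ 3 mixtures are supported as a pass-through (the intersections of any
  adjacent pair are computed) but model selection over k is not offered.
* The weighted score is continuous; no claim is made about equivalence to
  any regulatory HER2 grading algorithm, and membrane completeness is not
  assessed.

## Worked example

```{r example, eval = FALSE}
spec <- synthetic_image_spec(n_cells = 250, seed = 7)
field <- generate_ihc_image(spec)
channels <- separate_stains(field$image, spec$vectors)

# calibrate on intensities sampled from the field's generating mixture
intens <- round(generate_mixture_sample(field$model, 1e4, seed = 7))
th <- derive_thresholds(intens, t0 = 230)
th

score_regions(channels, th)

# decalcification battery on a synthetic ER time course
decal_battery(generate_timecourse(seed = 7))
```
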