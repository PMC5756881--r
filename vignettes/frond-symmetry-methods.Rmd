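---
title: "Measuring frond symmetry and size: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring frond symmetry and size: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(frondsym)
```

## The problem

Duckweed (*Lemna*) fronds are small floating plants with a single leaf-like
body that is typically oval, bilaterally symmetric about one axis, and
pointier at one end — roughly the outline of an egg or a guitar pick. Because
the frond margin offers almost no repeatable anatomical landmarks, symmetry
cannot be quantified with the usual landmark-based morphometrics. frondsym
instead implements a landmark-free *object symmetry* index, the Continuous
Symmetry Measure (CSM), computed on equally spaced reference points placed
around the frond outline, together with the standard size descriptors (area,
perimeter, circularity) and a model-selection workflow for relating offspring
morphology to the age of the parent plant at the moment the offspring
detached.

One caveat is inherited from the method itself: for outlines without
homologous left/right landmarks, departures from symmetry cannot be decomposed
into fluctuating asymmetry, directional asymmetry and antisymmetry. CSM
measures bilateral asymmetry *in general*.

## From photograph to outline

`extract_outline()` chains six deterministic steps:

1. **Thresholding.** Fronds are green (dark in the blue channel) and are
   photographed on a pale background (bright in blue), so the *inverse* blue
   channel is bimodal. Otsu's criterion — exhaustive scan of all 256 cutoff
   levels for the one maximizing between-class variance — picks the
   threshold; pixels strictly above it are foreground. When a plateau of
   cutoffs ties (well-separated modes), the midpoint of the tied range is
   used, which keeps the choice deterministic and centred between the modes.
2. **Component cleaning.** Connected components are found under
   4-connectivity and all but the largest (by pixel count) are deleted; ties
   are broken in favour of the component containing the lexicographically
   smallest `(row, col)` pixel.
3. **Hole filling.** Background pixels not reachable from the image border by
   4-connected background steps are flood-filled to foreground.
4. **Contour tracing.** Boundary pixels (foreground pixels with at least one
   4-adjacent background pixel; pixels outside the image count as background,
   i.e. the mask is implicitly padded) are ordered by a Moore-neighbourhood
   contour walk with the Jacob stopping criterion, counterclockwise in
   `(x = col, y = -row)` coordinates, starting from the topmost-then-leftmost
   boundary pixel. The 4-adjacency definition of "boundary" is deliberate:
   the contour walk of a 4-connected, hole-free component visits exactly that
   set, whereas diagonal-notch pixels that are only 8-adjacent to background
   are provably missed by any contour walk. For degenerate masks (e.g. a
   one-pixel-wide bar) no closed 8-adjacent cycle through every boundary
   pixel exists; the walk's revisits are then collapsed to first visits, so
   the *set* property (every boundary pixel exactly once) always holds while
   the adjacency property holds for blob-like masks — which cleaned frond
   masks always are.
5. **Resampling.** `L` reference points (default `L = 200`) are placed at
   equal arc-length intervals along the closed piecewise-linear curve through
   the trace pixels, starting at the first trace pixel; sub-pixel positions
   are allowed.
6. **Normalization.** For symmetry analysis the points are centred on their
   centroid and scaled so the greatest centroid-to-point distance is 1,
   making CSM scale- and translation-free. The centroid is the arithmetic
   mean of the `L` reference points (not the area centroid): the symmetry
   procedure operates on the reference points, so their mean is the natural
   centre. Normalization recentres as well as rescales; the reflection-axis
   mathematics below assumes the centroid is at the origin.

Size is always measured on the *pre-normalized* points: area by the shoelace
formula times the squared mm-per-pixel calibration, perimeter as the closed
polygon length times the calibration, and circularity as
$4\pi \cdot \text{area} / \text{perimeter}^2 \in (0, 1]$. The calibration is
a required user input for absolute units — it cannot be recovered from an
image — and defaults to 1 (pixel units).

## The Continuous Symmetry Measure

CSM asks: *how far is this outline from the nearest bilaterally symmetric
configuration?* Formally, for normalized points $p_0, \dots, p_{L-1}$:

1. **Pairings.** Candidate left/right correspondences are generated by
   picking a start location on the boundary and repeatedly pairing the next
   clockwise and counterclockwise unpaired points. With even `L` there are
   exactly `L` distinct pairings: `L/2` with the start between two points
   (`L/2` pairs) and `L/2` with the start at a point (`L/2 + 1` pairs, the
   start and the point `L/2` away being self-paired).
2. **Optimal axis.** For a given pairing, the reflection axis through the
   centroid minimizing the mean squared distance to the closest symmetric
   configuration has a closed form. Writing the objective as
   $C - (A\cos 2\theta + B\sin 2\theta)/L$ with
   $A = \sum_{\text{pairs}} (x_i x_j - y_i y_j) + \tfrac12 \sum_{\text{self}} (x^2 - y^2)$,
   $B = \sum_{\text{pairs}} (x_i y_j + x_j y_i) + \sum_{\text{self}} xy$, the
   optimum is $2\theta = \operatorname{atan2}(B, A)$. The axis is constrained
   through the centroid of the normalized points; the package validates the
   closed form against a dense 3600-step angle grid refined by golden-section
   search in its test suite, and the reported CSM value is always computed
   from the explicit symmetry transform rather than from the closed-form
   objective, so the two routes cross-check each other on every call.
3. **Symmetry transform.** One member of each pair is reflected across the
   axis and averaged with its pair-mate; the partner point is the reflection
   of that average back across the axis; self-paired points are projected
   onto the axis. The result is exactly mirror-symmetric, and is identical
   whichever pair member is "reflected first" (asserted by test).
4. **CSM.** The mean squared distance between the observed points and their
   transform, averaged over all `L` reference points (self-paired points
   contribute their squared axis distance once each), minimized over the `L`
   pairings. Zero means perfect bilateral symmetry. The value is reported as
   this raw mean squared distance in normalized coordinates — *not*
   multiplied by 100 as in some published variants — because the averaged
   squared distance is the quantity the procedure minimizes.

`csm_forced()` evaluates only the at-point pairing whose self-paired start is
the reference point farthest from the centroid — for a frond, the pointy tip
that marks the putative biological symmetry axis. By construction
`csm_forced >= csm`; ties in the farthest point are resolved by evaluating
all tied candidates and keeping the minimum. Whether the original analyses
normalized by `L` exactly as chosen here is not recoverable from published
descriptions; the convention (each reference point counted once) is the
literal reading of "average over every reference point" and is recorded here.

```{r csm-demo}
bent <- make_outline(asymmetry = 0.12)
res <- csm(bent)
res
autoplot(res)
```

## The synthetic generator

`make_outline()` draws an egg curve $r(t) = 1 + p\cos t$ (pointiness $p$),
compressed across the symmetry axis by `1/elongation`, and for
`asymmetry = ` $\varepsilon > 0$ multiplies the radius on one side only by
$1 + \varepsilon \sin^2 t \sin 2t$ — a smooth S-shaped perturbation that
pushes one lobe out and the other in, vanishing to second order at the axis.
This form was chosen over a simple one-sided bump because a single smooth
bump can be partially absorbed by a slightly rotated reflection axis,
making CSM non-monotone at large $\varepsilon$; the S-shaped perturbation
yields a strictly increasing CSM over the documented box
$\varepsilon \in [0, 0.2]$ (property-tested on the grid
$\{0, 0.02, \dots, 0.2\}$). At $\varepsilon = 0$ the generator emits an
exactly mirror-symmetric point set (the lower half reuses the upper half's
coordinates bit-for-bit), so the pipeline's zero really is zero.

`render_frond_image()` rasterizes an outline with green-ish foreground
(blue 40) on a pale background (blue 235) so the inverse blue channel is
bimodal, then optionally adds Gaussian intensity noise, small
foreground-coloured specks clear of the frond, and background-coloured
interior holes — exactly the defects the cleaning steps exist to remove.
What the renderer does *not* emulate: real frond texture (veins, pigment
gradients), uneven illumination, soft focus at the margin, and partial
damage. Passing round-trip tests therefore demonstrate correctness of the
geometry chain under controlled conditions, not robustness to every failure
mode of real microscope photographs.

`simulate_cohort()` generates the study design: 30 parents, 403 offspring
(as evenly distributed as possible), 4 shelves, integer detachment ages
spanning days 1–30 drawn without replacement per parent (hence strictly
increasing), shelf assigned uniformly per offspring, and per response
$$y = \beta_0 + \beta_1 P + \beta_2 P^2 + \beta_3 P^3 + s_{\text{shelf}}
  + b_{0,\text{parent}} + b_{1,\text{parent}} P + \epsilon$$
on the response's generating scale (identity for size, $\ln$ for the
symmetry measures, $\ln(1-x)$ for circularity), with an exclusion flag drawn
from $\text{Bernoulli}(\operatorname{logit}^{-1}(e_0 + e_1 P))$ and
measurements removed for excluded fronds. Default coefficients are
qualitative emulations (the real coefficients were never published): size
rises over the parent's first week and then declines (a cubic with turning
points near days 7 and 40), shape measures are at most weakly age-dependent,
and the exclusion process (`excl_beta = c(-2.9, 0.1)`) rises with age to
roughly 23% overall. Gaussian tails are not truncated, so a simulated size
can in principle be unphysically small; this keeps the generating model
exactly linear-Gaussian for recovery experiments.

## The statistical workflow

`analyze_cohort()` reproduces the two-stage information-theoretic protocol:

* **Transforms.** CSM and CSM_forced are right-skewed and analyzed as
  $\ln x$; circularity is left-skewed and analyzed as $\ln(1 - x)$ (low
  values = circular); area and perimeter are untransformed. Exact zeros —
  possible for perfectly symmetric *synthetic* fronds, never observed in
  real data — would map to $-\infty$ and are floored at half the smallest
  positive observed value, with the count of floored values flagged on the
  result.
* **Stage 1 (random effects).** Nine candidates — three random-effects
  structures (parent random intercept + slope, parent random intercept,
  none) crossed with the linear, quadratic and cubic age polynomials — are
  fitted by REML (`nlme::lme` / `nlme::gls`) and compared by AICc. If the
  winning structure differs across polynomials, the winner under the
  best-supported polynomial (lowest own AICc) is taken, tie-broken by the
  larger best-versus-second-best margin; this mirrors the narrative
  resolution used in the original protocol (margins and the ultimately
  best-fitting polynomial both favoured the richer structure).
* **Stage 2 (fixed effects).** With the structure fixed, all eight models —
  age polynomials of degree 0–3 crossed with presence/absence of the shelf
  factor — are fitted by *maximum* likelihood (required for comparing fixed
  effects) and ranked by AICc; candidates within 2 AICc of the best are
  flagged as statistically indistinguishable. The winner is refitted by REML
  for reporting and prediction.
* **Exclusion.** A binomial model of the exclusion flag on age is selected
  by AICc among the three random-structure candidates (`lme4::glmer` /
  `glm`), and the age slope's Wald $z$ is reported. Complete separation is
  detected and flagged.

Conventions that the protocol leaves open, fixed here and exposed:

* `AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)` with `n` = number of offspring
  observations (not parents) and `k` taken from the fitted model's log-
  likelihood attribute: fixed coefficients + variance parameters + residual
  variance. A cubic with random intercept and slope therefore has
  `df = 4 + 3 + 1 = 8`.
* Shelf enters as a 4-level categorical factor (3 df), consistent with the
  df jumps in the reference model tables; a continuous temperature covariate
  would be the alternative reading.
* Prediction curves are population-level (random effects at zero), averaged
  across shelf levels when shelf is in the model (design rows averaged
  before prediction; identical to averaging predictions for identity links,
  and applied on the link scale for the binomial model), with normal-
  approximation 95% bands from the fixed-effects covariance. The original
  band construction is unstated; this is the standard delta-method choice.
* Non-convergent candidates are dropped from the comparison with a warning
  rather than silently imputed.

```{r analysis-demo}
coh <- simulate_cohort(seed = 1)
fit <- analyze_cohort(coh, responses = c("area_mm2", "csm"))
glance(fit)
autoplot(fit)
```

## Validation strategy and problem sizes

Every layer is tested against an independent oracle rather than against
itself: Otsu against an exhaustive variance scan on raw values, components
and boundaries against brute-force enumeration, the analytic reflection axis
against a dense angle grid with golden-section refinement, full CSM against
exhaustive search over all pairings (sizes 4–12, 100 random polygons per
size, agreement to 1e-7), and the statistical stack against
simulation-recovery experiments at the study's own scale (30 parents / 403
offspring; 100 selection replicates, 200 slope-recovery replicates, 1000
type-I-error replicates). The render-extract round trip uses 20 seeds at
256-pixel canvases with noise SD 8, 4 specks and 2 holes, recovering CSM
within 5e-3 and area within 2%. These sizes were chosen to give tight Monte
Carlo error on a single CPU; `scripts/acceptance.R` re-runs the same
quantities from scratch.

## Known limitations

* One frond per image; no interactive landmarking; no correction for frond
  curling (handled physically by flattening in the source protocol).
* Reflection symmetry only — no rotational symmetry measures, and no
  decomposition of asymmetry into fluctuating/directional/anti components
  (impossible for landmark-free outlines).
* The synthetic cohort emulates the *structure* of the study, not its
  coefficients; selection-frequency results are properties of the emulation.
* CSM values depend mildly on `L`; comparisons should hold `L` fixed
  (default 200 throughout).
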