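---
title: "Methods: box-counting fractal dimension of retinal OCT-angiography vasculature and its measurement reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fractal dimension and reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdretina)
```

## The problem

The fractal dimension (FD) of the retinal vascular network is a single
scalar summarising how completely the branching vessel tree fills the
retina, and it is under study as a non-invasive biomarker of systemic
microvascular health. On wide-field en-face OCT-angiography of healthy
eyes, reported values cluster near 1.69 for both the superficial (SCP) and
deep (DCP) capillary plexuses. Before such a metric can be used clinically,
its **repeatability** (same operator, repeated scans) and
**reproducibility** (different operators) must be characterised. This
package implements the complete measurement-and-agreement pipeline, plus a
synthetic angiogram generator so the whole chain is testable without
imaging hardware.

## The measurement model

For one en-face image the measurement is a four-stage pipeline
(`estimate_fd()`):

1. **Binarisation** (`binarise()`): a fixed intensity threshold classifies
   every pixel; `>= threshold` is vessel. The acquisition-side threshold
   used in practice is not published, so it is a configurable parameter
   with default 0.5 on normalised intensity; the `>=` tie-break is part of
   the contract so results are bit-exact.
2. **Skeletonisation** (`skeletonise()`): Zhang–Suen two-subiteration
   parallel thinning reduces each vessel to its one-pixel centre line.
   Zhang–Suen can leave fully-foreground 2×2 blocks at staircase corners
   and X-junctions; a cleanup pass deletes one pixel per residual block —
   preferring locally 8-simple pixels (Hilditch connectivity number 1) and
   falling back to any pixel whose removal provably keeps the global
   8-connected component count. The exported invariants are: the skeleton
   lies inside the mask, contains no fully-foreground 2×2 block, and never
   has more 8-connected components than the mask.
3. **Continuity check** (`verify_continuity()`): the protocol requires
   that thinning introduce no discontinuities; operationally, the
   component count must not increase. `estimate_fd()` fails hard if it
   does.
4. **Box counting and fit** (`box_count_curve()`, `fit_fd()`): grids of
   shrinking cell size $s$ are overlaid (single grid, anchored top-left,
   partial edge cells count); $N(s)$ is the number of cells containing at
   least one skeleton pixel, and the FD is the ordinary least-squares
   slope of $\log N(s)$ against $\log(1/s)$. The mesh schedule is dyadic —
   from the largest power of two at most half the smaller image dimension
   down to 2 px — because a dyadic grid makes the validation fixtures
   analytic (see below). All scheduled scales enter the unweighted fit; at
   least four scales are required.

The slope is reported raw, on $[0, 2]$: a line has dimension 1, a filled
region 2, and healthy vascular networks fall in between. No normalisation
is applied.

### Numerical choices

* Counts are exact integers; the curve invariant
  $N(s) \le \lceil H/s\rceil \lceil W/s\rceil$ and monotonicity are
  testable against a brute-force per-cell scan.
* A flat log–log curve (all counts equal) is reported as slope 0 with
  $R^2 = 1$ rather than an undefined fit.
* Images below 32 px in their smaller dimension yield fewer than four
  dyadic scales and are rejected at fit time.

## Agreement statistics

The reliability module consumes a complete subjects × raters table of FD
values (`measurement_table` long format or a matrix).

**ICC** (`icc()`): single-measure Shrout–Fleiss forms computed from ANOVA
mean squares — ICC(1,1), ICC(2,1), ICC(3,1) — with exact F-based 95%
confidence bounds (Satterthwaite degrees of freedom for the ICC(2,1)
interval). The package default is **ICC(2,1)** (two-way random, absolute
agreement): in a repeatability/reproducibility design both the scan
occasion and the observer are draws from a population of acquisitions, and
absolute agreement (not mere consistency) is what matters for
interchangeable measurements. The study this package models names only
"Shrout–Fleiss notation", so the form is selectable. For degenerate
perfect-agreement tables the F interval is 0/0; the CI collapses onto the
point estimate.

**CV** (`cv()`): per-subject SD/mean × 100 averaged over subjects is the
default aggregation (one CV per observer per plexus is reported without a
stated pooling rule in the motivating study; an `overall` mode on the
flattened series is provided). Sample SD ($n-1$) everywhere. An observer
with a single scan per participant has no within-subject repeats, so the
per-observer CV in the `table2` summary is only defined (and only
reported) for observer 2; the per-comparison CV in `reliability.csv` uses
the two paired ratings of each comparison instead.

**Bland–Altman** (`bland_altman()`): bias = mean difference, limits of
agreement = bias ± 1.96 × SD of differences; pair coordinates
((x+y)/2, x−y) are exported for plotting.

**Paired t, Shapiro–Wilk, Cicchetti** (`paired_t()`, `normality_check()`,
`cicchetti_label()`): standard two-sided paired t on the differences;
Shapiro–Wilk delegated to `stats::shapiro.test()`; Cicchetti clinical
bands poor < 0.40 ≤ fair < 0.60 ≤ good < 0.75 ≤ excellent (boundaries to
the upper band).

## Study design encoding

Three scans per participant: scan 1 by observer 1, scans 2 and 3 by
observer 2. Repeatability compares scans 2 vs 3; reproducibility scans 1
vs 2 (`study_design()`, `assemble_comparisons()`). Eye selection follows
birth-year parity (even → right, odd → left) with fallback to the other
eye if the selected one is uninterpretable, and participant-level
exclusion when both eyes fail quality — signal strength < 7/10, abnormal
segmentation, perfusion-map artefacts, or uninterpretability, all treated
as equally disqualifying since no precedence is stated
(`select_study_eye()`, `apply_quality_filters()`). The two artefact
exclusions in the motivating cohort are modelled as participant-level
removals (45 enrolled → 43 analysed); the source text is ambiguous between
removing scans and removing participants, and the participant-level
reading is the conservative one for a complete-design ICC.

## The synthetic world

Real SS-OCTA images are available only on request, so the package ships a
generator whose defaults *are* the stated study conditions:

* **Fixtures** (`generate_fixture()`): line, filled square, single pixel,
  and the Sierpiński gasket built as Pascal's triangle mod 2 on a
  $2^d$ grid. The dyadic construction aligns exactly with the dyadic mesh:
  the count at mesh size $2^k$ is exactly $3^{d-k}$, so the fitted slope
  is exactly $\log 3/\log 2 \approx 1.585$ — an analytic oracle for the
  whole counting/fitting chain.
* **Vessel trees** (`generate_vessel_tree()`): recursive stochastic
  bifurcation from border roots — jittered headings, geometrically
  decaying stroke width, anti-aliased rendering, Gaussian background
  noise. Defaults (256 px, 6 roots, branch probability 0.38, jitter 18°,
  initial width 3 px, decay 0.93 per generation, depth ≤ 14, noise SD
  0.05) were calibrated **once** so the skeleton FD over 20 seeds lies in
  [1.5, 1.8] (measured: mean 1.68, range 1.56–1.77), bracketing the
  healthy-eye reference ≈1.69; they were not revisited afterwards.
* **Repeat-scan perturbations** (`perturb_scan()`): rigid sub-pixel
  translation (bilinear), gamma contrast change, fresh acquisition noise.
  Intra- and inter-observer models differ only in magnitude — the
  inter-observer gap is attributed to head-position/centration changes,
  i.e. a larger geometric perturbation, not a different mechanism.
  Defaults: intra |shift| = 0.5 px, noise SD 0.01; inter |shift| = 3 px,
  gamma 1.05, noise SD 0.03. In `generate_cohort()` the template's shift
  magnitude is given a uniformly random direction per scan (a fixed
  (dx, dy) would make repeat scans identical); `perturb_scan()` itself
  honours the exact vector.
* **Variance-components tables** (`simulate_measurement_table()`):
  $y_{ij} = \mu + b_i + o_j + e_{ij}$ with independent Normal effects;
  the implied true ICC is
  $\sigma_b^2 / (\sigma_b^2 + \sigma_o^2 + \sigma_e^2)$. This gives the
  reliability module a ground truth independent of the imaging chain.

**What a green test establishes — and what it does not.** The synthetic
trees reproduce the *geometry class* (dense planar branching at the right
fractal dimension) and the *design* (43 × 3 × 2 with ordered perturbation
magnitudes), so end-to-end tests can check structural claims: exact box
counts, skeleton invariants, ICC recovery, and the qualitative ordering
repeatability-ICC > reproducibility-ICC. They do not emulate OCT speckle,
projection artefacts between plexuses, layer-segmentation failures, or
device-specific contrast transfer — so no test here validates the absolute
ICC/CV values of any real device, and the paper-reported coefficients are
deliberately not acceptance targets.

## Known limitations

* Single fixed counting grid (no multi-offset minimisation) and a dyadic
  schedule; absolute FD values depend mildly on both conventions, which is
  one reason FD values are not comparable across implementations.
* The thinning cleanup can, in principle, encounter a 2×2 block whose
  every deletion would split the network; it then leaves the block rather
  than break continuity (not observed across the tested seeds).
* ICC confidence intervals assume the Normal two-way model; the simulator
  satisfies it by construction, real FD tables need the Shapiro–Wilk
  check first.
* `cv()` requires strictly positive means — fine for FD (≈1.7) but not a
  general-purpose CV.
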