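# fdretina

Box-counting fractal dimension of the retinal vascular network on en-face
OCT-angiography images, with the full repeatability/reproducibility
statistics used in agreement studies — and a seeded synthetic-angiogram
generator so every stage is testable without imaging hardware.

## Who this is for

Researchers quantifying retinal microvascular complexity from
OCT-angiography (or any binary curvilinear network image) who need:

* a deterministic, oracle-tested **box-counting FD estimator**
  (binarise → skeletonise → continuity check → shrinking-mesh counts →
  log–log slope), and
* the standard **measurement-agreement toolbox**: Shrout–Fleiss ICC with
  exact F-based 95% CIs, coefficient of variation, Bland–Altman limits of
  agreement, paired t-test, Shapiro–Wilk check, Cicchetti reliability
  labels, and the scan-1-vs-2 / scan-2-vs-3 observer design of
  repeatability studies.

## The statistic at the core

A skeletonised vessel network is overlaid with grids of shrinking cell
size *s*; *N(s)* cells contain vessel pixels. The box-counting fractal
dimension is the OLS slope

> FD = slope of log *N(s)* vs log (1/*s*),  FD ∈ [0, 2]

over a dyadic mesh schedule. A line gives 1, a filled region 2; healthy
wide-field retinal networks measure ≈ 1.7. Agreement between repeated
measurements y<sub>ij</sub> (subject i, rater/scan j) is summarised by the
single-measure intraclass correlation, by default the two-way random,
absolute-agreement form

> ICC(2,1) = (MS<sub>R</sub> − MS<sub>E</sub>) /
> (MS<sub>R</sub> + (k−1) MS<sub>E</sub> + k (MS<sub>C</sub> − MS<sub>E</sub>) / n)

from the ANOVA mean squares of the complete n × k table.

## Worked example

```r
library(fdretina)

# one synthetic en-face angiogram and its fractal dimension
img <- generate_vessel_tree(seed = 42)
estimate_fd(img, threshold = 0.5)
#> Box-counting fractal dimension: 1.6462 (R^2 = 0.9957, 7 scales)

# a 12-participant study: 3 scans x 2 plexuses each, scan 1 by observer 1,
# scans 2-3 by observer 2; repeatability = scans 2 vs 3, reproducibility =
# scans 1 vs 2
out <- run_study(run_config(simulate = list(n_participants = 12L), seed = 42))
out$reliability[, c("plexus", "comparison", "icc", "ci_low", "ci_high", "label")]
#>   plexus      comparison   icc ci_low ci_high     label
#> 1    SCP   repeatability 0.997  0.991   0.999 excellent
#> 2    SCP reproducibility 0.986  0.953   0.996 excellent
#> 3    DCP   repeatability 0.997  0.991   0.999 excellent
#> 4    DCP reproducibility 0.978  0.923   0.994 excellent
```

The FD of 1.6462 sits in the healthy-eye range; the ICC rows show the
designed ordering — same-operator repeat scans (small re-centration) agree
better than scans by different operators (larger re-centration), in both
the superficial (SCP) and deep (DCP) plexus. `run_study()` with an
`output_dir` also writes per-image FDs, Bland–Altman pair coordinates, and
demographic/FD summary tables as CSV/JSON.

Validation fixtures have analytic dimensions, e.g. the dyadic Sierpiński
gasket:

```r
fd <- estimate_fd(generate_fixture("sierpinski", 256, depth = 8) + 0,
                  skeletonise = FALSE)$fd
c(fd, log(3) / log(2))
#> [1] 1.584963 1.584963
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/fdretina.R", package = "fdretina"))')
Rscript "$CLI" simulate --n 43 --seed 1 --out cohort/
Rscript "$CLI" estimate --in cohort/ --threshold 0.5 --out fd.csv
Rscript "$CLI" reliability --fd fd.csv --icc-model icc2 --out report/
Rscript "$CLI" run --config study.yaml          # end-to-end
```

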