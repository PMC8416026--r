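---
title: "Quantifying mitotic loop-layer architecture from Hi-C and 3D imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitotic loop-layer architecture from Hi-C and 3D imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(mitoscale)
library(dplyr)
```

## The model behind the package

Mitotic chromosomes are organized as consecutive chromatin loops, extruded
by condensin complexes, that stack radially around a central axis. Groups
of loops occupy one radial "layer" of the rod-shaped chromatid. This
geometry leaves a characteristic signature in the Hi-C contact probability
decay curve `P(s)` — the average contact frequency of two loci as a
function of their genomic separation `s`:

* **intra-loop regime** (`s` below the mean loop size `L`): contacts are
  dominated by locus pairs inside one loop and decay shallowly;
* **intra-layer regime** (`L <= s < D`): pairs sit in different loops of
  the same layer, which are spatially adjacent, so the decay stays slow;
* **inter-layer regime** (`s >= D`): pairs are on different layers,
  separated along the chromosome axis, and contact probability collapses.

The informative object is the log-log slope `d log10 P / d log10 s`. Its
local **maximum** in the 10 kb–1 Mb window estimates the mean loop size
`L`; its **minimum** in the 1–100 Mb window — the point of steepest decay
— estimates the layer size `D` (the amount of DNA per layer); and
`n = D / L` is the number of loops per layer. These three numbers are how
conditions such as linker-histone (H1.8) depletion are compared: fewer
condensins on chromatin means fewer, larger loops and a larger layer;
excess condensin loading means smaller loops, a smaller layer, and longer,
thinner chromosomes, with `n` approximately conserved.

## From contacts to estimates

`compute_ps()` forms, per geometric distance bin,
`P_k = O_k / N_k` — observed interactions divided by the number of
possible locus pairs at those separations, pooled genome-wide before
dividing — then normalizes by the total interaction count so curves from
different sequencing depths superimpose. Two details matter numerically:

* **Representative separations.** Each distance bin reports the
  possible-pair-weighted geometric mean of the separations it actually
  contains, not the nominal bin center. At coarse matrix resolution the
  first log bins hold only one or two discrete offsets; using nominal
  centers would put ripple of ~0.1 into the slope, comparable to the loop
  peak itself.
* **Smoothing.** The raw central-difference slope is smoothed by local
  linear regression with tricube weights whose bandwidth (`span`,
  default 0.3) is expressed in decades of genomic distance. A bandwidth
  tied to physical log-distance keeps the smoother's footprint fixed
  (±0.3 decades) regardless of how many bins the scheme uses; the loop
  peak of mitotic curves is only ~0.1 slope units tall and ~0.7 decades
  wide, and a much wider smoother would erase it.

Balancing (`balance_matrix()`) is standard iterative correction with the
first two diagonals masked, converging when the variance of nonzero
scaled marginals drops below `1e-5` (at most 200 iterations; bins with
empty marginals are flagged invalid). Synthetic maps drawn by this
package have uniform coverage by construction, so the estimators are
typically run on raw counts; balancing matters for real data with
coverage bias.

Estimator conventions: the peak is searched in 10 kb–1 Mb and ties break
toward smaller `s` (a conservative loop estimate); the drop is searched in
1–100 Mb, and a minimum landing on the window boundary is flagged
unreliable rather than reported as a discovery. A flatness diagnostic
marks peaks that barely rise above the window median (threshold 0.02 slope
units), as seen for chromosomes with broad loop-size distributions.

## What the contact-map simulator emulates

`loop_layer_model()` specifies the expected decay through its log-log
slope profile:

* a steeper short-range regime below the fiber scale (default 10 kb),
  ramping from `-alpha_loop - 0.4 (alpha_inter - alpha_loop)` at 1 kb,
  mimicking chromatin-fiber contact decay at sub-loop separations;
* a slope peak reaching exactly `-alpha_loop` at `s = L`;
* an intra-layer plateau at `-alpha_layer`;
* a dip reaching exactly `-alpha_inter` at `s = D`, recovering to the
  plateau beyond the drop — the shape empirical mitotic derivative curves
  display around the layer size.

With exponential loop-size variation (the default), the peak and dip are
broadened by the log-scale densities of `Exp(L)` loop sizes and `Gamma(n)`
layer sizes and re-centered so that the slope's argmax/argmin remain at
`L` and `D`: the generator's ground truth *is* the location of these
features, and variation manifests as the flattened peak seen in egg
extract chromosomes rather than as a displacement. When all three
exponents are equal the profile collapses to a single power law, which the
tests use as an analytic limit. Default exponents
(`alpha_loop = 0.5`, `alpha_layer = 0.6`, `alpha_inter = 3.0`) were chosen
once to reproduce the qualitative shallow/shallow/steep shape of mitotic
decay curves; they are free parameters of the simulator and every
recovery run states them.

`sample_contact_map()` draws separations by inverse-CDF sampling of
`P*(s)` weighted by the number of genomic positions admitting each
separation, places each pair uniformly, and aggregates at the requested
bin width. What the simulator does **not** emulate: trans contacts,
coverage bias (so balancing is a no-op on its output), sister-chromatid
structure, and mechanistic loop extrusion dynamics. Passing recovery tests
therefore demonstrates that the estimators read the decay signature
correctly at realistic depth and noise, not that they are robust to every
artifact of real libraries.

```{r, fig.width = 6, fig.height = 3.5}
model <- loop_layer_model(loop_size = 140e3, loops_per_layer = 36)
cm <- sample_contact_map(model, depth = 1e6, bin_width = 1e4, seed = 7)
ps <- suppressWarnings(compute_ps(cm))
d <- ps_derivative(ps, span = 0.3)
est <- estimate_loop_layer(d)
glance(est)
autoplot(d, estimate = est)
```

Problem sizes used throughout the package's own checks: one synthetic
100 Mb chromosome, 10 kb bins, depths of 1–5 million contacts, and ten
simulation seeds per condition, which puts the loop estimate's seed-to-seed
spread around 10–15% and its median well inside the 25% recovery band.

## 3D imaging quantification

The imaging half mirrors a standard extract-chromosome workflow:

* `quantify_if()` — single-slice immunofluorescence: the z-slice with
  maximal total DNA signal is selected, a constant background (median
  intensity outside a 10 px-dilated DNA mask) is subtracted from both
  channels, the DNA mask comes from Otsu's threshold (256-bin histogram),
  and each connected DNA mass reports mean marker over mean DNA. The
  background rule is parameter-free and robust; swap in a rolling-ball
  estimate upstream if illumination gradients matter.
* `surface_area_3d()` — the DNA volume is linearly interpolated along z to
  67 nm spacing, thresholded, labeled with 26-connectivity, and components
  of more than 10,000 voxels (a filter applied to the interpolated
  volume's voxels) report surface area and integrated DNA intensity.
  Surface area is measured on a marching-tetrahedra isosurface of the
  component mask after Gaussian smoothing (σ = 1 voxel). Smoothing is what
  makes the number meaningful: on a raw binary ball of radius 20 voxels
  the staircase surface overmeasures `4*pi*r^2` by ~27%, while the smoothed
  mesh is within 1%. A voxel-face counting mode exists for exact
  axis-aligned geometry.
* `count_cenpa_foci()` — DNA and CENP-A are thresholded independently
  (Otsu), each connected DNA object is one chromosomal mass, and the foci
  counted in a mass are the merge-radius-clustered local maxima of the
  (matched-filtered) CENP-A signal whose position falls inside the mass. A
  mass with fewer than 4 foci is classified as an individualized
  chromosome; with 4 or more, as a cluster.
  `individualization_frequency()` turns the records into the percent of
  individualized masses, per replicate when replicate ids are present.

Three robustness choices in the focus counter deserve explanation, since
plain Otsu-plus-components fails on realistic inputs:

* **Matched filter** (`smooth_sigma = 1` px): when a handful of small foci
  occupy a fraction of a percent of the image, Otsu's criterion prefers a
  cut *inside* the read-noise distribution (the tiny spot class contributes
  almost no weight), flooding the mask. Smoothing at the spot scale
  tightens the background class so the spot class wins.
* **Local maxima rather than components**: two spots whose masks touch at
  the threshold would otherwise merge into one count; maxima separated by
  a valley are counted individually, while maxima closer than
  `merge_radius` (default 3 px) collapse to one focus — which also
  implements the convention that a sister-centromere doublet is a single
  focus.
* **Mask hygiene**: the DNA mask is morphologically closed (radius 1) so a
  single noisy pixel cannot punch a hole under a focus centroid, and
  objects below `min_mass_px` (default 20 px) are treated as noise specks,
  not chromosomal masses.

The stack simulator (`scene_spec()`/`render_scene()`) plants ellipsoidal
or curved-tube DNA masses with per-mass marker ratios, Gaussian foci, and
Gaussian read noise (optional Poisson shot noise), and returns analytic
ground truth (voxel counts, Knud Thomsen ellipsoid areas, focus counts,
ratios). It does not simulate a PSF beyond the Gaussian spots,
photobleaching, or chromatic shift; detection performance on real
deconvolved stacks will degrade sooner than on these fixtures at matched
SNR.

```{r}
sp <- scene_spec(
  dim = c(64, 64, 5),
  masses = list(
    mass_ellipsoid(c(20, 20, 3), c(10, 10, 2), marker_ratio = 0.5),
    mass_ellipsoid(c(46, 46, 3), c(9, 9, 2), marker_ratio = 1.5)
  ),
  foci = tibble::tibble(
    mass = c(1, 1, 2), y = c(16, 26, 46), x = c(16, 26, 46),
    z = 3, amplitude = 600, sigma_px = 1.2
  ),
  noise_sd = 30, seed = 11
)
rs <- render_scene(sp)
quantify_if(rs$stack, "marker")
count_cenpa_foci(rs$stack)
```

## Two-tier statistics

Per-nucleus intensity measurements from independent experiments are put on
a common scale by `normalize_to_control()`, which divides every value in a
replicate by that replicate's control median (so control medians equal
exactly 1; the operation is idempotent). Within an experiment, conditions
are compared by `mann_whitney()` — rank-sum with tie correction, reporting
`min(U_a, U_b)`, with an exact enumeration p-value for pooled `n <= 20`
(valid under ties) and a tie-corrected, continuity-corrected normal
approximation otherwise. Across experiments, `t_test_on_medians()` reduces
each replicate to its median and applies an unpaired Student's t-test
(equal variances, the convention for aggregate-median comparisons; a Welch
toggle is provided). Zero-variance median sets are flagged degenerate
instead of producing an unstable statistic. No multiple-testing correction
is applied, matching the source workflow's reporting of individual
pairwise tests.

## Numerical conventions and degenerate inputs

* Bins are 0-based half-open; pairs-text positions are 1-based
  (`bin = (pos - 1) %/% bin_width`). Strand fields are parsed and ignored.
* Distance-bin edges are geometric (`8 bins/decade over 1 kb–100 Mb` by
  default); the last edge is clipped to `s_max`.
* Bins with no possible pairs are flagged invalid and excluded from
  differentiation; the derivative requires at least 3 valid bins.
* Near-ties in the smoothed slope (within `1e-9`) resolve to the smallest
  `s`, so a perfectly flat curve yields a boundary-flagged estimate rather
  than a noise-selected interior one.
* Constant images cannot be thresholded (error); a constant CENP-A channel
  yields zero foci.
* Masses assigned to different labels must not overlap in the scene
  renderer (the truth would be ambiguous), and each planted focus must lie
  inside its mass.

## Known limitations

* The layer-size estimator reads the *center* of the derivative drop; on
  curves whose drop is cut off by the chromosome end, the boundary flag —
  not the number — is the signal to trust.
* Loop-size recovery assumes the derivative peak falls inside 10 kb–1 Mb;
  heavily perturbed chromatin (e.g. nucleosome-depleted, with ~12 kb
  loops) needs a wider window.
* The cooler reader handles single-resolution containers and requires a
  `python` interpreter with `h5py` on the PATH; multi-resolution files are
  rejected with the available resolution paths.
* Surface areas of non-convex touching chromatids merged by
  26-connectivity are reported for the merged object, consistent with
  treating each connected DNA object as one mass.
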