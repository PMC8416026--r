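# mitoscale

Quantitative analysis of mitotic chromosome organization from Hi-C contact
data and 3D fluorescence microscopy, for researchers studying how loop
extrusion, topoisomerase activity and chromatin factors (e.g. linker
histones) shape chromosome architecture in systems such as *Xenopus* egg
extracts.

## What it computes

Mitotic chromatids are arrays of chromatin loops stacked as radial layers
along a rod axis. This geometry imprints three regimes on the contact
probability decay curve `P(s)` — intra-loop, intra-layer and inter-layer —
and the log-log slope `d log10 P / d log10 s` carries the two architectural
length scales:

* **loop size `L`**: genomic distance at the local *maximum* of the
  smoothed slope (searched in 10 kb – 1 Mb);
* **layer size `D`**: distance at the slope *minimum* — the steepest drop
  of `P(s)` — in 1 – 100 Mb; the DNA content of one radial layer of loops;
* **loops per layer `n = D / L`**.

The package provides the full path from data to estimates:

* `read_contacts()` / `read_pairs()` — pairs-format text, dense text, and
  single-resolution cooler HDF5 (via the bundled h5py bridge);
* `balance_matrix()` — iterative correction (ICE) with the first two
  diagonals masked;
* `compute_ps()`, `ps_derivative()`, `estimate_loop_layer()` — normalized
  genome-wide `P(s)`, tricube-smoothed log-log derivative, and the
  loop/layer/loops-per-layer estimates with diagnostics;
* `loop_layer_model()`, `expected_ps()`, `sample_contact_map()` — a
  three-regime contact-decay simulator with known ground truth, for
  validating the estimators end to end;
* `otsu_threshold()`, `quantify_if()`, `surface_area_3d()`,
  `count_cenpa_foci()`, `individualization_frequency()` — Otsu
  segmentation, per-mass immunofluorescence ratios, marching-tetrahedra 3D
  surface areas of chromosome masses, centromere-focus counting and the
  "fewer than 4 CENP-A foci = individualized chromosome" classifier;
* `scene_spec()` / `render_scene()` — a synthetic 3D stack generator with
  analytic ground truth;
* `normalize_to_control()`, `mann_whitney()`, `t_test_on_medians()` — the
  two-tier statistics used for grouped per-nucleus measurements.

## Worked example

Simulate a 100 Mb chromosome with 140 kb loops and 36 loops per layer
(layer size 5.04 Mb), then recover the architecture from the contact map:

```r
library(mitoscale)

model <- loop_layer_model(loop_size = 140e3, loops_per_layer = 36)
cm  <- sample_contact_map(model, depth = 5e6, bin_width = 1e4, seed = 1)
ps  <- compute_ps(cm, log_bin_scheme(1e3, 1e8, 8))
d   <- ps_derivative(ps, span = 0.3)
est <- estimate_loop_layer(d)
glance(est)
#> # A tibble: 1 x 8
#>   loop_size layer_size loops_per_layer peak_slope drop_slope flat_peak
#>       <dbl>      <dbl>           <dbl>      <dbl>      <dbl> <lgl>
#> 1   122382.   5040196.            41.2     -0.508      -2.45 FALSE
#> # i 2 more variables: loop_at_boundary <lgl>, layer_at_boundary <lgl>
```

The loop estimate (122 kb here; median 141 kb over ten seeds) tracks the
planted 140 kb within the seed-to-seed spread of the derivative peak, and
the layer estimate lands on the planted 5.04 Mb almost exactly — the slope
drop is a much sharper feature than the flattened loop peak.
`autoplot(d, estimate = est)` draws the derivative with both estimates
marked.

On the imaging side, a rendered stack with two chromosome masses carrying
marker ratios 0.5 and 1.5 and three centromere foci returns:

```r
sp <- scene_spec(
  dim = c(64, 64, 5),
  masses = list(
    mass_ellipsoid(c(20, 20, 3), c(10, 12, 3), marker_ratio = 1.5),
    mass_ellipsoid(c(48, 44, 3), c(9, 10, 3), marker_ratio = 0.5)
  ),
  foci = tibble::tibble(
    mass = c(1, 1, 2), y = c(18, 24, 48), x = c(18, 24, 44),
    z = 3, amplitude = 500, sigma_px = 1.5
  ),
  noise_sd = 10, seed = 7
)
rs <- render_scene(sp)
quantify_if(rs$stack, "marker")
#>    mass n_pixels mean_dna mean_marker ratio
#> 1     1      373    1000.       1501. 1.50
#> 2     2      279    1000.        500. 0.500
count_cenpa_foci(rs$stack)
#>    mass n_pixels n_foci individualized
#> 1     1      373      2 TRUE
#> 2     2      279      1 TRUE
```

Both masses hold fewer than 4 foci, so both classify as individualized
chromosomes (`individualization_frequency()` would report 100%).

## Further reading

The methods vignette (`vignettes/loop-layer-architecture.Rmd`) documents
the decay model and its assumptions, every tunable parameter with units
and defaults, what the simulators do and do not emulate, numerical
conventions, and known limitations.
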