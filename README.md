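# erquant

Quantitative analysis of cortical endoplasmic reticulum (ER) architecture
and dynamics from multi-channel time-series fluorescence images.

The cortical ER of plant (and animal) cells is a dense polygonal network of
membrane tubules and flattened sheets (cisternae) that remodels within
seconds. Its tubules are ~30–50 nm wide — below the resolution of a
confocal microscope — and much of the network streams along actin cables
while a subset of nodes stays pinned at ER–plasma-membrane contact sites.
`erquant` turns such movies into numbers: per-tubule lengths and
sub-resolution widths, bulge/constriction statistics, cisterna shape and
texture, a full network graph, per-element speeds and flow coherence,
persistency of static elements, and multivariate comparisons between
treatment groups. A synthetic scene generator with complete ground truth
makes every stage testable without microscope data.

## The core methods

* **Tubule enhancement** uses phase congruency over a log-Gabor filter
  bank (3–5 scales, 4–6 orientations). The local weighted mean phase angle
  ("feature type") maps bright ridges to ~1 and step edges to ~0.5
  independently of intensity, so dim tubules segment as reliably as bright
  ones. Segmentation is hysteresis thresholding (0.3/0.5) after zeroing
  shallow local minima (depth ≤ 0.05, which keeps appressed tubules
  apart), followed by Zhang–Suen thinning to a single-pixel skeleton.
* **Sub-resolution width calibration.** The intensity collected from a
  tubule of radius `r_t` inside a psf of lateral size `psf_xy` scales as
  the sampled volume `V_t = π r_t² psf_xy`, relative to a sheet of
  thickness `T_s` yielding `V_s = π psf_xy² T_s`. With the sheet intensity
  `I_s` as an internal standard, the tubule radius follows from its
  integrated granulometry intensity `I_t` as

      r_t = sqrt( (I_t / I_s) · psf_xy · T_s / 4 )

  with defaults `psf_xy = 140 nm` and `T_s = 40 nm` (from serial-section
  block-face electron microscopy of ER profiles).
* **Graph conversion**: junctions, free ends, puncta and cisterna
  centroids become nodes; tubules become edges carrying length,
  centre-weighted width (junction-region pixels excluded), branch angles,
  speed and persistency.
* **Dynamics**: dense optical flow by Farnebäck polynomial expansion
  (5-px neighbourhood, 3-level pyramid, 15-px averaging) gives per-element
  scalar/vector mean speeds and flow coherence `|Σv| / Σ|v|`; persistency
  maps count per-pixel occupancy of dilated skeletons over a lag window
  (default 12 frames ≈ 5 s) and locate persistent nodes by a temporal
  median filter.
* **Statistics**: metric tables are transformed towards normality
  (arcsin / log / logit / sqrt), compared by MANOVA (Pillai's trace, Roy's
  largest root) and per-metric ANOVA with Tukey HSD contrasts against the
  control.

## Worked example

```r
library(erquant)

sc  <- generate_network_scene(n_polygons = 9, seed = 7)      # ground-truthed scene
an  <- animate_scene(sc$truth, n_frames = 5,
                     translation_um_s = c(0.05, 0.12), seed = 3)
res <- analyze_movie(an$stack, er_config())
print(res)
#> ER movie analysis
#>   5 frame(s), pixel 40 nm, reference frame 3
#> ER network graph: 31 nodes, 37 edges
#>   nodes: cisterna = 1, free_end = 4, junction = 15, punctum = 6, resolver = 5
#>   total tubule length 34.74 um
#> ER cisterna set: 1 cisternae, 1 puncta
#> ER polygonal regions: 8 enclosed polygons
#>   mean tubule speed 0.130 um/s, coherence 0.99
```

The scene was generated with tubule radii of 25–50 nm and animated with a
bulk velocity of `(0.05, 0.12)` µm/s, i.e. a speed of 0.130 µm/s; the
pipeline recovers a mean tubule speed of 0.130 µm/s with coherence 0.99
(purely directed flow) and a mean calibrated tubule width of ~70 nm
(diameter), consistent with the generated radii. `res$metrics` holds the
full one-row summary used for group comparisons; `write_results()` writes
the per-edge/node/cisterna/polygon tables (CSV), the graph (GraphML) and
overlays (TIFF).

A thin command-line wrapper is installed with the package
(`inst/cli/erquant`): `erquant simulate --polygons 9 --seed 1 --out DIR`
and `erquant run MOVIE.tif --pixel-size-nm 40 --out DIR`.

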