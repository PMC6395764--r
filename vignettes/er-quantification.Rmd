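---
title: "Quantifying ER network architecture and dynamics with erquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ER network architecture and dynamics with erquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erquant)
```

The cortical endoplasmic reticulum is a dynamic polygonal network of
membrane tubules and sheet-like cisternae. This vignette explains the
models and procedures behind each stage of the `erquant` pipeline, the
parameters that matter, what the synthetic scene generator does and does
not emulate, and the numerical choices made where the design was open.

## Image model and preprocessing

Images are single optical sections of fluorescently labelled ER, 8–16 bit,
with pixel spacing of 20–80 nm and frame intervals around 0.41 s. The
pipeline standardises resolution by bilinear up-sampling until the
thinnest tubules (`fwhm_min_px`, measured by the user on the input grid)
span about 5 pixels; the factor is constrained to half-integers so the
resampling stays benign. Background is the mean of a user-defined ROI,
subtracted per channel and clamped at zero because all later stages assume
non-negative intensities. Smoothing uses a guided filter with the image as
its own guide and the kernel set to the minimum tubule FWHM, which reduces
noise on flat regions without blurring across tubule edges; the
regularisation defaults to `(0.01 × intensity range)^2`.

The analysis mask excludes the image periphery where the ER curves out of
focus. The frame is thresholded at the *lowest* level of a 2–4 class Otsu
partition (multi-level partitioning handles very bright inclusions such as
fusiform bodies: the surrounding ER then sits above the lowest cut),
internal holes are filled for boundary fitting, and the outer boundary is
a contracted convex hull eroded by a few pixels. Contraction keeps, inside
the hull, the pixels whose distance to the foreground is at most `shrink`
times the largest hull-to-foreground distance — `shrink = 1` gives the
full convex hull, values of 0.5–0.8 wrap the boundary onto the irregular
outline. Otsu ties that span empty histogram gaps are resolved to the
middle of the gap, the convention most implementations follow.

## Tubule enhancement and segmentation

An intensity threshold cannot segment tubules whose width, and hence
brightness, varies. The pipeline instead uses phase congruency: a log-Gabor
quadrature filter bank (default 4 scales from a 3 px minimum wavelength,
multiplier 2.1; 6 orientations with angular spread ratio 1.2) is applied in
the Fourier domain, and at each pixel the local weighted mean phase angle
is computed from the summed even and odd responses. Bright ridges sit at
+π/2, edges at 0 and dark ridges at −π/2; the angle is mapped to
`[0, 1]` so tubule centre-lines approach 1. Because the angle is a ratio
of filter responses it is invariant to linear intensity rescaling.

Pixels whose total filter amplitude falls below a noise floor are zeroed.
The floor is estimated from the finest-scale amplitude: on Gaussian noise
these amplitudes are Rayleigh distributed, so their median over the
(mostly background) image estimates the noise amplitude, which is scaled
by the number of scales and a compensation factor `noise_k = 2`. Estimating
the floor from the finest scale rather than the total amplitude matters on
dense scenes, where the median total amplitude contains mostly signal.

Segmentation applies an h-minimum step before hysteresis: regional minima
of depth at most 0.05 are zeroed, so two closely appressed tubules
separated by a faint valley are not merged into one. Shallow basins are
found by morphological reconstruction: they are exactly the pixels raised
by the h-minima transform whose fill level stops rising as h increases.
Hysteresis keeps pixels ≥ 0.3 that are 8-connected to a pixel ≥ 0.5, and
the region is thinned to a single-pixel skeleton (Zhang–Suen). Parallel
thinning can, in rare pixel configurations, split a junction; a repair
pass reinstates bridge pixels (inside the original mask) between
components that end within two pixels of each other, so connectivity of
the binary region is preserved.

## Cisternae, puncta and polygonal regions

Cisternae are segmented by opening the intensity image with a disc of the
maximum tubule FWHM, which erases everything tubular; candidate regions
are thresholded and their boundaries shrunk back onto the intensity
profile by an edge-based contraction contour (boundary pixels below half
the region's bright reference level are peeled until stable, at most 100
iterations). Regions smaller than 0.3 µm² are not cisternae but are kept
as candidate puncta — bright persistent spots that enter the network graph
as nodes. Shape metrics are computed in physical units: area, perimeter
(smoothed polygonal contour length, so a rasterised disc approaches
circularity 1), major/minor axis from second moments (with the 1/12 px²
quantisation correction), solidity (area over convex area), elongation
(1 − minor/major), circularity (4π area / perimeter², capped at 1 since
contour smoothing can underestimate the perimeter of small regions by a
few percent) and roughness (perimeter over convex perimeter). Elongation
and roughness have no universal definition; the formulas above are this
package's convention.

Polygonal regions — the cytoplasmic areas fully enclosed by the network —
are the connected components of the mask minus skeleton and cisternae that
do not touch the mask boundary, with the same shape metrics.

## Sub-resolution width estimation

Three width estimates are computed per skeleton pixel. The FWHM estimate
takes the intensity at the skeleton pixel as the peak and finds, via the
Euclidean distance transform, the distance at which intensity first falls
below half the peak: it measures the tubule convolved with the psf and
saturates near the psf width (~140 nm) for thin tubules. The granulometry
profile applies openings with discs of radius 0 to `FWHM_max` and records
the opened intensity under each skeleton pixel, which reads out the
cross-section profile; the steepest drop of this curve is an
integer-valued width (coarse by construction, with ties broken to the
smaller scale so width is not over-estimated).

The calibrated estimate inverts the psf sampling model
`r_t = sqrt((I_t / I_s) · psf_xy · T_s / 4)`, where `I_s` is the mean
intensity of cisterna interiors eroded by 2 px (or the configured 0.35 of
full scale when no cisterna is present) and `I_t` is the integrated
granulometry intensity: the trapezoid area under the plateau-subtracted
curve, doubled to cover both sides of the axis, divided by the psf width
in pixels. Defined this way `I_t` is invariant to psf blur (the
cross-section integral is conserved) and scales linearly with intensity,
so `r_t` is invariant to uniform rescaling. At `I_t = I_s` the formula
gives `sqrt(140 × 40 / 4) ≈ 37.4 nm`. On noise-free rendered tubes of
15–60 nm radius the median recovery error is well under 15%.

## Graph representation

Skeleton pixels with three or more branch directions (measured by the
crossing number of the 8-neighbourhood, which ignores thinning staircases)
are junction pixels; adjacent junction pixels cluster into one node at
their centroid. Each edge stores its ordered pixel path; lengths sum the
1/√2 pixel steps. Sub-scale artifacts are cleaned at the graph level:
micro self-loops at junctions (lens-shaped pixel cycles left when tubules
cross slightly off-centre) are absorbed into the junction cluster, and
junction–junction edges shorter than half the minimum FWHM are contracted.
Free-end spurs shorter than the minimum FWHM are pruned by default.
Duplicate edges between the same node pair are resolved by inserting
degree-2 resolver nodes at path midpoints until the graph is simple (a
self-loop therefore ends up with two resolvers; the one-split version
would leave a parallel pair).

Edge widths exclude junction regions: pixels within an exclusion distance
of each endpoint (the maximum initial width of the tubules meeting there)
are dropped before averaging, falling back to the plain mean (flagged) for
short spurs. Branch angles are measured between chords from the node to
each incident edge's path midpoint, reported between circularly
consecutive chords; node strength is the summed centre width of incident
edges. Cisternae join the graph as single nodes at their
intensity-weighted centroids, wired to every node on their boundary with
connector edges that are flagged, given the global mean centre width and
Euclidean lengths — they participate in graph-theoretic counts but are
excluded from tubule statistics. Puncta snap to the nearest skeleton node
within one FWHM or become isolated nodes.

On synthetic lattice scenes the extracted topology matches the generator's
planar graph after contracting degree-2 nodes, up to the inherent
ambiguity of pixel skeletons: a degree-4 crossing can legitimately extract
as two degree-3 junctions a few pixels apart, so tests compare contracted
counts within ±2 and verify the handshake lemma and the Euler face count
(`polygons = E − V + components`) exactly.

## Morphology along tubules and cisternal texture

Bulges and constrictions are peaks of the intensity trace integrated
normal to the tubule axis (tangent from a ±2 px window, normal half-width
`FWHM_max / 2`), excluding node regions. A peak must reach 5% of the trace
maximum in height and 3% in topographic prominence; troughs are peaks of
the inverted trace. Both thresholds are fractions of the maximum, so event
counts are invariant to intensity rescaling. The tubule width at each
event is sampled from the calibrated width map. For dual-channel data the
per-event channel ratio and the Pearson correlation of the aligned traces
quantify in-phase versus anti-phase marker distributions.

Cisternal sub-structure is summarised by a symmetric grey-level
co-occurrence matrix over four directions (E, N, NE, NW, with symmetric
counterparts) at an offset set to the minimum tubule radius, using 32
fixed intensity bins over the full bit-depth range — fixed-range binning
is what makes the metrics comparable across images collected under
identical conditions. Contrast (normalised by `(n_bins − 1)²`),
correlation, energy and homogeneity follow the standard formulas. On a
perfectly homogeneous region the formulas give contrast 0, homogeneity 1
and energy 1, and correlation is undefined (σ = 0) and flagged `NaN`
rather than set to 1 — descriptions of an ideal sheet as having "zero
energy" trace back to a different energy convention and conflict with the
Σp² formula used here. Aggregation is available per cisterna (mean of
metrics) and pooled (one accumulated GLCM, weighting cisternae by pixel
pairs). The intensity profile across cisternal boundaries is averaged in
signed integer distance-transform bins (bin 0 = innermost boundary ring).

## Dynamics and persistency

Optical flow between consecutive frames uses Farnebäck polynomial
expansion: each frame is approximated locally by a quadratic polynomial
under a Gaussian applicability (neighbourhood 5 px, σ = 1.5) and the
displacement field follows from the change in linear coefficients,
refined over a 3-level image pyramid with 3 iterations per level and
local averaging over 15 px. The averaging window scales with the pyramid
level so the coarsest level is not over-smoothed relative to its extent.
Velocities are averaged before conversion to µm/s (the order is fixed for
bit-reproducibility). Per element — edge path, cisterna mask, or node
disc — the summary reports the scalar mean speed, the vector mean (net
directed speed), the maximum, flow coherence (vector/scalar mean: 1 for
parallel flow, 0 for no net movement) and circular direction statistics.
Divergence and curl are central differences in 1/s with the border ring
suppressed. Distributions of mean speeds are summarised by a Gaussian fit
to log speeds with the back-transformed (geometric) mean.

Persistency is mapped two ways. The intensity method thresholds each
frame, and counts a pixel persistent in a frame pair (default lag 12
frames, ~5 s at 0.41 s) when it lies in the AND of the two binary masks
with an absolute intensity difference below 0.2 of full scale; scores are
fractions of pairs, reported over the OR of occupancy. The structure
method dilates per-frame skeletons and cisterna masks by `FWHM_min / 2`
and either sums occupancy over the window (graded) or ANDs the endpoint
frames (binary — which by construction marks an element present at start
and end but absent in between as persistent; a known limitation of the
endpoint definition). Persistent nodes come from a temporal median over
the whole time course, Gaussian smoothing with σ = `FWHM_min / 2`,
min–max normalisation and extraction of local maxima above 0.3–0.5
(default 0.4). All persistency outputs are in seconds.

## Group statistics

Per-movie metric rows are transformed towards normality — arcsin for
metrics bounded in [0, 1], log for wide-range positive metrics, logit
after clamping to [0.025, 0.975], square root for persistency (which
includes zeros and deviates from normality; a warning, not an exclusion).
Groups are compared by MANOVA with Pillai's trace and Roy's largest root,
followed by per-metric one-way ANOVA with Tukey HSD contrasts against the
control at the 0.05/0.01/0.001 levels, and canonical discriminant scores
for visualising separation. No sphericity correction is applied by
default; with the very small p-values typical of these comparisons the
conclusions are insensitive to it. The MANOVA requires more residual
degrees of freedom than metrics, so batch analysis reduces the metric
subset (with a warning) when too few movies are available.

## The synthetic scene generator

Scenes are polygonal tubule networks on a jittered rectangular lattice
(cell 1.4 µm, vertex jitter 0.22 of a cell), rendered at 40 nm pixels
under a Gaussian psf of 140 nm FWHM. Tubules are Gaussian line profiles
whose *integrated* cross-section brightness is proportional to their
cross-sectional area, with the proportionality fixed so the psf
calibration above recovers the true radius exactly by construction;
radii are drawn uniformly from 25–50 nm, matching electron-microscopy
measurements of ER tubules. Cisternae are uniform patches at the sheet
reference intensity 0.35 blurred by the psf. Noise is additive Gaussian
(default SD 0.02, an SNR comfortably above 5 for typical tubules) with
optional Poisson shot noise. Movies re-render the geometry under a bulk
translation plus optional per-frame jitter; geometry within one psf FWHM
of an anchor point does not move, with a smooth ramp to full displacement
at three psf widths, and anchors additionally carry a punctate
contact-site signal (a psf-sized spot at twice the sheet reference
intensity) in every frame, emulating the bright persistent puncta at
ER–plasma-membrane contact sites. Anchored-recovery scenarios use a
diagonal bulk translation so lattice-aligned tubules do not slide along
their own axes, and sample anchors among interior nodes — an anchor at the
image border has a clipped pinning zone and is not a meaningful test case.

What the generator does not emulate: actin-dependent remodelling (tubule
growth, sliding, fusion), photobleaching, depth-dependent defocus, and
curved tubules between junctions. Passing tests on these scenes therefore
demonstrates that the measurement chain is correct and well calibrated on
networks with known geometry, noise and motion — not that segmentation
accuracy on real micrographs equals the synthetic F1.

## Problem sizes and determinism

The shipped tests and the acceptance script use 9-polygon scenes
(~120×120 px), movies of 2–26 frames, 20-scene segmentation sweeps,
10⁴-replicate null simulations for the Tukey family-wise error, and
exhaustive brute-force oracles on regions up to 16×16 — sizes chosen so a
complete run takes a few minutes on one core while every stage still
operates in its intended regime. Every stochastic operation takes an
explicit seed and restores the caller's RNG state; identical seeds give
bit-identical scenes, analyses and CSV output.

## Known limitations

Pixel-skeleton topology is ambiguous at degree-4 crossings (see above).
The FWHM width saturates at the psf for sub-resolution tubules and is
reported for completeness, not calibration. The greedy one-to-one
tolerance matching used in precision–recall is slightly conservative
compared to optimal assignment. Persistent-node detection normalises to
the brightest persistent feature, so faint anchors in a field with a much
brighter one can fall below a fixed threshold. Scalar-mean speeds carry a
positive noise bias (speed magnitudes cannot cancel), which is inherent
to the definition rather than the estimator.
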