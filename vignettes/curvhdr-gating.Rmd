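---
title: "Curvature-guided HDR gating: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-guided HDR gating: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvgate)
```

## The gating problem and the model

A flow cytometry sample is a point cloud of tens to hundreds of thousands of
events in channel space (forward/side scatter, fluorescence intensities).
Gating selects subsets of events corresponding to cell populations. The
working assumption of this package is that populations of interest are
*modal regions* of the underlying event density \(f\): neighbourhoods of
local maxima. The method, curvHDR, finds candidate modal regions by testing
the curvature of a kernel density estimate, then refines each candidate into
a highest-density-region (HDR) gate fitted to the events it contains.

The pipeline, for 1-3 selected channels:

1. Remove boundary saturation pile-ups (events stacked at a channel's exact
   observed minimum or maximum when that exact value holds more than 1% of
   events). Apply a skew-reducing transform; `asinh` by default.
2. Standardize every channel to zero mean and unit standard deviation, so a
   single scalar bandwidth is meaningful.
3. On a regular mesh, estimate the density \(\hat f\) and its Hessian
   \(\hat H\) by kernel smoothing with bandwidth matrix \(h^2_{\mathrm{curv}} I\),
   and flag mesh nodes where \(\hat H\) is negative definite *and* the Wald
   statistic
   \(W(x) = \mathrm{vech}(\hat H)^\top \hat\Sigma^{-1} \mathrm{vech}(\hat H)\)
   exceeds the \(\chi^2_{d(d+1)/2}\) critical value, with
   \(\hat\Sigma(x) = \hat f(x)\, R /(n h_{\mathrm{curv}}^{d+4})\) and
   \(R = \int \mathrm{vech}(D^2 K)\,\mathrm{vech}(D^2 K)^\top\) the
   (closed-form) matrix of integrated products of second partials of the
   Gaussian kernel.
4. Group flagged nodes into connected regions (intervals, polygons, or
   closed triangle meshes) and replace each of the \(S\) regions by its
   convex hull.
5. Grow each hull so its area/volume is \(G\) times larger, by approximate
   circle/sphere rolling: offset each edge midpoint (face centroid) a
   distance \(2r\) along the outward normal and hull the offsets, solving
   for \(r\) by root search on the achieved ratio.
6. Collect the events inside each grown region.
7. On each such subset, fit a kernel density estimate with a two-stage
   diagonal plug-in bandwidth.
8. The gate is the union over subsets of the level-\(\tau\) HDR components,
   where the level is the \(\lceil \tau m \rceil\)-th smallest estimated
   density value at the subset's own points. The HDR \(R_\tau\) carries
   probability mass \(1 - \tau\): \(R_{0.1}\) holds 90% of the mass,
   \(R_{0.9}\) a concentrated 10% near the peak.
9. Event membership is the union of per-component containment.
10. The gate geometry and membership map back to original measurement units.

All density and derivative estimation is *binned*: events are distributed
multilinearly onto the mesh (linear binning) and the kernel — or its
analytic derivative; never a finite difference — is applied by separable
convolution along each axis, so cost is independent of \(n\).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `tau` | 0.1 | HDR level; the gate keeps a fraction `1 - tau` of each subset. The main tuning knob; lower values give wider, more inclusive gates. |
| `growth_factor` (G) | `2^d` | target area/volume ratio of the grown hull; about a doubling per dimension. |
| `alpha` | 0.05 | significance level of the curvature test. Results are insensitive to small values. |
| `h_curv` | \([4/\{(d+6)n\}]^{1/(d+8)}\) | curvature-phase bandwidth: the optimal scalar bandwidth for Hessian estimation of a standard normal density — approximately the largest bandwidth worth using on standardized data. |
| `transform` | `asinh` | variance-stabilizing transform; `identity` available for pre-transformed data. |
| `grid_nodes` | 151 (d ≤ 2), 51 (d = 3) | curvature mesh nodes per axis. |
| `hdr_grid_nodes` | 101 (d ≤ 2), 21 (d = 3) | per-subset HDR mesh nodes per axis. |
| `debris_threshold` | 0.01 | frequency above which an exact extreme value counts as a saturation pile-up. |
| `adjustment` | `hochberg` | multiplicity handling of the curvature p-values over in-support nodes (`pointwise` available). |
| `min_region_nodes` | 3 | flagged-node support below which a curvature region is discarded as spurious. |
| `density_floor` | `1e-3` | relative density below which nodes are never flagged (the variance estimate is unstable there). |

Evaluation grids cover the standardized data range padded by 3.7 bandwidths
per side, so Gaussian kernel mass outside the grid is negligible and the
estimate integrates to 1 within 2%.

## The plug-in bandwidth

For the HDR phase each axis is first scaled to unit standard deviation; one
bandwidth `h` is selected on the scaled data and mapped back as `h * sd`
per axis, making the selector exactly equivariant under axis scaling and
giving the `m^{-1/(d+4)}` rate. For `d = 1` the classical two-stage direct
plug-in is used (normal-reference 8th-order functional, pilot for the
6th-order functional, pilot for \(\psi_4\), then
\(h = [R(K)/(m\,\hat\psi_4)]^{1/5}\)). For `d = 2, 3` the stage-1 pilot is
the normal-reference curvature bandwidth; the fourth-order functionals
\(\psi_{iijj}\) are re-estimated with it by binned double sums, and the
final bandwidth solves the diagonal AMISE expression
\(h = [d\,R(K)^d/(m \sum_{ij}\hat\psi_{iijj})]^{1/(d+4)}\). If an estimated
functional comes out with the wrong sign (possible at small `m`), the
normal-scale bandwidth is used instead. On Gaussian data the selector lands
within a few percent of the normal-scale rule, as it should.

The HDR level uses the order-statistic estimator (the
\(\lceil\tau m\rceil\)-th smallest density value at the subset points)
rather than an interpolated quantile: it is deterministic, convention-free,
and exactly enumerable in small examples. The quantile convention is applied
uniformly; no interpolation variant is offered.

## Geometry

Regions are extracted from gridded fields by maximal runs (d = 1),
`contourLines` marching squares (d = 2), and an in-package marching
tetrahedra pass over the Freudenthal 6-tetrahedra cube decomposition
(d = 3). Crossing vertices are keyed by the lattice edge they lie on, so
shared vertices weld exactly and every component is a closed, consistently
oriented triangle mesh; orientation is fixed so volumes are positive.
Components are split by shared-vertex connectivity. The 3-D convex hull is
an incremental visible-face/horizon construction; point-in-polyhedron
testing is a ray-parity test with a fixed irrational-slope direction and a
deterministic retry sequence for rays that graze vertices or edges, so no
random number generator is consumed. Containment is boundary-inclusive
everywhere: gates are closed sets, and events exactly on a printed
rectangle bound have deterministic membership.

Two deliberate deviations from the literal textbook constructions:

* The grown region is the hull of the offset points *together with* the
  original vertices. The bare hull of offsets can clip sharp vertices of
  the input at small rolling radii, violating the contract that growth
  contains its input; including the input restores it without affecting
  the achieved ratio (0.5% tolerance, bracketed root search on a ratio
  that increases continuously from below 1).
* The 2-D offset ring is re-hulled before use. The input is convex, so
  hulling only removes numerically re-entrant artifacts.

Numerical tie-breaks and degenerate inputs: collinear/coplanar point sets
raise a classed degenerate-hull error and the affected curvature region is
dropped with a logged note; all-false indicator grids and levels at or
above the density maximum yield empty component lists, and an empty gate is
a warning, not an error. Curvature regions are processed in a deterministic
order (component centroids, lexicographic), so results are bit-reproducible
for identical inputs and parameters.

Nonlinear back-transformation (`sinh` after un-standardizing) maps straight
edges to curves, so polygon edges are densified and mesh faces midpoint-
subdivided before mapping; membership is computed in standardized space and
is preserved by construction to within the densification resolution.

## The synthetic generator

`simulate_sample()` draws Gaussian mixture populations specified on the
asinh (design) scale — where real fluorescence populations are roughly
Gaussian — and stores `sinh(design)` as the instrument-unit values, plus a
uniform "debris" background over a design-scale box and exact-value
saturation pile-ups at the channel ceiling (262143, an 18-bit digital
cytometer range; saturation is by definition the instrument maximum).
Labels record the source (cluster index, -1 debris, -2 saturation) and the
sample is a pure function of its spec, including the seed.

The canonical fixtures were chosen once, on sampling-theory grounds
(cluster separations of several standardized units against curvature
bandwidths of ~0.35, arc thickness resolvable by the HDR-phase plug-in
bandwidth), and are frozen: F1, a 1-D bimodal sample with 60/32 weight
split; F2, a 2-D three-population sample whose third population is a
banana-shaped 6-component Gaussian arc with weights peaked at the arc
middle (so the population has one dominant mode and yields one curvature
seed); F3, a 3-D two-population sample with 10% debris. What the generator
does *not* emulate: spillover/compensation structure, autofluorescence,
instrument noise correlations, doublets. Tests passing on these fixtures
demonstrate the pipeline's statistical and geometric contracts, not
robustness to every artifact of real cytometry data.

## Known limitations

* The curvature test's null is a locally flat smooth density. Near hard
  support boundaries (saturation cliffs, uniform-background edges) the
  *smoothed* density genuinely carries negative-definite curvature, and the
  test flags it. This is real signal about the smoothed field, not
  mis-calibration — deep inside a flat region the pointwise flag rate
  measures at or below `alpha` (conservative, since flagging also requires
  negative definiteness) — but it means boundary-adjacent structure can
  seed gates. The practical remedy, as with manual workflows, is composing
  with rectangle gates via `intersect_rectangle()`; debris removal and the
  density floor mitigate but do not eliminate it.
* Polygon components with interior holes (a donut-shaped HDR) are reported
  as separate ring components and membership treats each ring as filled;
  genuinely annular gates are not representable.
* Rectangle intersection in 3-D is applied at membership level; the mesh is
  reported with its clip box rather than re-meshed (exact mesh booleans are
  out of scope).
* The bandwidth matrix of the curvature phase is restricted to
  \(h^2 I\) on standardized data; unequal-axis and full-matrix variants are
  not offered. Dimensions above 3 are not supported.
* Grown regions see *all* events, so two curvature seeds inside one
  population produce overlapping (unmerged, both reported) HDR components;
  membership counts each event once.

## Problem sizes used by the test suite

The suite exercises the full pipeline at `n` = 8000-20000 events (d = 1, 2)
and 8000 (d = 3), mass-convention checks at `n` = 20000 with independent
validation draws of the same size, curvature-calibration simulations at
5000-50000 events per replicate, and geometry oracles on 10^4-10^6 random
points per region. These sizes are representative of single-sample gating
workloads while keeping the default check run short.
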