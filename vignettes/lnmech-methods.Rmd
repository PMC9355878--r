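---
title: "Models and methods behind lnmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lnmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnmech)
```

`lnmech` gathers the quantitative procedures needed to characterise how a
lymph node resists swelling: bulk viscoelasticity from plate compression,
capsule elasticity from micropipette aspiration, stromal-network spacing
from inscribed-circle packing, clonal clustering of reticular cells
against a spatial Monte-Carlo null, conduit fibril alignment against a
fitted centerline, and recoil velocimetry after laser ablation. This
vignette explains each model, its assumptions, the tunable parameters,
and the numerical and design choices — including the ones the underlying
procedures leave genuinely open.

## Plate-compression viscoelasticity

A node held at constant compressive strain relaxes with two distinct
timescales: a fast response within seconds and a slow response over
minutes attributed to cellular rearrangement. The minimal spring-dashpot
(generalized Kelvin) network with this behaviour has two branches, so the
force is fitted as

$$F(t) = F_{eq} + A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2},
\qquad \tau_1 < \tau_2 .$$

Double exponentials are notoriously ill-conditioned: nearby $(\tau_1,
\tau_2)$ pairs produce nearly identical curves, and naive least squares
falls into local minima. `fit_relaxation()` therefore uses variable
projection over a log-spaced timescale grid — for each candidate pair the
amplitudes and asymptote are a *linear* least-squares solve — and only
then refines the best candidates with Levenberg–Marquardt
(`minpack.lm::nlsLM`), with $\tau_i > 0$ bounds and `tau1 < tau2`
enforced by relabelling. The asymptote $F_{eq}$ is the fitted parameter,
not the last sample or a tail average: with recordings of 20–60 min and
slow timescales of minutes, the tail has not fully converged and the
fitted asymptote is the less biased estimate. Fits whose $\tau_2$ exceeds
half the recording span are flagged `viscosity_undetermined` rather than
dropped — the slow branch is then extrapolation, not measurement.

From the fit and the manually measured side-view geometry (heights $h_0,
h_{eq}$; plate-contact radius $R_3$; surface curvature radii $R_1, R_2$,
all in mm; forces in µN — conveniently, µN/mm² ≡ Pa):

$$\varepsilon = 1 - h_{eq}/h_0, \qquad
s = \frac{F_{eq}}{\pi R_3^2}, \qquad
E = s/\varepsilon, \qquad
\sigma = \frac{s}{1/R_1 + 1/R_2}, \qquad
V = \tfrac{4}{3}\pi R_1 (h_0/2)^2 .$$

The effective resistance $\sigma$ (N/m) treats the equilibrium force
balance like a Laplace pressure balance across a curved surface: it is
the surface-tension-like quantity that opposes organ expansion.

The mapping from decay amplitudes to spring constants is not uniquely
pinned down by the printed relations ($\tau_i = \mu_i / k_i$ alone). We
take each branch's stress amplitude over the applied strain,

$$k_i = \frac{A_i / (\pi R_3^2)}{\varepsilon}, \qquad
\mu_i = k_i \tau_i,$$

which is dimensionally forced, reduces to the correct single-branch limit
($A_2 = 0 \Rightarrow \mu_2 = 0$), and makes the generator round-trip
exactly. It is one defensible reading of the deferred derivation, and the
one this package commits to; $\mu_2$ (the slow branch) is reported as
*the* viscosity.

## Micropipette aspiration and capsule tension

With a pipette of inner diameter $d$ (default 15 µm) and suction
$\Delta P$ (operating point 750 Pa), the aspirated tongue height $h$
gives the capsule Young's modulus through Laplace's law,
$E = \Delta P / (h/d)^2$. The quadratic dependence doubles relative
measurement errors: 2% noise on $h$ becomes roughly 4% on $E$, which the
generator/test pair verifies. Passive capsule tension is
$E_{capsule} \times \text{thickness}$ (µm → m), the force per unit
length needed to stretch the full capsule.

## Stromal-network gap analysis

Network spacing is summarised by greedily packing maximal inscribed
circles (2D) or spheres (3D) into the gap space of a binarised network
mask. The loop is: compute the Euclidean distance transform of network ∪
already-placed elements (the image border counts as an obstacle one pixel
beyond the edge, so elements cannot protrude out of the field); place the
largest element that fits, taking the first fitting centre in raster
(column-major) order among ties; when nothing of the current diameter
fits, shrink the diameter by one pixel; stop after single-pixel elements
exhaust the gap area.

The discrete geometry is defined exactly: an element of integer diameter
$d$ centred at pixel $c$ covers the pixels with $4\|p - c\|^2 < d^2$ and
fits iff $4\,\mathrm{EDT}^2(c) \ge d^2$. Both sides of that equivalence
quantify over the same integer lattice, so the fast packer (squared
integer distances via the separable lower-envelope transform, in C++) is
*bit-identical* to an exhaustive packer that enumerates every pixel of
every candidate element — the test suite asserts identical element tables
on random 2D and 3D masks. Determinism of the tie-break (first raster
centre) is a choice; the procedure's source description is silent on
ties.

Distributions report, per unit-diameter bin, the covered fraction of
total gap area and the diameter-weighted fraction (area fraction ×
diameter in µm). Two summary diameters are emitted because the choice is
genuinely open: the default `mean_fitted_diameter` weights by the
weighted fraction (the quantity such analyses plot), and
`mean_diameter_area` weights by plain area fraction. Stack averaging is
an unweighted per-bin mean across slices on the union diameter grid.
Anisotropic stacks are first resampled (nearest neighbour) to isotropic
voxels. Pixel classification/segmentation is upstream and out of scope —
inputs are binary masks.

## Clonal cluster statistics

Detected spots from the two spectral channels are first registered
(channel misalignment from chromatic aberration and sequential
acquisition) with the iterative closest point algorithm: nearest-
neighbour correspondences, optimal rigid transform by SVD (Kabsch),
iterate to convergence. Correspondence is anchored by double-labelled
cells present in both channels. Collinear clouds are rejected (the
rotation is then underdetermined).

Registered spots become cells: mutual nearest-neighbour pairs closer than
the typical cell radius (default 6 µm) merge into yellow cells at the
pair midpoint; the rest stay green or red. Cells outside the node, within
100 µm of its surface (edge effects), or inside HEV volumes are excluded
— and the random null is placed in exactly the same region, so observed
and simulated data face identical constraints. With an analytic ellipsoid
the margin is realised by shrinking each semi-axis by 100 µm (exact
on-axis, mildly conservative obliquely).

Clusters are found per lineage (green with green, red with red; yellow
cells never cluster but stay in the denominator) with DBSCAN: cells are
12-µm spheres, and two cells are neighbours when their surface-to-surface
gap is at most the 20-µm search radius, i.e. centre distance ≤ 32 µm.
That "gap" reading of the radius is the default; the alternative
surface-to-centre reading (26 µm) is exposed as `radius_mode`. `minPts`
is 3 counting the point itself, matching "a minimum of three cells", and
clusters are all density-connected members. The implementation is checked
against a brute-force density-reachability oracle on the full distance
matrix.

The Cluster Factor is the observed clustered fraction divided by the mean
clustered fraction of ten uniform random placements of the same
per-lineage cell counts (rejection sampling in the placement region).
CF = 1 is chance; CF = 100 means 100-fold enrichment. A CF-vs-distance
profile bins cells by distance to the nearest HEV surface (default 50-µm
bins) and takes the per-bin fraction ratio against the pooled null.

One calibration property deserves honesty: with ~300 cells per lineage in
a (600, 400, 400)-µm half-axis phantom eroded by 100 µm, the expected
number of chance DBSCAN clumps is only ≈ 7, so the CF of a single CSR
realisation fluctuates beyond a factor 2 of the null mean in roughly a
tenth of runs. This is Poisson statistics of rare clumps, not an
implementation artefact; the test suite measures exactly this, and the
clustered-generator counterpart (CF > 10 for clonal data) is stable.

## Conduit fibril alignment

The conduit centerline is a natural cubic spline through four support
points, chord-length parameterised. The supports minimise a composite
cost with four dimensionless terms: mean squared distance of fibril
points to the spline (data), integrated squared curvature (smoothness),
squared mismatch between spline arc length and the bundle length, and
variance of the inter-support arc spacings (even coverage). The default
weights are 1, 10⁻³, 10⁻², 10⁻²; because every term is normalised by the
bundle length, the fit is covariant under uniform scaling with the *same*
weights. The bundle length target is estimated as the arc length of a
coarse slab-centroid polyline through the point cloud: individual fibrils
are much shorter than the conduit, so anchoring the length term to mean
fibril length would collapse the spline (we observed exactly that on a
quarter-arc phantom before fixing the target). Optimisation is
multi-start Nelder–Mead (principal-axis initialisation: centroids of four
slabs along the first principal component, plus deterministically
jittered restarts); hand-set support points can be supplied to bypass the
optimiser entirely, mirroring the manual-correction escape hatch such
pipelines need.

Alignment angles use the folded cosine,
$A = \arccos\!\big(|\hat v_{fibril} \cdot \hat v_{centerline}|\big) \in
[0°, 90°]$: fibril polarity is meaningless, so antiparallel counts as
aligned. Fibril tangents are central differences on the (optionally
moving-average smoothed) polyline; the centerline tangent is evaluated at
the nearest centerline point, found by dense arc sampling (1000 points)
with local parabolic refinement. Per-fibril angles are arithmetic means
over sample points (all polyline vertices by default).

## Laser-ablation recoil

Two independent pathways quantify recoil after a cut.

*Kymograph slope.* The retracting edge is, per post-cut frame, the
maximum of the absolute spatial gradient of the (mildly smoothed, σ =
1 px) profile, sub-pixel refined by a parabola through the three
bracketing gradient samples. A frame is accepted only if that peak
dominates the strongest gradient elsewhere in the profile by a factor
(default 1.4): this operationalises the "single dominant edge"
requirement and cleanly rejects pure noise, whose many peaks are of
comparable height — a MAD-style noise floor cannot make that distinction
because in-band fluorescence texture is not noise. Tracking stops when
the edge is lost (e.g. leaves the field). The recoil velocity is the
least-squares slope over a window after the cut (default 5 frames = 1 s
at the 200-ms frame rate); for slow recoils a longer window covering
~2 µm of travel is the appropriate measurement design.

*PIV.* Pre- and post-cut frames are bandpass filtered
(difference-of-Gaussians, σ = 1 and 8 px — the underlying filter choice
is unstated, so these defaults are configurable), tiled into 32-px
windows (50% overlap), and matched by FFT cross-correlation over shifts
up to a third of the window. Validity requires both a minimum correlation
peak (0.3) and peak dominance over runners-up (1.2), which flags
featureless, decorrelated, or quasi-periodic windows. Sub-pixel
refinement is a three-point Gaussian fit on overlap-corrected stencil
values (partial overlap tilts the correlation linearly in the shift; the
correction removes that bias without amplifying noise during peak
selection). The reported recoil is the mean velocity component along the
cut-line normal, oriented towards the region of interest, over valid
vectors inside it.

## Morphometry

Compartment volumes subtract overlaps in a fixed order — lymphatics keep
everything, the T-zone loses lymphatic voxels, follicles lose both — and
fractions are of the exclusive sum, which therefore always total 1 and
tile the union exactly. The YAP/TAZ readout is the mean nuclear over mean
cytoplasmic intensity (gain-invariant; > 1 flags nuclear localisation).
Capsule thickness averages at least three per-node locations; intensity
normalisation divides by the control mean.

## Synthetic data: what it emulates, and what it does not

Every generator is seeded (one stream per invocation; the caller's RNG
state is restored) and echoes its ground truth. They emulate the
*geometry and statistics* the analyses rest on: double-exponential force
decay with Gaussian noise over a default 25%-strain geometry; strand
lattices with known inscribed gap diameters; parent–offspring clustered
point processes (Gaussian offspring dispersion) with singletons and
optional double-labelled cells inside the ellipsoid-minus-cylinders
phantom, with a rigid channel misalignment to exercise ICP; straight
fibrils at an exact cone half-angle about a known spline; a textured band
(sum of random plane waves, continuously sampled so sub-pixel motion is
faithful) retracting at constant speed, with a kymograph averaged over a
31-line band as bench kymographs are; aspiration tongue heights inverted
from a known modulus.

They deliberately do *not* emulate optics (PSF, shot noise,
depth-dependent attenuation), segmentation errors, tissue heterogeneity,
drift, or non-exponential rheology. Passing tests therefore demonstrate
that the *inference machinery* is correct and calibrated under the stated
models — not that real images will be as kind. The default phantom (600,
400, 400)-µm semi-axes with three 20-µm HEV cylinders is desk-scale, not
an anatomical claim.

## Problem sizes and numerical choices in the test suite

The suite exercises: 100 noisy relaxation traces (~450 samples each,
$\tau_1 \in [2, 20]$ s, $\tau_2 \in [100, 600]$ s, 1% noise) for
parameter recovery; 50 random masks (2D up to 32², 3D up to 16³) for
exact packer-oracle equivalence; 200 seeded CSR runs and 200
clustered-generator runs (600 cells, 10 null replicates each) for CF
calibration; fibril bundles of 40 traces at 5°/20°/40° dispersion;
recoil movies at 0.5/2/8 µm/s on 160 × 96-px frames; and 100 random mask
triples for compartment invariants. Degenerate inputs (constant traces,
all-network masks, empty channels, collinear clouds, pure-noise images,
all-blocked placement regions) are tested to fail loudly rather than
silently.

## Known limitations

- The amplitude-to-stiffness mapping $k_i = (A_i/\pi R_3^2)/\varepsilon$
  is one reading of a derivation the source material defers; all derived
  $\mu$ values inherit that choice (the timescales $\tau_i$ do not).
- The ellipsoid edge margin by semi-axis shrinkage is not an exact
  100-µm erosion off-axis; observed and simulated cells share the same
  region, so CF comparisons are internally consistent.
- DBSCAN border points are assigned to the first cluster that reaches
  them (expansion order); membership *sets* are deterministic and
  oracle-checked, only multi-claimed border attribution is
  order-defined.
- The centerline optimiser is local; pathological bundles (e.g.
  self-crossing conduits) need the manual support-point override.
- PIV assumes locally rigid motion within an interrogation window and
  loses validity at shear discontinuities — by design it reports such
  windows as invalid rather than guessing.
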