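# lnmech

Quantitative toolkit for the mechanics and stromal architecture of
swelling lymph nodes.

When a lymph node reacts to immunization it can grow more than tenfold in
volume within two weeks. What resists that expansion — the fibroblastic
reticular cell (FRC) network, its collagen conduits, or the organ capsule —
is a mechanical question, and answering it takes a set of bespoke
quantitative procedures that sit between raw microscopy/rheology output and
biological conclusions. `lnmech` implements those procedures as tested,
scriptable R functions, together with seeded synthetic-data generators so
every stage can be exercised against known ground truth:

- **Plate-compression viscoelasticity** — stress-relaxation traces
  `F(t) = F_eq + A_1 e^{-t/τ_1} + A_2 e^{-t/τ_2}` are fitted with a
  generalized Kelvin (two springs `k_i`, two dashpots `µ_i = k_i τ_i`)
  model; with the side-view geometry this yields the strain
  `ε = 1 − h_eq/h_0`, stress `s = F_eq/(πR_3^2)`, Young's modulus
  `E = s/ε`, the effective resistance
  `σ = s / (1/R_1 + 1/R_2)` (N/m), the tissue viscosity `µ_2`, and the
  node volume `V = 4/3 π R_1 (h_0/2)^2`.
- **Micropipette aspiration** — capsule Young's modulus from Laplace's law,
  `E = ΔP/(h/d)^2`, and the passive capsule tension
  `E_capsule × thickness`.
- **Stromal-network gap analysis** — greedy packing of maximal inscribed
  circles (2D) or spheres (3D) into the gaps of a binary network mask,
  driven by an exact Euclidean distance transform; pore-size
  distributions, diameter-weighted area fractions and mean fitted
  diameters.
- **Clonal cluster statistics** — ICP registration of two-channel spot
  clouds, lineage colour classes, sphere-contact DBSCAN (12-µm cell
  spheres, 20-µm search radius, minimum three same-lineage cells), a
  uniform random-placement Monte-Carlo null, and the Cluster Factor
  CF = (observed clustered fraction)/(simulated clustered fraction),
  including CF-vs-HEV-distance profiles.
- **Conduit fibril alignment** — a four-support cubic-spline centerline
  fitted by a composite cost (data distance, curvature, length mismatch,
  support spacing), and per-fibril alignment angles
  `A = acos(|v_fibril · v_centerline| / (|v_fibril||v_centerline|))`.
- **Laser-ablation recoil** — edge tracking in kymographs with sub-pixel
  refinement, slope-based recoil velocities, and PIV (normalised
  cross-correlation) displacement fields averaged perpendicular to the
  cut.
- **Morphometry** — exclusive compartment volume fractions with the fixed
  overlap-subtraction order, YAP/TAZ nuclear-to-cytoplasmic ratios,
  capsule thickness averaging, control-normalised intensities.

## Worked example

Invert a synthetic stress-relaxation measurement (1% force noise) into
tissue mechanics:

```r
library(lnmech)
g <- gen_relaxation_trace(F_eq = 40, A1 = 30, tau1 = 5, A2 = 20, tau2 = 300,
                          noise_sd = 0.4, seed = 7)
mech <- analyze_relaxation(g$trace, g$geometry)
mech
#> Lymph-node tissue mechanics
#>   strain eps            = 0.250
#>   stress s              = 50.89 Pa
#>   Young's modulus E     = 203.5 Pa
#>   effective resistance  = 0.02544 N/m
#>   viscosity mu2         = 3.071e+04 Pa s
#>   volume V              = 4.189 mm^3
```

The node was compressed to 75% of its height (strain 0.25); the fitted
equilibrium force (39.97 µN, true value 40) over the plate-contact area
gives a 50.9 Pa stress, hence `E ≈ 204 Pa`, and dividing by the surface
curvature terms an effective resistance of 0.025 N/m. The slow relaxation
branch (`τ_2 ≈ 300 s`) carries the tissue viscosity `µ_2 ≈ 3.1 × 10^4 Pa·s`.

Measure network spacing on a lattice phantom with 8-µm gaps
(16 px × 0.5 µm):

```r
net <- gen_network_mask("2d", size = 84, lattice_pitch = 21, strand_width = 5,
                        pixel_size = 0.5)
psd <- pore_size_distribution(fill_gaps_2d(net$mask), net$mask)
psd
#> Pore-size distribution: 3 diameter bins (1-8 um)
#>   mean fitted diameter (weighted) = 7.7 um
#>   mean fitted diameter (area)     = 6.31 um
```

The modal fitted circle matches the constructed 8-µm gap; smaller circles
fill the corners left between the large circles and the strands.

Score clonal clustering of sparse-labelled reticular cells against the
spatial null:

```r
masks <- region_masks()           # ellipsoid phantom, 100-µm edge margin
sim <- gen_madm_cells(masks, n_parents = 15, offspring_per_parent = 10,
                      dispersion_sd_um = 8, n_singletons = 150, seed = 42)
cells <- apply_exclusions(classify_colors(sim$green, sim$red), masks)
st <- find_clusters(cells)
null <- simulate_random(table(cells$color_class)[c("green", "red")], masks,
                        n_reps = 10, seed = 43)
st$cf <- cluster_factor(st, null)
st
#> Cluster statistics: 16 clusters among 448 cells
#>   clustered fraction = 0.3482
#>   cluster factor     = 22.61
```

A Cluster Factor of ~23 means about 23 times more cells sit in
same-lineage clusters than expected from uniform random placement in the
same volume — clear clonal clustering, as constructed (ten offspring per
clone at 8-µm dispersion).

## Data formats

Force traces: CSV (`t_s, F_uN`); geometry: JSON (mm); masks: single- or
multi-page TIFF; spot tables: CSV (µm); fibril traces: SWC-like text (nm);
kymographs/frames: numeric matrices (TIFF-importable). See `R/io.R`
helpers `read_force_trace()`, `read_geometry()`, `read_mask_tiff()`,
`read_spots()`, `read_fibrils_swc()` and their writers.
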