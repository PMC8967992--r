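# npcorg

Quantitative analysis of nuclear pore complex (NPC) organization in fission
yeast nuclei imaged by 3D structured illumination microscopy (3D-SIM), built
around a fully synthetic, ground-truth-bearing simulation of the imaging
experiment.

NPCs appear in 3D-SIM as diffraction-limited puncta on the nuclear envelope
(NE). The package answers, per nucleus: how many NPCs are there, over what
NE surface area, at what density, and how are they arranged relative to
landmarks — the spindle pole body (SPB) and the nucleolus? Because
diffraction-limited detection undercounts crowded spots, every stage can be
run against simulated nuclei whose ground truth is known exactly, which is
how the pipeline's accuracy is calibrated and tested.

It is aimed at quantitative cell biologists and image analysts working with
punctate NE signals in small (yeast-sized) nuclei.

## What it computes

* **Synthetic nuclei** — *n* emitters placed uniformly on a sphere of radius
  *r* with a minimum centre-to-centre spacing (default 100 nm), rendered as
  anisotropic 3D Gaussians (FWHM 100 nm in x–y, 300 nm in z; SD = FWHM/2.355)
  at 40 nm pixels / 125 nm z-steps, then passed through a camera model:
  `I = gain · Poisson(E) + N(0, σ_read)` with gain 20 and σ_read = 40.
  An optional second channel carries an SPB landmark pair separated by
  180 nm, placed in the top polar cap with its axis tangent to the sphere.
* **Spot detection** — iterative "track max, not mask": record the brightest
  voxel, zero a spheroid of 8 px (320 nm) lateral diameter × 5 slices
  (625 nm) around it, repeat while the next maximum ≥ 25% of the original
  image maximum.
* **NE surface model** — 3D convex hull of the detected positions with an
  outlier-removal step (up to 10% of points, removed deepest-first while the
  on-hull fraction increases). Density = count / hull surface area
  (NPCs/µm²); co-detection between channels uses a 250 nm radius.
* **SPA-SIM** — joint two-3D-Gaussian fit of the SPB pair, a 400 nm
  nucleus-edge filter, realignment of every volume onto the pair axis,
  averaging with x-mirroring, and a 12-px-wide axis profile. A protein is
  excluded near the SPB if the normalized profile at the SPB positions falls
  below 0.8 (a threshold anchored to the random-NPC simulation null); zone
  size is the FWHM (= 2.355 × SD) of an inverted-Gaussian fit.
* **Nucleolar profiles** — two-channel NE line profiles aligned at the
  centre of the nucleolar-marker peak (boxcar smoothing, half-max run),
  resampled, averaged, and summarized as the normalized Nup intensity at
  position 0.
* **Staging** — deterministic cell-cycle labels from cell length, nuclear
  count and septation, and SPB-duplication stages from the daughter/mother
  intensity ratio (bands at 0.5 and 0.8).

## Worked example

Simulate one mid-G2-like nucleus (radius 1.25 µm, 125 NPCs — a true density
of 6.37 NPCs/µm²) and measure it back:

```r
library(npcorg)

cfg  <- sim_config(radius_nm = 1250, n_npcs = 125, seed = 42)
sim  <- simulate_nucleus(cfg)
mask <- segment_nuclei(max_project(sim$volume), cfg$pixel_nm)[[1]]
foci <- detect_foci(sim$volume, mask)
hull <- fit_hull(foci)
summarize_nucleus(foci, hull)
```

```
  npc_count surface_area_um2 volume_um3 density_per_um2 intensity_per_area stage
1       109         19.06721     7.5972        5.716621                 NA  <NA>
```

109 of 125 NPCs are detected (crowded spots merge under the masking
spheroid), on a hull of 19.07 µm² — slightly inside the true sphere's
19.63 µm² because an inscribed polyhedron underestimates the surface — for a
measured density of 5.72 vs the true 6.37 NPCs/µm², the expected ~10%
undercount at this density. `analysis/02_density_calibration.R` maps this
error over a radius × density grid; the mean absolute error stays below 30%
at 4–7 NPCs/µm² and grows with density.

The `analysis/` scripts run the full study end to end (condition grid,
density calibration, SPA null and constructed exclusion zone, nucleolar
reductions, staging), writing tables under `results/`.

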