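---
title: "Models and measurement procedures in aureole"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and measurement procedures in aureole}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aureole)
```

## The system

A 3D aggregate of cohesive cells (murine sarcoma S180 expressing
E-cadherin–GFP, ~150 µm across) deposited on an adhesive, fibronectin-coated
substrate spreads by emitting a cellular monolayer — the *precursor film* —
in close analogy with the precursor film of a wetting droplet. When the
substrate is carpeted with sedimented microparticles (MPs, 0.8–1 µm), the
motile cells at the film periphery phagocytose the particles as the front
advances, leaving a cleared film behind and accumulating particles in a dark
annulus of saturated cells at the edge: the *aureole*. The geometry of that
annulus is an assay: its width, together with particle conservation, yields
the volume fraction of particles a cell can internalize.

This package implements the quantitative chain from raw geometry to
parameters: the spreading law, the velocity enhancement by substrate
roughness, the particle-conservation model of the aureole, automated image
measurements, and least-squares fits — exercised end to end on synthetic
data whose ground truth is known.

## Spreading law

The dissipation opposing spreading has a permeation term (cells entering the
film from the aggregate across a region of width ξ) and a slippage term
(film–substrate friction):

$$T\dot S = 2\pi\eta\frac{R\dot R^2}{R_L} + 2\pi k R^2\dot R^2\ln\frac{R}{R_L},$$

with η the tissue viscosity, k the friction coefficient and $R_L$ the
aggregate–film contact radius. Permeation dominates when
$\eta/R_L > k\ln(R/R_L)$ (`permeation_dominant()`), the regime of stiff,
viscous aggregates. Balancing the permeation friction against the driving
force S gives a diffusive spreading law, linear in area:

$$\frac{A - A_0}{R_0} = V^* t, \qquad D = V^* R_0,$$

implemented in `spread_area()` and inverted by `fit_velocity()` (ordinary
least squares of A on t; $V^*$ = slope/$R_0$). On particle-coated substrates
the deposited spheres roughen the interface and increase the spreading
parameter, hence

$$V^*(\varphi_S) = V^*(0)\,(1 + \alpha\,\varphi_S)$$

up to a plateau at $\varphi_S^P$ where the spheres pack densely; above it
the velocity is constant. The clamp is hard (`min(phi_S, phi_plateau)`), not
a smooth crossover, because the observed velocity is flat above the plateau.

## Particle conservation and the aureole

Sedimented particles at areal density ν (surface fraction
$\varphi_S = \nu\pi d^2/4$, which exceeds 1 for multilayers) are cleared by
the advancing front. Every cleared particle is either inside an aureole cell
(concentration $C_i$, at most $C_{is}$) or adsorbed on its membrane (surface
concentration $C_S$, on both faces):

$$\frac{2\pi R\Delta}{A_{cell}}\left(C_i V_{cell} + 2 C_S A_{cell}\right) = \pi R^2\nu.$$

For the first row of cells Δ equals one cell diameter $d_{cell}$; the film
radius at which that row saturates is the critical radius

$$R_c\,\varphi_S = 3\,\phi_{is}\,\frac{d_{cell}}{d}\frac{V_{cell}}{A_{cell}},$$

with $\phi_{is} = C_{is} v_p$ the saturation volume fraction. With the
reference geometry (d = 1 µm, $d_{cell}$ = 22 µm, $V_{cell}$ = 1600 µm³,
$A_{cell}$ = 770 µm²) the right-hand coefficient is 137 µm, so one measured
$R_c$ at known coverage determines $\phi_{is}$ (`phi_is_from_Rc()`). Beyond
$R_c$,

$$\Delta\left(3\frac{\phi_{is}}{d}\frac{V_{cell}}{A_{cell}} + 4\phi_s\right) = R\,\varphi_S:$$

the width grows linearly with R (`aureole_width()`; the two branches are
continuous at $R_c$ when $\phi_s = 0$). Membrane adsorption switches on
above a coverage threshold, $\phi_s = a(\varphi_S - \varphi_{S0})$, which
makes Δ/R saturate at high coverage. Volume and surface fractions convert to
per-cell counts via $n_i = \phi_{is}V_{cell}/v_p$ and
$n_s = 2\phi_s A_{cell}/(\pi d^2/4)$ (`particle_counts()`); for flocculating
particles counts are divided by a cluster factor and refer to clusters.

Clearing is kinetically possible only if a cell finishes internalizing the
particles beneath it before the front moves one cell diameter on: the
passage time is $\tau_p = d_{cell}/V^*$ (≈ 6 min at
$V^* = 6.2\times10^{-2}$ µm/s), to be compared with the ~2 min
internalization time of micron-scale beads (`clearing_feasible()`).
Particles above ~5 µm internalize too slowly and are pushed ahead of the
film instead; that regime is outside this package's scope.

### A note on $V_{cell}$

Two independent cell-volume values circulate: 1600 µm³ (used in the
conservation worked example, and the default here) and 1620 µm³ (the direct
measurement on suspended spherical cells). `cell_geometry(V_cell = 1620)`
switches to the latter; the derived counts move by ~1%.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with embedded
ground truth. It emulates the study conditions, not arbitrary microscopy:

* **Trajectories** (`make_trajectory()`): $R_0$ = 75 µm aggregates, one
  frame every 10 min for 15 h. Each aggregate draws its velocity once from a
  normal law centred on the enhancement law — the across-aggregate SD
  defaults to the dispersions reported per particle type
  (e.g. $0.9\times10^{-2}$ µm/s on bare substrate) — and each area sample
  then receives 5% multiplicative Gaussian noise. The published figures do
  not state a per-frame noise level; 5% relative area noise is a typical
  hand-traced contour repeatability and is the generator's fixed default.
* **Front uptake** (`simulate_front_uptake()`): a discrete, integer-exact
  embodiment of the conservation model. Rows of width $d_{cell}$ ride the
  advancing front; the particles swept from each newly covered annulus go to
  the outermost row with spare internal capacity ($n_i$ per cell), then to
  its membrane allowance ($n_s$ per cell, only above $\varphi_{S0}$), and
  leftovers pass inward. The aureole width is the number of internally
  saturated rows times $d_{cell}$. Cells per row are counted on the front
  circumference ($2\pi R\,d_{cell}/A_{cell}$), the same thin-annulus
  counting the conservation relation itself uses; counting rows as true
  geometric annuli at their own radii instead shifts the emergent Δ(R) slope
  about +10–14% relative to the closed form (the aureole then sits at
  mid-radius $R - \Delta/2$), a model-counting mismatch rather than a
  physical difference. The ledger (swept = ingested + adsorbed + remaining)
  balances exactly, in integers, at every step.
* **Micrographs** (`render_micrograph()`): concentric bright-field-like
  scene — dark aggregate disk, bright cleared film, darkest aureole annulus,
  and an outer carpet of per-pixel Bernoulli speckle at the configured
  coverage (a second, darker speckle layer above full monolayer). Optical
  blur is deliberately omitted: all measurement operations are
  threshold-based, and flat-disk rendering keeps their ground truth exact.
* **Z-stacks** (`render_zstack()`): a spherical cell of volume $V_{cell}$,
  its nucleus (default fraction 0.25), and non-overlapping 1-µm beads placed
  uniformly in the cytoplasm, voxelized at 0.25 µm laterally and axially
  (the acquisition step of the confocal procedure). Bead fractions above 0.4
  are refused as unpackable.

Seeded determinism is a contract: every generator reproduces byte-identical
output under a fixed seed.

What passing tests on these data do **not** show: robustness to uneven
illumination, debris, cell-shape irregularity, optical blur or flocculated
particle clumps. The measurement operations are warranted for synthetic
frames and clean user images of the same structure only.

## Measurement procedures

`measure_film_area()` and `measure_aureole_width()` automate the manual
contour tracing: segment the spread region with and without the dark
peripheral annulus, and convert areas to equivalent-circle radii
($R = \sqrt{A/\pi}$), so the width is a difference of mean radii exactly as
in the manual area-difference procedure. Because a frame carries up to four
intensity populations (film, background, speckle, aureole/aggregate), a
single Otsu split cannot isolate the darkest class; thresholds come from a
1D k-means over intensities (k = 4, centers seeded across the intensity
range, near-duplicate centers merged at 0.08), with the bright cut between
the two brightest classes and the dark cut between the two darkest. The
segmentation keeps the largest connected component and fills holes; an
annulus less than one pixel wide is reported as "not found" rather than as a
width.

`measure_surface_fraction()` applies an Otsu threshold inside the carpet
region (everything outside the measured outer contour) and reports the dark
fraction. It is valid below one monolayer: projected-area thresholding
saturates at full coverage, so multilayer coatings ($\varphi_S > 1$) must be
quantified from the suspension instead (`coating_from_suspension()`).

`zstack_volume_fractions()` sums per-slice thresholded areas times the slice
spacing — a rectangle rule on the lower slice, mirroring the
elementary-volume summation of the confocal procedure, not a trapezoidal
correction. `radial_darkness_profile()` averages intensity azimuthally in
bins of one cell diameter, the check that particle density across the
aureole is uniform.

## Fitting choices

With at most seven coverage levels per particle type, derivative-based
breakpoint optimization is fragile; both `fit_enhancement()` and
`fit_uptake()` locate their breakpoints ($\varphi_S^P$, $\varphi_{S0}$) by a
coarse 0.05 grid scan with 0.01 local refinement, solving the remaining
parameters by least squares at each candidate. Ties between breakpoints
(exactly collinear data) resolve to the largest candidate, i.e. the
internalization-only interpretation. `fit_uptake()` is sequential:
$\phi_{is}$ from a through-origin fit of the linear branch first, then
$(a, \varphi_{S0})$ on the plateau branch with $\phi_{is}$ fixed — matching
the two-step analysis of the experimental curves. The published threshold
values ("~0.5", "~0.2", "~0.46") are treated as approximate; fits re-estimate
them. Printed slope a = 0.9 and plateau Δ/R = 0.3 are not exactly mutually
consistent (the asymptotic plateau is 1/(4a)); fits report what the data
give.

A single noisy six-point ladder does not identify α reliably (the ratio
slope/intercept and the breakpoint are strongly correlated at 15% point
noise), so recovery checks measure each coverage level on a cohort of 20
aggregates — the published points are themselves means over cohorts of 8–48
— and fit the pooled ensemble.

## Numerical conventions

* Units: µm, s, µm², µm³ everywhere internally; SI constants (k_BT in J, g
  in m/s², densities in kg/m³) convert at the boundary of
  `sedimentation_length()`.
* Neutral or positive buoyancy reports an infinite sedimentation length with
  a no-sedimentation flag, never an error; a stalled front gives an infinite
  passage time.
* `aureole_width()` special cases: constant $d_{cell}$ below $R_c$ (no
  partial-filling interpolation — the first row is one cell row); zero width
  at zero coverage; an error if both $\phi_{is}$ and $\phi_s$ are zero with
  particles present (they must go somewhere).
* Degenerate fits are flagged, not silently extrapolated:
  `plateau_unidentifiable` when the RSS profile over breakpoints is flat,
  `no_plateau_branch` when all points are linear, `non_spreading` for a
  negative area slope.
* Problem sizes in the shipped tests and analysis scripts: cohorts of 10–20
  aggregates, front-uptake runs of 90–1000 steps, 450×450 px frames, 63³
  voxel stacks — small enough to re-run in seconds while leaving the
  quantization of each discrete mechanism well below the tolerances checked.

## Known limitations

* The front-uptake simulator is deterministic (uniform partitioning of
  particles among the cells of a row); a multinomial partitioning mode was
  considered and dropped because the measured aureole darkness is uniform,
  so heterogeneity would add variance the data do not constrain.
* No PDE solution of the dissipation balance is attempted; the package
  evaluates the printed balance and the regime criterion only.
* Flocculation kinetics are not modelled; for PsAmine200 the cluster factor
  is exposed as a free parameter and count rows for that particle refer to
  clusters.
* Real micrograph segmentation (uneven illumination, debris) is explicitly
  out of warranty; the imaging module is validated on rendered scenes.
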