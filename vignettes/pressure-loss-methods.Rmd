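---
title: "Quantifying pharyngeal pressure loss: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pharyngeal pressure loss: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwayloss)
```

## The problem

During inspiration the respiratory muscles generate a negative pressure
gradient that drives air from the nostrils to the alveoli. Part of that
mechanical energy is not converted into kinetic energy of the flow but
dissipated — the *pressure loss*, a surrogate for energy loss. In patients
with obstructive sleep apnoea the pharyngeal segment between the hard
palate (plane I) and the tip of the epiglottis (plane IV) is where most of
this loss concentrates: the lumen is hourglass-shaped, with a
velopharyngeal constriction (the minimum-area plane, *plane_Amin*) that
accelerates the flow into a pharyngeal jet, and a downstream expansion
where the jet separates from the anterior wall and a recirculation region
forms. Narrower constrictions and longer constricted segments mean larger
losses, requiring more negative driving static pressure — mechanical
conditions that favour further collapse.

`airwayloss` implements the analysis chain that quantifies this: slicing a
triangulated airway surface into a stack of cross-sectional planes,
morphometry of the constriction, a reduced-order flow model, the pressure
algebra (static Ps, dynamic Pv, total Pt and plane-I-referenced Pt'),
subsegmental loss coefficients and square-law resistances, wall-shear
aggregation, a frictional/interior loss decomposition, and a three-level
jet/separation classification. Because patient imaging and a 3D
Navier–Stokes solver are out of scope, the package carries its own
synthetic geometry and flow-field generators; they are first-class, tested
components, and the quasi-1D solver doubles as the verification oracle for
the post-processing chain.

## The plane stack and its conventions

Planes are perpendicular to the z axis, and z *decreases* downstream, so
plane indices increase in the flow direction; plane spacing defaults to
0.5 mm. Areas are reported in mm² at the I/O edges (the CT convention) and
converted to SI internally; segment length is reported as
`(n_planes − 1) × spacing`.

`slice_airway()` intersects each plane with the triangle mesh, chains the
intersection segments into closed contours by the identity of the crossed
mesh edges (exact, no coordinate tolerance), and sums the absolute
shoelace areas of all loops — a bifid or non-convex lumen may legitimately
intersect a plane in several contours, and only total area enters the
downstream equations. Nested (annular) contours are not distinguished;
airway lumina do not produce them. Planes through mesh vertices are nudged
by 10⁻⁶ of the spacing toward the mesh interior. An empty intersection is
an error naming the plane, because a discontinuous lumen invalidates the
stack — the same reason such models are excluded from imaging studies.

`find_plane_amin()` returns the global area minimum of a region; plateau
ties break to the most upstream plane, which keeps the result
deterministic and consistent with the requirement that plane_Amin be
smaller than at least one neighbour. The velopharynx/oropharynx dividing
plane (soft-palate tip) is an anatomical landmark that cannot be detected
on a bare mesh, so it is a required configuration input. Two area-ratio
diagnostics are exposed: the plane-to-next ratio `A_N / A_{N+1}`
(`area_ratio_series()`, the primary definition) and the ratio to
plane_Amin (`area_ratio_to_amin()`).

## The quasi-1D flow model

`solve_quasi1d()` marches the total pressure downstream at a fixed
volumetric flow rate (default 18 L/min, the standard steady inspiratory
condition all analyses here assume):

- bulk velocity `v_N = Q / A_N`;
- `Pt_1` is the plane-I datum (0 Pa): referencing to plane I removes the
  losses already incurred in the nasal cavity, so Pt' isolates the segment
  of interest;
- `Pt_{N+1} = Pt_N − ΔPt_friction − ΔPt_expansion`, both losses ≥ 0, so Pt
  never increases downstream;
- `Ps_N = Pt_N − ½ρ v_N²`, making `Pt = Ps + Pv` an identity.

Friction follows the Darcy–Weisbach form `f (Δz/D_h) ½ρv²` with the
circular-equivalent hydraulic diameter `D_h = 2√(A/π)` and wall shear
`τ_w = (f/8) ρ v²`. The friction factor is laminar (`64/Re`) up to
Re = 2000 and Blasius (`0.316 Re^{-0.25}`) above 4000, with a linear blend
between — the pharyngeal constriction sits at Re ≈ 2–6 × 10³, squarely in
the transitional band, and no exact law exists there; the blend is
continuous at both ends. A `"none"` model provides the exact lossless
Bernoulli limit. Gas properties default to air at ~20 °C
(ρ = 1.204 kg m⁻³, μ = 1.81 × 10⁻⁵ Pa s).

Expansion loss uses the Borda–Carnot form `½ρ v_up² (1 − A_up/A_down)²`,
the classical irreversible loss of a sudden expansion, as the model for
separation/recirculation ("interior") loss; contractions incur no
expansion loss, and the contraction loss coefficient defaults to 0 (ideal
acceleration — upstream losses are frictional). Applying Borda–Carnot per
0.5 mm step of a *gradual* expansion underestimates the loss of a truly
abrupt one; it is a reduced-order surrogate, not a turbulence model.

The solver is verified against closed forms: a laminar straight tube
reproduces the Hagen–Poiseuille drop `8μLQ/(πr⁴)` and mean wall shear
`4μQ/(πr³)` essentially exactly, and with all losses off `|Pt'|` stays at
machine zero for arbitrary profiles.

## Post-processing equations

`mass_flow_average()` implements the standard post-processor convention
`Σ φ ρ|u·n| a / Σ ρ|u·n| a`; the weighting formula is a convention, not a
published equation, and the mass-flux form is adopted because it is what
CFD post-processors compute. From the per-plane averages the chain derives
`Pv = ½ρv²`, `Pt = Ps + Pv`, and `Pt'_N = Pt_N − Pt_1`.

Each subsegment (lumen slab between planes N and N+1 with its lateral wall
band) gets, via `subsegment_resistance()`:

- the drop `ΔPt = Pt_N − Pt_{N+1}`;
- the loss coefficient `K = ΔPt / Pv_N`;
- the square-law resistance `R = ΔPt / (v_N (A_N + A_{N+1})/2)²`, with `v`
  the mass-flow-averaged velocity *magnitude* at plane N.

`R` is dimensionally Pa s² m⁻⁶ and is reported as such; published tables
sometimes print such resistances with a bare "Pa" label, and ratios of two
resistances are unit-free either way. Negative drops (apparent
total-pressure gain, possible in noisy fields) yield negative R and are
flagged, not suppressed.

`loss_decomposition()` splits each drop into a frictional part — the wall
dissipation power per unit flow, `τ̄_w · A_wall · v̄_N / Q` — and an
interior remainder. The wall-power estimate is chosen because it is exact
in the laminar Poiseuille limit (`τ_w · 2L/r = ΔP`), so a straight tube
attributes 100% of its loss to friction; whatever it cannot explain in an
expansion is separation/recirculation/turbulence loss. A negative interior
component is a diagnostic of the estimate overshooting and is reported
as-is.

## The three-level classification

`classify_levels()` partitions the stack into: level 1, *jet formation*
(plane I through plane_Amin inclusive — kinetic energy accumulates as the
lumen converges); level 2, *pre full separation* (the near-constant
constricted run after plane_Amin, while `A/A_amin ≤ θ_exp` and the
reversed-flow area fraction stays below `θ_rec`); level 3, *full flow
separation* (the rapidly expanded remainder with an established
recirculation region). The taxonomy is narrative in origin and carries no
published thresholds, so `θ_exp = 1.5` and `θ_rec = 0.10` are declared
configuration values, fixed explicitly by every test that depends on
them; level boundaries are monotone in `θ_exp` by construction. Level 1
closes at plane_Amin inclusive because the pressure extrema and jet
formation sit at the constriction. Whether planes upstream of the first
area decrease should count as "jet formation" is not specified anywhere;
level 1 simply spans from plane I.

Recirculation is detected as reversed near-wall flow:
`reverse_flow_fraction()` is the area-weighted fraction of samples whose
axial velocity opposes the bulk direction.

## The synthetic generators

`airway_spec()` / `make_area_profile()` build hourglass area profiles:
monotone cosine taper from the inlet area to the minimum, an optional
constricted plateau just downstream of the minimum, and a smooth expansion
below. Eight named templates reproduce the morphometry of the reference
subjects (`ftp_reference_morphometry()`): plane counts 91–134, dividing
planes, velopharyngeal plane_Amin locations, and minimum areas from
0.5443 to 2.226 cm². Three generator choices deserve note:

- the plateau sits entirely *downstream* of plane_Amin (that is where the
  constant constricted segment lies anatomically) and rises by only 0.4%
  across its length, keeping the minimum unique without ever making a long
  plateau less resistive than a plateau-free expansion onset;
- plateau lengths for the templates are set from the reported level-2
  plane ranges (e.g. 20 mm for the mouth-closed FTP II subject whose
  constriction spans planes 14–54); inlet and expansion areas are not
  published and are fixed once at realistic adult values (180–320 mm²);
- templates are single-constriction shapes parameterized on the
  *velopharyngeal* minimum; for the mouth-open FTP I subject, whose true
  global minimum is oropharyngeal, the template still models the
  velopharyngeal landmark — the generator emulates a shape class, not a
  patient.

`make_surface_mesh()` sweeps a circle or ellipse along z. Only area — not
cross-sectional shape — enters any equation, so shape is free. Ring
vertices lie on the exact ellipse; the inscribed polygon under-represents
the area by `1 − (n_θ/2π) sin(2π/n_θ)` (≈ 2.5% at n_θ = 16, 0.16% at 64),
which is precisely the refinement handle the slicer-convergence tests
exercise, mirroring a grid-independence criterion of < 1% variation.
`perturb_mesh()` adds bounded radial noise for robustness fixtures. STL
I/O quantizes coordinates to IEEE float32 in both ASCII and binary
variants, so the formats are geometrically bit-identical and binary
round-trips are exact.

`make_flow_field()` builds discrete plane samples: a forward jet core of
area fraction β (default 1 upstream of the constriction, narrowing
linearly to 0.6 through the expansion) and an anterior reversed region
moving at γ = 0.2 of the core speed, with speeds normalized so the net
flux equals Q *exactly* on every plane (the radial sampling boundaries
include the core interface exactly, so the reversed area fraction is
exactly 1 − β). β and γ are illustrative defaults: no quantitative jet
width or recirculation strength is published, only the qualitative
structure. TKE peaks at the core/recirculation interface where the shear
layer sits. Static-pressure samples are anchored so that each plane's
mass-flow-averaged *total* pressure equals the quasi-1D solution: the
solver owns the loss budget and the jet structure only redistributes it
between Ps and Pv. For β = 1 this reduces to sampling the solver's static
pressure directly, which is why a uniform field is the oracle-equivalence
fixture — post-processing must (and does) reproduce the solver's
Ps/Pv/Pt to discretization precision there. Wall patches carry the
solver's `τ_w`, optionally with seeded bounded noise.

What the generator does **not** emulate: curved airway centerlines
(planes are always perpendicular to a straight z axis, as in the imaging
convention), secondary laryngeal jets, unsteady/cyclic breathing,
turbulence spectra, or the fine-grained WSS topography of a real wall.
Passing tests therefore demonstrate correctness of the *analysis chain*
and the reduced-order physics, not predictive accuracy for patient
anatomy.

## Numerical choices and degenerate inputs

- Plane/vertex coincidence: 10⁻⁶-spacing nudge toward the mesh interior.
- plane_Amin ties: first (most upstream) minimal plane.
- An all-equal-area region raises "no constriction" in
  `find_plane_amin()` but is *flagged* (not an error) in
  `morphometry_report()`.
- Zero mass flux through a plane makes the mass-flow average undefined:
  error.
- Flux normalization with β too small and γ too large would require
  non-positive net flux: error, reported explicitly.
- Eq-level identities (`Pt = Ps + Pv`, `ΔPt = K·Pv = R·(v̄Ā)²`,
  `frictional + interior = ΔPt`, `Pt'(plane I) = 0`) hold to machine
  precision by construction and are asserted on randomized records.

## Problem sizes

The test suite and the acceptance script run the full stack at the
reference scale — 91–134 planes at 0.5 mm, meshes of ~13k–17k triangles at
n_θ = 64, 25-template monotonicity grids — which keeps every geometry
round-trip exact to within 2% and the whole suite fast enough to run on
every change.

## Known limitations

- The quasi-1D model has no turbulence closure; TKE in the synthetic
  fields is shaped, not solved.
- Borda–Carnot per grid step under-counts abrupt-expansion loss relative
  to a 3D solve; comparisons across geometries (the monotone trends) are
  meaningful, absolute drops are not patient predictions.
- The frictional/interior split is exact only in the Poiseuille limit;
  in strongly separated regions it is an estimate.
- Published per-subject resistance values are reproduced as a reference
  table, not recomputed, since the patient geometries behind them are not
  available; the package recomputes their *ratio* and every quantity that
  is derivable from stated conditions (areas, flow rate, gas properties).
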