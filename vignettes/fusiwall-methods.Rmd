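---
title: "Methods: co-analysis of wall enhancement, hemodynamics and morphology in fusiform aneurysms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-analysis of wall enhancement, hemodynamics and morphology in fusiform aneurysms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Intracranial fusiform aneurysms (IFAs) are circumferential, non-saccular
dilations of an intracranial artery, classically divided into three
Flemming types: *fusiform* (a focal spindle-shaped bulge), *dolichoectatic*
(uniform dilation with elongation) and *transitional* (uniform dilation
with a superimposed focal expansion). Two imaging-derived quantities are
widely read as markers of wall instability:

* **aneurysm wall enhancement (AWE)** — contrast uptake of the wall on
  post-contrast high-resolution vessel-wall MRI, linked to inflammation and
  neovascularization; and
* **adverse near-wall hemodynamics** — low and oscillatory wall shear
  stress, quantified from CFD as TAWSS, OSI, GON and RRT.

`fusiwall` implements the full co-analysis connecting the two on a
per-vertex basis over the aneurysm surface, together with centerline
morphometrics (D~max~, L~max~, curvature, torsion), cohort statistics, and
a seeded synthetic cohort generator that stands in for the clinical
HR-MRI/CFD inputs so that every stage is exercisable, testable and
reproducible without any patient data.

## Data model

* `surface_mesh` — triangulated luminal wall (mm) with named per-vertex
  scalar/vector attributes. Legacy ASCII VTK polydata is the canonical
  carrier of per-vertex fields; STL and PLY carry geometry only.
* `centerline` — ordered polyline with cumulative arc length and optional
  aneurysm-segment bounds.
* `wss_series` — per-vertex wall-shear-stress vectors (Pa) at instants
  spanning one cardiac cycle of duration $T$.
* `intensity_volume` — post-contrast voxel grid with a 4×4 voxel-to-world
  affine (NIfTI convention: 0-based indices, a voxel's world position is
  the affine applied to its integer index), plus pituitary-stalk and lumen
  ROI masks stored as companion NIfTI files.

All lengths are mm, stresses Pa, times s.

## Hemodynamic indices

With $\mathrm{WSS}_i$ the instantaneous WSS vector and $T$ the cycle:

$$\mathrm{TAWSS} = \frac1T \int_0^T |\mathrm{WSS}_i|\,dt, \qquad
\mathrm{OSI} = \frac12\left(1 -
  \frac{\left|\int_0^T \mathrm{WSS}_i\,dt\right|}
       {\int_0^T |\mathrm{WSS}_i|\,dt}\right),$$

$$\mathrm{GON} = 1 - \frac{\left|\int_0^T \mathbf G\,dt\right|}
       {\int_0^T |\mathbf G|\,dt}, \qquad
\mathrm{RRT} = \frac{1}{(1 - 2\,\mathrm{OSI})\,\mathrm{TAWSS}}
             = \frac{T}{\left|\int_0^T \mathrm{WSS}_i\,dt\right|}.$$

Three choices deserve comment:

* **Magnitude inside the TAWSS integral.** TAWSS is defined as the
  time-averaged *magnitude* of the shear vector. Only under that
  convention does the right-hand RRT identity hold, and the package
  asserts the identity to 1e-10 relative at every defined vertex.
* **The gradient vector $\mathbf G$.** Following the original
  gradient-oscillatory-number construction, $\mathbf G$ collects the two
  diagonal components of the surface gradient of the WSS components in a
  per-vertex tangent frame $(\hat p, \hat q)$ aligned with the
  time-averaged WSS direction: $\mathbf G = (\partial W_p/\partial p,\,
  \partial W_q/\partial q)$. Surface gradients are per-face linear (P1)
  gradients averaged to vertices with face-area weights; this is exact for
  fields linear over a planar patch and is cross-checked in the tests
  against an independent 1-ring least-squares fit. Where the mean WSS is
  numerically parallel to the vertex normal the frame is replaced by an
  arbitrary tangent basis and the vertex flagged.
* **Time integration** is a composite trapezoid over the supplied samples
  of a single (final) cycle; no periodicity is assumed. Doubling the
  sampling rate moves TAWSS/OSI by well under 0.5 % on the default
  waveform. Degenerate vertices ($\int|\mathrm{WSS}|dt = 0$ or
  $\int \mathrm{WSS}\,dt = 0$) get OSI/GON 0 and RRT $+\infty$ and are
  flagged.

Aneurysm TAWSS is additionally reported normalized by the area-weighted
mean TAWSS of the parent vessel (the tube proximal to the segment, falling
back to everything outside it), making magnitudes comparable across cases.
Regional summaries use area-weighted means by default (a plain-mean flag
exists); whether the original analysis weighted by area is not stated in
its source, and at the mesh resolutions used the difference is small.

## Morphometrics

Centerlines are resampled to uniform arc length, then differentiated by a
Savitzky–Golay-style local polynomial fit (degree 4, window 7 points)
giving $r'$, $r''$, $r'''$, from which
$\kappa = |r' \times r''|/|r'|^3$ and
$\tau = (r' \times r'') \cdot r''' / |r' \times r''|^2$ (reported as
$|\tau|$, matching the nonnegative clinical summaries). Where
$|r' \times r''|$ falls below 1e-7 (straight portions) both are set to 0.
The 0.1 mm sampling used in the tests recovers circle and helix closed
forms within 1 %.

The aneurysm segment is the maximal contiguous arc-length interval where
the local radius reaches 1.5× the parent radius — the common clinical
definition of fusiform dilation — with the parent reference taken as the
median radius over the profile's lowest quartile (the non-dilated tube).
The local radius at a centerline point is measured on the cross-section
cut by the plane normal to the local tangent, keeping the connected
section curve nearest the centerline.

**D~max~ is a caliper diameter.** The clinical phrasing "maximum distance
between the centerline and the surface" reads as a radius, but reported
clinical values (8–13 mm for vertebrobasilar IFAs) are diameters by
convention, so `d_max()` returns the maximal cross-sectional caliper
diameter (maximum pairwise distance among section points); the radius-like
variant is available via `as_radius = TRUE`. L~max~ is the arc length of
the segment.

## Enhancement mapping

The analysis mirrors standard vessel-wall MRI practice: the maximum signal
of the pituitary stalk is the reference; voxels at or above 0.6× that
reference, outside the lumen, within a 1.5 mm band of the luminal surface
(about two diagonals of the 0.7 mm voxels) and not in the stalk ROI form
the AWE segmentation. The segmentation is projected to the surface: a
vertex is enhanced when a mask-voxel centre lies within 1.5 mm, taking the
nearest such voxel's intensity (nearest-voxel, not interpolated — the
segmentation is a hard mask). The enhancement ratio is ER = intensity /
stalk maximum; non-enhanced vertices carry ER = 0 so node-wise
correlations operate on all vertices. Enhancement area, its proportion of
the segment area, and CR~max~ (max ER over the segment) use barycentric
vertex areas (one third of each incident face), so enhanced and
non-enhanced areas partition the segment area exactly. Registration
between volume and mesh is an input (identity for synthetic cases).

## The synthetic cohort generator

The generator defines the study conditions for every test: 7 cases per
Flemming type (21 in all), mirroring the clinical design it emulates.

**Geometry.** A centerline (helix with radius 9–14 mm and pitch 2.5–4.5 mm,
giving gentle curvature ~0.07–0.1 mm⁻¹) is swept with a
rotation-minimizing frame (double-reflection method — a Frenet frame is
undefined at inflections) at radius

$$r(s) = r_0\left[1 + (g-1)\,w(s) + A e^{-(s-s_0)^2/2\sigma^2}\right],$$

where $w(s)$ is a raised-cosine plateau over the dilated extent tapering
to 0 at inlet and outlet. The taper is a deliberate design choice: a
uniform dilation applied to the whole tube would leave no parent vessel,
making parent-normalized TAWSS and radius-ratio segmentation meaningless;
real dolichoectatic segments also rejoin normal-caliber artery. At the
bulge centre $r(s_0) = r_0(g + A)$. Type recipes (before ±8 % lognormal
jitter): fusiform $g=1$, $A=1.55$, length 38 mm; dolichoectatic $g=2.6$,
$A=0$, 45 mm; transitional $g=2.2$, $A=1.35$, 52 mm, with parent radius
1.7–1.9 mm — chosen once so the per-type size ordering matches the
clinical cohort (transitional largest D~max~ and L~max~, fusiform
smallest).

**Flow surrogate.** Per-vertex WSS is a Poiseuille-type axial component
$4\mu Q(t)/(\pi r(s)^3)$ along the local tangent (blood: $\rho$ = 1066
kg/m³, $\mu$ = 0.0035 Pa·s), driven by a two-peak carotid-like waveform
over $T = 0.8$ s at 100 samples (0.008 s step), with peak flow set so the
nominal peak Reynolds number $2\rho Q_{peak}/(\pi\mu r_0)$ sits near 600
(500–700 across the cohort's parent radii). Inside the dilation a
transverse component $\beta_{osc}\cdot 0.12\,\tau_{parent}\cdot
w_{bulge}(s)\,(0.6 + 0.4\cos 2\theta)\sin(2\pi t/T)$ oscillates along the
circumferential direction. This is *not* a Navier–Stokes solution; it is a
surrogate with the interface of one (a per-vertex vector time series) that
reproduces, by construction, the qualitative near-wall regimes CFD
predicts in fusiform dilations: the $r^{-3}$ law keeps bulge TAWSS below
parent TAWSS, the sign-alternating transverse term raises OSI toward 0.5
in the bulge, and its circumferential modulation makes the spatial WSS
gradient oscillate in direction, elevating GON there. Both inequalities
(bulge TAWSS below / OSI above parent) are asserted on every generated
case.

**Enhancement surrogate.** Voxels are classified against the tube ground
truth (lumen: centre within $r(s)$ of the axis; wall: the next one-voxel
shell). Wall intensity is $I_{stalk}(a + b\,\mathrm{rank}(RRT)/n + \eta)$
from the nearest vertex, clipped at 0: enhancement rises with the *rank*
of relative residence time (RRT is heavy-tailed; rank coupling gives a
controllable Spearman structure). $\eta$ is Gaussian noise smoothed over
the mesh 1-ring graph (12 sweeps) and rescaled to sd `noise_sd` — wall
enhancement on MRI is regionally coherent, so the noise is patchy rather
than voxel-iid; with iid noise the 1.5 mm projection radius would dilate
the enhanced set to the whole segment. Defaults $a=0$, $b=0.7$,
sd $=0.15$ put the dilated wall just around the 0.6 threshold, yielding
partial, patchy enhancement and weak-to-moderate node-wise correlations
(|ρ| ≈ 0.1–0.5), the regime the clinical analysis reports. A disjoint
stalk block carries a ramp whose maximum is exactly $I_{stalk}$;
background sits at 0.15 and the blood pool at 0.5 of it.

**What the generator does not emulate:** real lumen segmentation error,
registration error, through-wall partial-volume profiles,
patient-specific inflow, non-Newtonian rheology, wall compliance, and
spatial autocorrelation structure beyond the smoothed noise. Passing
tests therefore demonstrate correctness of the measurement pipeline and
internal consistency of the analysis on data with known structure — not
clinical validity on real HR-MRI/CFD inputs.

## Statistics

* **Mann–Whitney U** (enhanced vs non-enhanced region means, pooled across
  cases, unpaired — matching the originating analysis; a paired Wilcoxon
  alternative is reported alongside since the regions are within-case).
  For TAWSS the pooled comparison uses the parent-normalized form — the
  stated purpose of that normalization is cross-patient comparability of
  TAWSS magnitudes, and pooling raw Pa values lets between-case level
  spread (parent caliber enters as $r^3$) swamp a within-case difference
  that is otherwise present in every case; raw-Pa region means are
  reported alongside:
  midrank U; exact p by the exact U distribution when both groups have
  n < 12 and no ties, else normal approximation with tie and continuity
  corrections. The two routes agree within 0.01 at n = 10.
* **Spearman** (per-case, ER vs each index over all segment vertices):
  midranks + t approximation with n−2 df; strength labelled "moderate"
  when |ρ| > 0.3, significance flagged at p < 0.001, uncorrected (a
  Bonferroni flag exists, off by default). Spatial autocorrelation of
  surface nodes inflates node-wise significance; it is acknowledged, not
  corrected — the same limitation as the analysis this mirrors.
* **One-way ANOVA** across the three types (classic fixed-effects,
  `var.equal`), preceded by Shapiro–Wilk normality reported per variable
  but not used to switch tests.

`cohort_report()` emits the four result tables: per-type mean ± SD with
ANOVA p; pooled region comparison with Mann–Whitney p; the per-case ρ
grid; and cohort-level Spearman of enhancement area against D~max~ and
L~max~.

## Numerical choices and problem sizes

* Nearest-neighbour queries (voxel↔vertex) use a grid-binned search with
  expanding shells; exhaustive scans back stragglers, and the brute-force
  definition is what the test oracles implement.
* Swept meshes default to 48 vertices per ring at 0.7 mm ring spacing
  (≈3–5 k vertices per case); volumes to 0.7 mm isotropic voxels. The
  packaged analyses and tests run the full 21-case design at these
  resolutions; closed-form geometry checks use 0.1 mm centerline sampling.
* Division-by-zero policy: OSI, GON → 0 and RRT → +∞ at degenerate
  vertices, all flagged.
* Determinism: every stochastic stage takes an integer seed; case seeds
  derive from the master seed, and generators save and restore the global
  RNG state. Re-running a configuration reproduces byte-identical tables.

## Known limitations

* The segment detector assumes a single dominant dilation; multiple
  disjoint dilations return only the longest.
* `local_radius` requires the centerline to lie inside the mesh; slices at
  open tube ends are interpolated from neighbours and flagged.
* The lumen/wall voxel classification of the *generator* uses ring-centre
  distances (exact for swept tubes only); the *analysis* itself never
  relies on that shortcut.
* Proportion-enhanced per type is not calibrated to the clinical table —
  only size orderings are; the clinical proportions depend on wall
  pathology the surrogate does not model.
* Node-wise p-values inherit the spatial-autocorrelation caveat above.
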