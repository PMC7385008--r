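---
title: "Methods: geometry consistency and wall-shear agreement for tubular vessel models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry consistency and wall-shear agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselwss)
```

## The problem

Patient-specific flow simulation starts from a surface model of the vessel
lumen segmented from a 3D image. Two acquisitions of the same anatomy — two
MR sequences, two time points, two observers — yield slightly different
surfaces, and because wall shear stress (WSS) depends nonlinearly on lumen
caliber, small geometric differences amplify into larger differences in the
simulated hemodynamics. This package implements the measurement chain needed
to quantify that amplification on tubular vessels such as the arteriovenous
fistula (AVF), where WSS patterns are implicated in stenosis development:

1. a **synthetic phantom generator** producing paired "segmentations" of
   known tubes,
2. **centerline and area profiling** of watertight surface meshes,
3. **flow-direction metrics** along the centerline,
4. **TAWSS/OSI post-processing** of wall-shear time series, and
5. **paired agreement statistics** (Bland–Altman, a normalized
   summed-difference error metric $E_f$).

Everything runs on synthetic data, so every recovered quantity has an
analytic ground truth.

## Geometry: centerline and area profile

A vessel model is a watertight triangulated surface in millimetres
(`surface_mesh`). Its centerline $\gamma(s)$, parameterized by arclength
$s$, is extracted by the maximal inscribed sphere principle: points deep
inside the lumen, equidistant from the wall, trace the vessel axis.
Concretely, `extract_centerline()`:

1. voxelizes the lumen interior (ray-casting parity test against the closed
   surface), at a pitch defaulting to a quarter of the estimated lumen
   radius $2V/S$ (volume over surface area — exact for a long cylinder),
   capped at $4\times10^6$ voxels;
2. computes the exact Euclidean distance field from each interior voxel to
   the wall (separable transform), giving the local inscribed radius
   $r_\text{local}$;
3. finds the minimum-cost 26-connected path between the two openings with
   step cost $\ell / (r_\text{local} + \varepsilon)$,
   $\varepsilon = \text{pitch}/20$, which makes wall-hugging shortcuts
   expensive and keeps the path on the inscribed-sphere ridge;
4. smooths the voxel path coordinate-wise with a smoothing spline against
   arclength and resamples it uniformly; and
5. **refines** each sample to the area centroid of the perpendicular
   cross-section contour, in two passes (the second re-slices with the
   tangents implied by the first). On a tube, the perpendicular section
   centroid lies on the generating path, so this step removes the voxel
   discretization error entirely; the voxel path only needs to be
   topologically right.

Refinement stations whose slice would graze an end cap are dropped rather
than kept at voxel accuracy; the user-supplied endpoint anchors each end.
Tangents are central differences on the refined curve (one-sided at the
ends), and the inscribed radius is re-measured as the exact point-to-surface
distance. On the generated phantoms this pipeline recovers a straight tube's
axis to below $10^{-10}$ mm and a 20 mm arc to better than 0.02 mm — the
test suite enforces 0.1 mm and 0.15 mm respectively, which is what matters
at 1 mm profile spacing.

The cross-sectional area $A(s)$ is measured by slicing the mesh with the
plane through $\gamma(s)$ normal to the tangent. Intersection segments are
computed once per mesh edge, so they chain into closed contours without any
tolerance matching; with multiple contours (e.g. near a bifurcation or when
a curved vessel re-enters the plane) the contour containing the slicing
point is selected, falling back to the nearest centroid. Profiles are
sampled every $\Delta s = 1$ mm (the study's reporting interval) from a
defined origin — an explicit point, the crossing of a bounding plane
("box entry", rejected as ambiguous if crossed more than once), or the
closest approach to a second centerline (the anastomosis convention for an
AVF). Samples closer to an end cap than one local vessel radius are dropped
as cap artifacts; because the inscribed radius itself collapses at a cap,
the margin is measured from the radius just inside each end.

The equivalent diameter is $d_\text{eq} = 2\sqrt{A/\pi}$, exactly inverting
the circle area.

## The synthetic phantom family

`phantom_set()` reproduces the five study conditions: straight tubes of
internal diameter 2, 3 and 5 mm aligned with the scanner z-axis, and two
curved "swing-site" tubes of 5 mm diameter. All default to 50 mm path
length. Only the curvature *ordering* of the curved phantoms is known
(curve-H curves more tightly than curve-L), so the generator fixes them as
circular arcs of radius 15 mm and 40 mm: over 50 mm these give peak
flow-direction derivatives $|\Gamma'|$ of $1/15$ and $\sin(1.25)/40$ mm⁻¹,
a ratio of about 2.8, comfortably preserving the ordering. Meshes are
polygon tubes (48 circumferential × 60 axial by default) with fan-capped
ends; vertices lie **on** the nominal radius, so a cross-section is the
inscribed 48-gon whose area sits 0.29 % below $\pi r^2$ — inside every 1 %
tolerance used, and halving at least fourfold per resolution doubling.

Paired "segmentations" perturb the radius field:

$$ r(s) = r_0\,\bigl(1 + b + \textstyle\sum_j f_j(s)\bigr) + \eta(s), $$

with $b$ a signed fractional bias (systematic over/under-estimation),
$f_j$ Gaussian bumps (position, extent, fractional change) modelling local
narrowings/dilations, and $\eta$ a smooth Gaussian process along $s$
(squared-exponential kernel, default 5 mm correlation length) matching the
smooth lofted-spline character of sweeping segmentation output. The study
defaults (`phantom_study_config()`) use $b_B = -5\%$ and 0.05 mm noise on
both sources, which lands the per-phantom mean diameter differences in the
0–15 % of diameter range the phantom experiments exhibit. All generators
are pure functions of (spec, seed); the same seed reproduces byte-identical
STL files.

What the generator does **not** emulate: imaging physics (no k-space, no
flow-related signal loss mechanism — the signal model below injects the
*statistical* dependence only), angle-dependent blurring, through-plane
partial volume, or solver turbulence. Passing tests therefore demonstrate
that the measurement chain is unbiased and correctly calibrated on
geometry it can see, not that any particular scanner behaves this way.

## Flow-direction metrics and the signal model

Along the centerline, $\Gamma = \hat t \cdot \hat B_0$ is the signed cosine
between the local tangent and the main field axis (z by default): 1 for
flow parallel to $B_0$, 0 perpendicular. (The package follows the signed
dot-product definition; an `absolute` option covers centerlines whose
traversal direction is arbitrary.) Its spatial derivative $\Gamma'$ — a
proxy for instantaneous curvature relative to the field — is taken by
second-order central differences on the 1 mm grid.

The synthetic signal model is
$I(s) = 1 + \beta\,\Gamma'(s) + \epsilon$, $\epsilon \sim N(0, \sigma^2)$,
with $\beta < 0$ injecting the signal-loss-with-curvature behaviour of
flow-sensitive sequences. With $\sigma = 0$ the Spearman correlation
between $I$ and $\Gamma'$ is exactly $-1$ (the tie-free closed form
$1 - 6\sum d_i^2 / (n(n^2-1))$ is used, so monotone pairs give exactly
$\pm 1$). `calibrate_signal_noise()` inverts the linear-model correlation
$\rho = \beta\,\mathrm{sd}(\Gamma')/\sqrt{\beta^2\mathrm{var}(\Gamma') + \sigma^2}$
to find the noise level for a target $|\rho|$; the study configuration
targets $-0.85$, the stronger of the two curved-phantom correlations, and
at that level the negative dependence is recovered with $p < 0.05$ in
essentially every replicate (the suite requires ≥ 95 % of 200).
Spearman $p$-values use exact permutation enumeration for $n \le 8$
(untied) and the $t$ approximation otherwise.

Min–max normalization maps intensities to $[0, 1]$; a constant profile maps
to zeros with a warning, and correlations on constant input are reported as
degenerate rather than numeric.

## TAWSS and OSI

For a wall-shear vector series $\tau_w(p, t)$ over one pulse period $T$
starting at $t_0$ (by convention $t_0 = 2T$, the third pulse of a
simulation, past start-up transients — the package treats this as metadata
and never simulates warm-up):

$$ \mathrm{TAWSS} = \frac{1}{T}\int_{t_0}^{t_0+T}\!\|\tau_w\|\,dt, \qquad
   \mathrm{OSI} = \frac{1}{2}\left(1 -
   \frac{\|\int_{t_0}^{t_0+T}\tau_w\,dt\|}
        {\int_{t_0}^{t_0+T}\|\tau_w\|\,dt}\right). $$

OSI is 0 when the shear vector holds one orientation all pulse and 0.5 when
it oscillates symmetrically between opposite orientations (zero
time-integral). The time grid is uniform, includes $t_0$ and excludes
$t_0 + T$, so the trapezoidal rule with periodic closure reduces to
$\Delta t \sum$ — exact for constant fields, second-order for kinked
magnitudes like $|\sin|$, and verified against adaptive quadrature to
$10^{-3}$. All-zero series have no defined OSI and return `NA`; tiny
negative round-off is clamped so OSI always lies in $[0, 0.5]$.

The synthetic waveform is a fixed-direction sinusoid
$\tau(p, t) = (m + a\sin 2\pi(t-t_0)/T)\,\hat d_p$ (plus a rotating-direction
mode); flow reversal occurs when $a > m$. A sinusoid was chosen over a full
Womersley solution because the downstream functionals consume only
$\tau(t)$, and the sinusoid has closed-form integrals for independent
checking.

## Pipe-flow oracles

The analytic backbone tying WSS to area:
$Re = \frac{4}{\pi}\frac{\rho Q}{\mu D}$;
the Darcy–Weisbach wall shear $\tau_w = \frac{f_D}{8}\rho (Q/A)^2$; the
laminar friction factor $f_D = 64/Re$ (flagged laminar below $Re = 2100$,
transitional to 4000, turbulent above; the turbulent friction factor is
caller-supplied, as it is empirical). Substituting $f_D = 64/Re$
reproduces the Poiseuille closed form $\tau_w = 32\mu Q/(\pi D^3)$
identically — the test suite checks this to machine precision across a
parameter sweep. At fixed flow rate this gives exact power laws
$\tau_w \sim A^{-1.5}$ (laminar) and $\tau_w \sim A^{-2}$ (constant $f_D$),
recovered by `wss_area_scaling_exponent()` as log–log regression slopes.
These exponents are why WSS errors exceed area errors: a relative area
difference is amplified 1.5–2× before it reaches the WSS comparison, and
OSI, which depends on direction reversal rather than magnitude, can
disagree maximally even when TAWSS agrees well.

Working fluids default to the study's: water
($\rho = 10^3$ kg m⁻³, $\mu = 10^{-3}$ Pa s) for phantom flow, blood
($\rho = 1.06\times10^3$, $\mu = 3.5\times10^{-3}$) for simulation
post-processing.

## Agreement statistics

Paired profiles are linearly interpolated onto the uniform grid covering
only the overlap of their ranges (fields of view rarely coincide; linear
interpolation is monotone and cannot overshoot an area profile). The error
metric is

$$ E_f = \frac{2}{n}\sum_{i=1}^{n}
   \left|\frac{f_{A,i} - f_{B,i}}{f_{A,i} + f_{B,i}}\right| $$

— zero for identical measurements, bounded by 2, symmetric, and invariant
under common rescaling. Pairs that are both exactly zero contribute
nothing; a zero pairwise sum with unequal values is rejected by index.
Bland–Altman analysis reports per-pair means and differences (first source
minus second, stated in output headers), the bias, the sample SD of
differences, and limits of agreement at $\pm 1.96$ SD (the conventional
multiplier; the source analyses do not state theirs). SD is computed per
slice pair, and labelled as such, since per-phantom aggregation is equally
defensible but not stated.

## Study drivers and reproducibility

`run_phantom_study()` chains generation → centerline → profile → comparison
for the five phantoms and writes the headline table (E_A, E_WSS via the
Darcy–Weisbach chain at the phantom's nominal flow, mean diameter
difference ± SD), Bland–Altman tables and signal correlations;
`run_paired_comparison()` is the patient-style workflow for two meshes plus
optional wall-shear series registered by arclength. Both accept a plain
list or YAML config, derive every random stream from the config seed, and
write CSVs through a `%.17g` formatter so outputs round-trip bit-exactly
and identical configs yield byte-identical reports. The numbered scripts
under `analysis/` run these studies and print what they find.

Problem sizes were chosen to keep each analysis interactive: 50 mm tubes at
48 × 60 mesh resolution (about 5 900 triangles) extract a centerline in a
few seconds; the test suite uses 30–40 mm tubes at 24 × 20 where full
accuracy is not the point. Monte-Carlo checks use 100–1000 replicates.

## Known limitations

- The centerline algorithm assumes a single tubular channel between two
  openings; branching trees are out of scope (only the two-centerline
  closest-approach origin is supported).
- Voxelization parity can misclassify a column that grazes the surface
  tangentially; the irregular grid offset makes this measure-zero in
  practice, and such columns are left outside (conservative).
- The inscribed radius reported near the ends reflects distance to the cap,
  not the vessel caliber; profile code compensates, but consumers of
  `centerline$radius` should trim one radius from each end.
- $E_f$ on OSI pairs where one source has OSI ≈ 0 saturates toward 2 by
  construction; interpret it jointly with TAWSS, as the drivers do.
- The wall thickness of physical phantoms (1–1.6 mm) affects imaging, not
  lumen geometry, and is not modelled: the generator builds lumen surfaces
  only.
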