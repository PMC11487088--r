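---
title: "Models and methods behind tectrepair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tectrepair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tectrepair)
```

This vignette is the package's own account of the science it implements: the
models, their assumptions, the parameters that matter, and the numerical and
design choices made where more than one defensible option existed.

## The biological setting

A stab wound to the optic tectum of a larval zebrafish closes within roughly
a day. Tracked neuronal nuclei — used as passive landmarks of the
periventricular zone (PVZ) tissue — move in straight, directed trajectories
toward the neuropil after injury, in contrast to the small random jitter of
uninjured tissue. Displacement vectors extrapolate to a common origin in the
superficial neuropil, where microglia accumulate; the hypothesis the package
operationalises is that microglia exert elastic traction on astrocytic
processes and thereby contract the tissue over the wound.

## Viscoelastic closure model

Neurons are treated as beads attached to springs in a viscous medium. With
mass normalised to one, displacement obeys

$$x'' + \nu x' + k x = 0,$$

whose underdamped ($k > \nu^2/4$) solution is

$$x(t) = a\,e^{-\nu t/2}\cos\!\big(\sqrt{k - \nu^2/4}\,t - \varphi\big).$$

Because the observed tissue displacement is monotonous, only one half-period
of the cosine is meaningful: over that window the closed form is a smooth,
monotone S-shaped segment, which is exactly the shape of a fluorescence
closure curve. `fit_oscillator()` therefore fits
`offset + x(t - t_1)` directly to intensity curves, with a free baseline and
signed amplitude so rising and falling readouts are both covered (whether a
curve is fitted raw or normalised is immaterial to this parameterisation).

Numerical choices:

* **Parameterisation.** The fit runs over $(a, \log\nu, \log\omega, \varphi,
  \text{offset})$ with $\omega = \sqrt{k - \nu^2/4}$, so the underdamped
  constraint holds by construction and $k = \omega^2 + \nu^2/4$ is derived.
* **Multi-start.** The cosine phase creates local minima; the optimiser
  (Levenberg–Marquardt, `minpack.lm`, cost tolerance 1e-12) is started from a
  12-point phase grid crossed with both amplitude signs, and the best
  converged start wins.
* **Degeneracy.** $(a, \varphi)$ and $(-a, \varphi \pm \pi)$ generate the
  same trajectory; fits are canonicalised to $\varphi \in (-\pi/2, \pi/2]$.
* **Half-period guard.** A fitted window longer than $\pi/\omega$ violates
  the monotone-segment assumption and triggers a warning rather than an
  error, since early exploratory fits legitimately probe it.

At 1%-of-amplitude Gaussian noise, recovery bias of $(a, \nu, k)$ over 100
seeded replicates is well under 5% (the damping rate is the least
identifiable of the three over a single half-period, because a slightly
larger amplitude can compensate a slightly faster decay).

## Trajectory statistics

**MSD.** Per track, the squared 2D displacement is averaged over all
overlapping frame pairs at each lag; lags run up to half the track span
(default `max_lag_fraction = 0.5` — longer lags average too few pairs), and
tracks are then averaged without weighting. This is the convention of the
DiPer tracking workflow. The anomalous exponent $\alpha$ is the OLS slope of
log MSD against log lag, with the 2D prefactor convention
$\mathrm{MSD} = 4 D \tau^\alpha$. Ballistic motion gives $\alpha = 2$
exactly; calibrated random walks recover $\alpha \approx 1$ and $D$ within
10%. The fit window is exposed because in vivo the superdiffusive phase is an
early, data-dependent window.

**Straightness** is net displacement over path length (the standard tracking
definition; a zero-length path is assigned straightness 0), and z statistics
refuse 2D tracks rather than returning 0 — a silent zero would read as a
real measurement.

**Linearisation.** Track starts are projected perpendicularly onto the
rostrocaudal polyline; the net displacement is decomposed onto the local
tangent/normal frame (normal = tangent rotated +90° counter-clockwise), so
anisotropy along versus across the curved PVZ can be compared across animals.

**Convergence.** Every displacement vector is extrapolated as a forward ray;
all ray pairs are intersected, and intersections are kept if they lie forward
along both rays, inside the tectum outline, and come from rays separated by
at least 10° (near-parallel pairs produce numerically explosive intersection
points; the threshold is exposed). The centroid of kept intersections
estimates the contraction origin and is also reported in normalised polar
coordinates: the angle from a user-supplied rostral axis and the radius
normalised by the origin-to-outline distance along the same direction. The
polar origin defaults to the outline centroid because the reference frame
used for in vivo normalisation is not part of the data. With 20 tracks and
1 µm localisation noise the planted centre is recovered with a mean error
around 2 µm, but the estimator is heavy-tailed — a handful of
near-threshold-angle pairs can displace a seed's centroid by several
micrometres — which is why the package reports all intersections rather than
only the centroid.

**Discrete Fréchet distance.** The Eiter–Mannila dynamic programme over
monotone couplings. The null model for microglia-versus-neuron comparisons
randomises the neuron track by resampling step magnitudes with replacement
and drawing directions uniformly: scale is preserved, directional correlation
— the property under test — is destroyed. The empirical p-value uses the
add-one correction $(1 + \#\{d_\text{null} \le d_\text{obs}\})/(n+1)$. The
exact randomisation behind the original comparison is unstated; this choice
is flagged as an assumption.

## Wound morphometry

Injury volume is the sum of per-plane shoelace areas times the plane spacing,
with no inter-plane interpolation — mirroring the plane-after-plane manual
outlining workflow. Against analytic solids the discretisation error is below
3% for sphere-like wounds at 1–2 µm spacing. The repair index
$\mathrm{RI} = 1 - V_\text{late}/V_\text{early}$ is exact arithmetic; values
above 0.5 classify a wound as closed and negative values as enlarged.

Ablation mask series are compared frame to frame on identical pixel grids
(registration is out of scope): gained, lost, total remodelled
(gained + lost) and net (gained − lost) areas are all reported because
published overlays are ambiguous about which is plotted; pixel counts stay
integral until one final scaling so that gained − lost equals the raw area
difference bit-exactly. Packing density uses a Gaussian blur (default
σ = 1 µm) followed by Otsu's global threshold, the standard reading of
"thresholded" when no method is named.

## The multi-agent tissue model

Three agent kinds move in 2D by an overdamped force balance
$V_i = \frac{1}{\eta}\big[\sum_j (F^{adh}_{ij} + F^{rep}_{ij} +
F^{trac}_{ij}) + F^{loc}_i\big]$, integrated by forward Euler:

* **Repulsion** $\sqrt{c^{rep}_i c^{rep}_j}\,(1 - d/R)^2$ inside the contact
  range $R = r_i + r_j$; **adhesion** $\sqrt{c^{adh}_i c^{adh}_j}\,
  (1 - d/R_A)^2$ inside $R_A = 1.25\,R$ — the polynomial potentials of
  PhysiCell-style centre-based models. Geometric-mean amplitude combination
  keeps every pair force antisymmetric (momentum exchange), which the tests
  verify as a pinned centroid for closed agent sets.
* **Elastic traction** $k_e (r_j - r_i)$, attractive, for every pair
  containing at least one microglia. The source model's prose (microglia pull
  on all other agents) takes precedence over its printed pair condition, and
  the attractive sign is required for contraction. Two bodies coupled only
  elastically separate as $r_0 e^{-2 k_e t/\eta}$, the closed-form oracle the
  integrator is tested against (forward Euler needs
  $dt \lesssim 0.01/k_e$; at $dt = 0.002$, $k_e = 0.01$ the relative error at
  $t = 100$ is $4\times10^{-5}$).
* **Locomotion**: speed times a persistent random direction, resampled
  uniformly when the persistence timer expires. No chemotaxis is modelled —
  microglial aggregation has to emerge from the elastic term, and does.
* **Skin agents** are immobile anchors ringing the tectum outline,
  representing skin stiffness in the force balance.

Published per-kind parameters (neuron/microglia/skin): persistence time
10/10/0 min, migration speed 0.01/1/0 µm/min, relative repulsion 5/5/5,
relative adhesion 0.1/0/0, elastic coefficient 5×10⁻⁷ min⁻¹. The effective
viscosity η is fixed at 1 so the relative amplitudes act directly as
velocity scales. Unpublished quantities — agent radii (3/5/5 µm), adhesion
reach (1.25), wound radius (15 µm), microglia counts — are exposed
configuration with these defaults.

**Elastic gain calibration.** The published elastic amplitude is a relative
coefficient of the source framework; inside this package's velocity scale,
$k_e = 5\times10^{-7}$ produces displacements of order 0.1 µm per day —
numerically negligible, which is also why the elastic term defaults to
unlimited range. Closure runs therefore apply a dimensionless
`elastic_gain` to $k_e$, calibrated once against the qualitative published
behaviour (no closure without microglia; linear rise then plateau with
count): gain 10 is non-monotone at high counts because global contraction
drags the band past the fixed wound ROI, gain 50 saturates by a handful of
microglia, and gain 25 — the frozen default — yields the full
zero/partial/plateau progression over counts {0, 4, 8, 16, 32}.

**Readouts.** The closure curve is the normalised Gaussian-rendered neuron
density inside the wound disc over time — the in silico analogue of the ROI
fluorescence measurement — recorded every 15 simulated minutes over 1440 min
(dt = 0.1 min). The repair analogue is $1 - \text{empty}_\text{end}/
\text{empty}_\text{start}$, where a wound grid point is empty while its
neuron density is below half the median PVZ density at the same time point.
Emptiness is scored on the wound disc eroded by one neuron radius: rim points
sit under the Gaussian shoulder of intact rim cells, and without the erosion
sub-cell-size adhesive compaction alone flips a few percent of them —
a partial-volume artifact of the measure, not tissue repair.

The default run packs ~340 neurons hexagonally into the PVZ band of a
120 × 80 µm half-ellipse tectum, clears a 15 µm injury disc, spreads
microglia uniformly in the neuropil and rings ~40 skin agents outside the
outline; one 1440-min run integrates in a few seconds (compiled core with a
uniform-grid neighbour search; a reference R stepper implements the identical
physics for the force-law tests). One RNG stream keyed by the seed drives
initialisation and motility, so identical configurations produce
byte-identical results. The five-count, three-replicate sweep completes in
about half a minute.

## Synthetic data: what it does and does not emulate

The generators reproduce the *structure* of the study's data so every
analysis stage has ground truth: directed superdiffusive tracks converging
on a point (built from the same oscillator displacement law as the kinetics
module, so model and data share one formula), small-step jitter tracks for
the uninjured contrast, Gaussian-blob movies with conserved per-blob
intensity, elliptical wound outline stacks whose summed-plane volume matches
a requested value, and ablation masks with recoil/static/drift signatures.
Measurement noise is additive Gaussian on positions (per-localisation
tracking error, default 0.05 µm), not on steps. The uninjured jitter
magnitude is a free parameter (default step σ = 0.3 µm per 15-min frame)
because only "minimal movement" is reported.

None of this is photorealistic microscopy: there is no PSF, no shot noise,
no background, no segmentation error, and the analytic half-ellipse geometry
is not a traced tissue outline. Passing tests therefore demonstrate
correctness of the estimators on data with known structure, not robustness
to real imaging artifacts.

## Degenerate inputs and tie-breaks

Readers reject malformed rows naming the offending track/column/plane;
z statistics error on 2D tracks; normalisation refuses zero-range curves;
the convergence estimator returns an undefined-flagged result (not an error)
when no valid intersection exists; coincident agents repel in a seeded
random direction; closure time interpolates linearly and flags curves that
never reach threshold. Write→read round trips are lossless to well below
1e-9 relative (coordinates are serialised at 17 significant digits).

## Known limitations

* The simulator is 2D, ignores the microenvironment, cell cycle and volume
  changes, and its elastic gain is calibrated, not measured; quantitative
  agreement with any specific published dose–response axis is not claimed.
* The in vivo headline numbers (superdiffusive exponent 1.86, convergence at
  radial 0.6/37°, microglial centre at 0.88/17°, closure at 18–22 hpi) derive
  from undeposited imaging data and are not reproducible here; the package
  demonstrates the corresponding estimators on synthetic data with known
  ground truth instead.
* The Fréchet null model and the MTrackJ export schema are documented
  assumptions; both are isolated behind single functions.
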