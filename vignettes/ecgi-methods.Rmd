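---
title: "Methods: inverse electrocardiographic imaging and segment-level dispersion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inverse ECGi and dispersion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Electrocardiographic imaging (ECGi) reconstructs potentials on the heart
surface from a dense array of body-surface electrodes plus heart and torso
geometry. From the reconstructed unipolar electrograms (EGMs) one extracts,
per heart-surface node, a local activation time (LAT: the instant of the
steepest negative dV/dt, referenced to QRS onset on the limb leads) and a
peak-to-peak voltage. Aggregated into the standardized AHA 17-segment model
of the left ventricle, the within-segment standard deviations of LAT and
voltage — *activation dispersion* and *voltage dispersion* — are markers of
an arrhythmogenic substrate: hypertrophic cardiomyopathy shows larger basal
activation dispersion, higher unipolar voltage and wider voltage dispersion
than either healthy hearts or post-infarction ventricles.

`ecgimap` implements this entire analysis as a reusable pipeline, and — in
the absence of public patient recordings — a synthetic-data module that
generates biventricular geometry, a 128-electrode torso, sinus-rhythm
activation, and four-group cohorts with the dispersion/voltage structure the
analysis targets, so the pipeline is testable end to end.

# Forward model

The torso is a homogeneous, isotropic volume conductor, bounded externally
by the closed torso surface (no current crosses the skin) and internally by
the closed combined heart surface (epicardium, LV endocardium, RV
endocardium, joined at a basal cap whose two openings are the cavity
mouths). Potentials are prescribed on the heart surface; the forward
problem is the exterior mixed boundary-value problem for Laplace's
equation.

Discretization is a vertex-collocation boundary-element method:

* The double layer uses analytic plane-triangle solid angles (the
  van Oosterom–Strackee formula), lumped equally onto the three vertices of
  each face. The diagonal (interior solid angle at each collocation point)
  is *not* assumed smooth; it is computed from the closure sum rule, which
  makes a spatially constant heart potential transfer to the electrodes
  exactly — the discrete analogue of a physical invariant of a homogeneous
  conductor. We verify `max |T·1 − 1| < 1e-3` (observed: ~1e-12).
* The single layer (the unknown normal current on the heart surface) uses a
  closed-form polar integration when the observation point is a vertex of
  the integrated triangle, and degree-5 Gauss quadrature with recursive
  4-way subdivision in the near field elsewhere.
* Meshes are re-oriented automatically (edge flood fill for consistency,
  signed-volume sign fix) before assembly, so input winding conventions do
  not matter.

Eliminating the heart-surface current yields the dense transfer matrix from
heart-node potentials to all torso-node potentials; rows are restricted to
the 128 electrode vertices (plus four limb-lead surrogate rows). Because
the heart potential is prescribed, the mixed system is full rank — the
additive-constant ambiguity of pure-Neumann formulations does not arise —
so the rank-one deflation term (fixing the mean torso potential) is kept
only as an automatic stabilizer for near-singular assemblies.

The oracle for all of this is the concentric-sphere shell: a degree-l
zonal harmonic prescribed on the inner sphere of an insulated shell appears
on the outer sphere attenuated by the closed-form ratio implemented in
`analytic_sphere_transfer()`. On icospheres at subdivision 3 the BEM
reproduces l = 1..3 within 1.2 % relative L2 error (bound: 5 %), and the
error decreases under refinement.

# Inverse solution

`tikhonov_solve()` implements zero-order Tikhonov with identity weighting,

$$\hat x_\lambda = \arg\min_x \; \|Tx - y\|_2^2 + \lambda^2\|x\|_2^2,$$

computed from the SVD of `T` via filter factors and applied column-wise
over time. One global lambda per beat is the default (stabilizes LAT
extraction); per-frame selection is available. `select_lambda()` offers the
L-curve (maximum curvature of the log residual / log solution-norm curve,
with curvature from analytic first derivatives on a fixed 64-point
logarithmic grid spanning `[1e-6, 1]·sigma_max`) and CRESO (first local
maximum of the derivative of `lambda^2 ||x_lambda||^2` with respect to
`lambda^2`, with a sign-change fallback). The L-curve is the default: in
our experiments it tracks the noise level monotonically, whereas the CRESO
criterion is erratic on smoothly decaying singular spectra.

# Feature extraction and quality control

Derivatives are central differences after a moving-average smoother. The
smoother width is expressed in milliseconds (5 ms for directly synthesized
traces; 8 ms inside `compute_maps()`, because regularized reconstructions
carry amplified measurement noise). QRS onset is detected per limb lead as
the first sustained crossing of a smoothed derivative envelope above
baseline-median + 4 MAD over a 50 ms baseline; leads without a detectable
depolarization (near-isoelectric axis) are dropped from the average.
Downslope search is restricted to the annotated beat window.

The reviewer-based quality control of reconstructed EGMs is replaced by a
deterministic neighbour-agreement rule evaluated on every mesh edge:
morphology agreement is the maximum normalized cross-correlation within a
±40 ms lag (threshold 0.8); timing agreement is a downslope difference
below 10 ms. Nodes are excluded when the majority of their edges disagree
in morphology; morphology-agreeing but timing-disagreeing nodes have their
downslope recomputed inside a ±25 ms window around the bipolar-EGM
extremum, and the recomputed value is kept only when it moves the node
toward its neighbourhood median LAT. In practice this QC almost never
touches epicardial nodes and masks most cavity (endocardial) nodes — see
*Limitations*.

# Segment statistics and group comparison

`assign_aha_segments()` bins nodes by the normalized long-axis coordinate
(equal basal/mid/apical thirds, apical cap = most apical 5 %, configurable)
and equal angular sectors anchored at the septal direction
(counter-clockwise viewed from the base). The five septal segments (basal
and mid anteroseptal and inferoseptal, apical septal) take their
"epicardial" surface from the RV endocardium
(`apply_rv_septal_substitution()`), since the septum has no epicardium.

Per (segment, surface) cell we report the arithmetic mean and *sample*
standard deviation (n−1 denominator; the inferential use is group-wise) of
LAT and peak-to-peak voltage over valid nodes, requiring at least 3 valid
nodes per cell. Group comparison follows the published analysis: the
heteroscedastic Wald chi-squared test with James's first-order critical
value for mean voltage (from per-group summary statistics), and the
Kruskal–Wallis test for the (non-normal) dispersion measures, both
unadjusted at alpha 0.05 (a Benjamini–Hochberg option exists but is off by
default). Welch's heteroscedastic ANOVA is bundled as a cross-check; on the
published per-segment summaries the two agree within 0.005.

James's critical value solves
$J = c_p\,[1 + (3c_p + k + 1)\Lambda/(2(k^2-1))]$ — a quadratic in
$c_p$ whose positive root is pushed through the chi-squared survival
function. Its type-I error at k = 4, n = 10 under 16-fold variance ratios
measures ~0.05–0.075 over 2,000 simulations, the known slight
anti-conservativeness of the first-order approximation at these sample
sizes.

A note on reproducing the published per-segment p-values from the bundled
summary table: the two anchor rows (basal anterior, both surfaces)
reproduce within ±0.01, and the median absolute difference across all 33
rows is ~0.007. A handful of reported values, however, are inconsistent
with *any* standard k-sample test of the printed means and SDs (James,
Welch, Brown–Forsythe, fixed-effects F all give ~0.02 where 0.204 is
reported for one endocardial row); the strict batch-agreement check is
therefore expected to fail on those rows, and we treat them as errata in
the source table rather than calibration targets.

# The synthetic-data generator

The generator defines the study conditions; its defaults are fixed, not
tuning knobs.

* **Heart**: truncated-ellipsoid epicardial cup (radius 40 mm, apex depth
  90 mm), LV endocardial cup offset 6 mm away from the septum
  (10 mm wall), and a crescent-section RV endocardial shell on the septal
  side, joined by a planar basal cap with two cavity mouths; closed,
  orientable, ~3.6 mm resolution at the 4,000-node default (matching
  clinical segmentations of ~3,992 ± 735 nodes). A ±2 % seeded global scale
  emulates between-subject size variation.
* **Torso**: rounded elliptic cylinder (half-axes 140 × 110 mm), with the
  heart placed anterior-left of the midline as in situ — electrode-to-
  epicardium distances of a few centimetres are what make the inverse
  problem tractable at all. 128 electrodes in 4 panels (anterior,
  posterior, left, right) of 4 strips × 8 rows wrap most of the chest
  circumference; four limb-lead surrogates sit at the shoulder/hip
  extremes.
* **Activation**: geodesic wavefront over the mesh edge graph (edge time =
  length / harmonic-mean conduction velocity of its endpoints) from septal
  endocardial pacing sites, with transmural links (nearest epicardial
  neighbour within 18 mm at 0.6 mm/ms) so activation breaks through from
  endocardium to epicardium as in sinus rhythm.
* **Electrograms**: each node receives a unit-normalized template — a
  sigmoidal downstroke (6 ms width parameter) with a small positive
  pre-wave — shifted to its LAT and scaled to its amplitude; by
  construction the steepest downslope sits on the activation instant and
  peak-to-peak equals the nominal amplitude. Recordings default to
  2,048 Hz (all time quantities are in ms, so the rate is a convenience,
  not an algorithmic constant); white Gaussian noise is added at a stated
  SNR over the QRS window (30 dB default).
* **Cohorts**: four presets. Healthy: fast homogeneous conduction, low
  amplitude spread. Post-MI (VT-free / VT): globally slowed conduction
  plus a slow-conducting scar patch (anteroseptal, or mixed anteroseptal /
  inferoposterior for the VT preset). HCM: a slow-conducting basal band
  plus elevated, widely dispersed amplitudes. Amplitude means and
  between-subject spreads follow the published epicardial basal-anterior
  summaries (842 ± 90, 898 ± 358, 934 ± 189, 1094 ± 211 uV); within-subject
  spreads follow the corresponding voltage-dispersion medians (110, 158,
  189, 215 uV). Conduction heterogeneity is a *smooth* lognormal random
  field (22 mm correlation length): point-to-point velocity noise at mesh
  resolution would be unphysical and unrecoverable by any imaging method.

What the generator does **not** emulate: biophysical action-potential
dynamics, repolarization, anisotropy, torso inhomogeneities (lungs, blood
pools as distinct conductivities), respiratory motion, electrode
localization error, or geometry mismatch between the true and assumed
transfer matrix. Passing tests therefore demonstrate the internal
consistency and statistical behaviour of the pipeline under an exact
forward model, not clinical-grade accuracy.

# Numerical choices and degenerate inputs

* Tie-breaks: steepest-downslope ties (within float jitter) resolve to the
  earliest sample; sector boundaries round angles to 1e-6 degrees so
  segment ids survive rigid-body transforms bit-exactly.
* Degenerate inputs: constant traces raise a no-downslope error; flat
  noise-only limb leads raise an onset-not-found error; λ = 0 with a
  rank-deficient transfer matrix directs the user to λ > 0; open meshes and
  hearts touching the torso are rejected before assembly.
* The exact Kruskal–Wallis permutation p enumerates all multinomial label
  assignments and is limited to pooled n ≤ 10.

# Problem sizes used by the tests and the acceptance script

Test fixtures use a 1,000-node heart (and icospheres at subdivisions 2–3);
the acceptance script rebuilds everything at the 1,500-node reduced
resolution with 128 electrodes, runs one subject per group for recovery
metrics, 2,000 null simulations for the James type-I rate, and 8 replicate
4 × 10-subject cohorts for the group-structure checks. These sizes were
chosen as the smallest at which the geometric and statistical behaviour is
stable.

# Known limitations

* **Cavity surfaces are weakly observable.** With 128 electrodes and a
  homogeneous torso, reconstructions on the LV/RV endocardium — surfaces
  enclosed a centimetre or more inside the epicardium — are dominated by
  the epicardial neighbourhood signal; the neighbour QC masks most of them.
  Consequently the five septal "epicardial" segments (RV-endocardial
  surrogates) often carry too few valid nodes, and per-segment dispersion
  rank-order between truth and recovery is preserved for ~10–13 of 17
  epicardial segments rather than all of them. Larger regularization and
  wider RV cavities were evaluated and degrade overall recovery; this is a
  physical resolution limit of the formulation, not an implementation
  artefact. Epicardial free-wall recovery is strong (Spearman ~0.85–0.92 at
  30 dB with the exact transfer matrix).
* Group-level results are qualitative reproductions (ordering, power), not
  numeric matches to patient data: absolute reconstructed-EGM amplitudes
  depend on the solver's scaling conventions, and the published per-node
  data were never deposited.
* The basal cap is an idealization of the combined valve orifice; clinical
  segmentations differ in how the base is closed.
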