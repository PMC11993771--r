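---
title: "Methods: virtual osteotomy planning, transformation measurement and noninferiority analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual osteotomy planning, transformation measurement and noninferiority analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

radioplan implements the computational core of a paired accuracy study of
patient-specific surgical guides for corrective osteotomy of extra-articular
distal radius malunions. Two planning arms (an in-house hospital team and an
external provider) each plan the same correction; the achieved correction is
compared to the plan on bone models, and the in-house arm is tested for
*noninferiority* against the external arm. The pipeline starts from triangle
surface meshes (STL) and comprises:

1. **Planning** — mirror the healthy contralateral radius, cut the malunited
   bone at the osteotomy plane, and rigidly align the distal fragment onto
   the mirrored reference (`plan_correction()`); drill trajectories defined
   on the corrected bone are carried back to the deformed bone with the
   inverse correction (`back_transform_drills()`).
2. **Measurement** — align the post-surgery bone to the planned model
   proximally, express everything in a landmark-defined anatomical frame,
   align distally, and decompose the residual transform into six clinical
   parameters (`measure_errors()`).
3. **Statistics** — paired absolute-error noninferiority confidence
   intervals, Mann-Whitney U, Shapiro-Wilk and an approximate post-hoc power
   (`paired_noninferiority()`, `mann_whitney_u()`, `shapiro_wilk()`,
   `posthoc_power_mw()`).
4. **Guide QC** — average distance error (ADE) between designed and scanned
   guides, before and after sterilisation (`ade()`,
   `sterilisation_report()`).
5. **Synthetic anatomy** — a parametric radius surrogate with exact ground
   truth that exercises the entire pipeline end to end
   (`generate_radius()`, `induce_malunion()`, `simulate_surgery()`,
   `generate_study()`).

All lengths are millimetres; angles are degrees at API boundaries and
radians internally.

## The anatomical frame

The frame (`build_frame()`) is constructed from two manually identified
landmarks and the shaft axis:

* **Origin** — the Central Reference Point (CRP), the centre of the rim
  between the lunate fossa and the sigmoid notch.
* **z axis** — parallel to the central shaft axis, pointing distally.
  `central_axis()` fits a least-squares 3D line through cross-section
  centroids of the segment 30-50 mm proximal to the CRP. The manual
  construction this replaces intersects two hand-placed planes in
  anteroposterior and lateral views; the intersection of two fitted planes
  is exactly a fitted 3D line, so the automated fit is the deterministic
  limit of the manual procedure. Centroids use overlapping Gaussian windows
  (SD = 1 mm sampling step): hard slab bins can split a tessellation ring
  between neighbouring bins and bias individual centroids, while the smooth
  windows make the fit tessellation-independent (verified to < 0.2 degrees
  between coarse and refined meshes). The fit is iterated with its own
  result as the provisional axis (at most 8 passes, terminating at
  0.01 degrees change).
* **x axis** — from the origin towards the projection of the radial styloid
  tip onto the plane normal to z; rejected if the projection is closer than
  5 mm (an ill-conditioned frame).
* **y axis** — perpendicular to the xz plane. With a volar reference point
  it is flipped if necessary so y points volarly; a mirrored (left)
  anatomy then yields a mirrored, left-handed frame, which is intended:
  volar tilt keeps its clinical sign on both sides. Without a volar
  reference, the side annotation decides.

Sign conventions: volar rotation about x is positive, and lengthening along
z is positive. Because the ulna is unchanged in this model, the radial
length error measured at the frame origin (sigmoid notch rim) equals the
ulnar variance error.

## Transformation measurement

`measure_errors()` is the package's core measurement:

1. ICP-align the result's proximal region to the planned model's proximal
   part, in **two passes**: register, re-mark the plane-based regions on
   the aligned result, and register again. Region membership depends on the
   alignment, so a one-pass selection is only trustworthy when the initial
   pose is already good.
2. Build the frame on the planned model and map both models with
   `world_alignment()` so the origin is (0,0,0) and the axes coincide with
   the world basis (an improper map for left-handed frames).
3. ICP-align the result's distal part to the planned distal part.
4. Report the displacement of the achieved fragment relative to the plan —
   the inverse of the step-3 alignment, already expressed in frame
   coordinates — decomposed into the six parameters.

**Rotation sequence.** Radiological rotation sequences differ between
tools; the package fixes the extrinsic x-y-z Cardan factorisation
`R = Rz(g) Ry(b) Rx(a)`. Volar tilt (x) is the primary endpoint and this
order reads it directly; `compose_clinical()` and `decompose_transform()`
are exact inverses (round trip < 1e-9 over the full clinical range), and a
gimbal guard rejects |b| >= 60 degrees, far beyond any clinical correction
error. This is a recorded dialect: a different sequence would decompose the
same transform into slightly different numbers, which is why published
tables from other tools cannot be regenerated without knowing their
sequence.

**Region margins.** A 2 mm dead zone around the osteotomy plane excludes
the geometrically unreliable junction. On the proximal side the dead zone
is widened by a further 4 mm: the achieved fragment can dip below the
plane by its residual error, and those vertices are *continuous* with the
shaft surface, so no distance threshold can reject them — only geometry
can.

**ICP settings.** `measurement_icp_params()` uses untrimmed ICP with
convergence tolerance 1e-6 mm (change in mean residual), 1200 sample
points, at most 400 iterations. Two deliberate choices:

* *No trimming in the measurement stages.* An automatic threshold (mean +
  2 SD) can lock in a slid pose along the shaft: at such an equilibrium the
  threshold discards exactly the feature points that would correct the
  slide. The margins above already remove the only genuine outliers.
* *Tight tolerance.* ICP converges linearly, and a residual-change
  criterion of 1e-4 mm can stop with the transform still ~0.05 mm / 0.05
  degrees from the optimum — acceptable for residual reporting, not for
  parameter recovery at the 0.2 degrees / 0.1 mm level the acceptance
  property demands. The looser `icp_params()` defaults (1e-4 mm, trimmed)
  remain appropriate for guide QC, where the "automatic distance
  threshold" emulates the commercial software and sub-0.001 mm transform
  accuracy is irrelevant.

## Guide quality control

`ade()` registers the scanned guide (mesh or scanner point cloud) onto the
reference design with trimmed ICP (auto threshold: mean + 2 SD of current
correspondence distances, recomputed per iteration — the commercial
formula is unpublished; this is the recorded dialect) and reports the mean
unsigned point-to-surface distance over all masked sample points, with
trimmed points re-included in the summary (a second dialect: whether the
commercial ADE excludes trimmed points is unstated). Masks — face-index
lists or a plane-plus-side region — stand in for the manual marking of the
outer contact surfaces; internal drill-bore metrology is out of scope
because optical scanners only see outer surfaces.
`sterilisation_report()` produces one ADE row per available comparison and
degrades to pre-vs-post only when the virtual design is unavailable, as for
externally produced guides.

## Statistics

With paired errors per patient and arm, the endpoint is
`d_i = |error_EC,i| - |error_SUH,i|` (external minus in-house, absolute
values — both error signs are equally undesirable). The two-sided 95%
interval is the t-interval with n-1 degrees of freedom
(`mean(d) +/- t_{n-1,0.975} sd(d)/sqrt(n)`); the source analysis states
only "95% CI", and at n = 16 the t-interval is the standard small-sample
choice. Noninferiority of the in-house arm is claimed when the lower limit
exceeds -margin (5 degrees volar tilt; 2 mm ulnar variance). The two
endpoints are tested separately without multiplicity adjustment, matching
the source analysis.

`mann_whitney_u()` computes U from rank sums with midranks; exact p by full
enumeration of labelings (feasible to n = 14 pooled), otherwise a normal
approximation with tie and continuity corrections. `shapiro_wilk()` wraps
the Royston (AS R94) reference implementation behind the package's
contract (3 <= n <= 5000, constant input rejected).
`posthoc_power_mw()` is an explicit approximation: two-sample t power at
Cohen's d from the pooled SD with sample sizes deflated by the 3/pi
asymptotic relative efficiency of the rank test under normal parents.
Desktop power tools implement their own variants; the package's value is
validated against a Monte-Carlo rank-test power simulation (within 0.10),
not against any published number.

## The synthetic world

`generate_radius()` sweeps elliptical cross-sections along a bowed
centreline: an 8 x 6 mm shaft flaring to 14 x 10 mm at the articular rim
over the distal 20 mm, an 8 mm styloid prominence on the radial side, a
3 mm lateral bow, a 15% proximal taper and a 5% axial thickness modulation
at 40 mm wavelength. The taper and modulation exist because a swept
surface without them is nearly an extrusion, leaving axial position almost
unobservable to surface registration — a degeneracy real bones do not
have. Both are symmetric about the centreline, so the stored ground truth
(landmarks at exact analytic positions; the axis as the line fit of the
analytic centreline over the 30-50 mm segment) remains exact, and
landmarks are independent of tessellation density by construction.

`induce_malunion()` cuts at a transverse plane 20 mm proximal to the CRP
(default) and moves the distal fragment by rotations about the frame axes
at the cut centroid plus shortening along -z, leaving an open step at the
junction. Default severity ranges are clinically plausible for dorsally
angulated malunions — dorsal tilt 10-30 degrees, inclination loss 0-10
degrees, shortening 2-8 mm, axial rotation within 8 degrees — and are
configuration-exposed, not asserted (the source cohort's per-case severity
is unpublished).

`simulate_surgery()` perturbs the planned correction by residual errors
sampled independently per parameter as centred normals in frame
coordinates. The per-arm scales derive from the published per-arm mean
absolute errors via the folded-normal relation `sigma = mean_abs /
sqrt(2/pi)` (`default_arm_specs()`); independence across parameters is a
simplification — the source reports no error covariance. Scan noise
displaces vertices along normals with SD 0.05 mm, the scanner's stated
single-shot error; `simulate_scan_points()` additionally emulates the
scanner's native output (resampled surface points, each carrying the full
noise).

In `generate_case()` the mirrored healthy contralateral equals the healthy
bone exactly (the surrogate patient is symmetric); the fragment alignment
is initialised from the three landmarks jittered by 1 mm, emulating the
planner's rough interactive positioning, and refined by trimmed ICP.

**What a green test establishes — and what it does not.** The synthetic
world validates the measurement chain (geometry in, parameters out, exact
truth), the decision logic, and the statistical calibration. It does not
validate segmentation quality, landmark identification on real anatomy,
implant-driven planning compromises (plate fit, offsets), or printing and
sterilisation physics; the surrogate's deviations from real bone (no
cortical detail, symmetric contralateral, independent error components)
mean quantitative agreement with any clinical cohort is out of reach by
design.

**Statistical calibration at scale** (type-I error, 500-study
noninferiority rates) runs at the *error level* via
`simulate_study_errors()`, sampling the injected errors directly rather
than running 8000 mesh registrations: the end-to-end acceptance property
shows the geometric pipeline reproduces injected errors to well under a
tenth of the noninferiority margins, so the error-level simulation is the
same experiment at a vastly smaller cost.

## Numerical choices and degenerate inputs

* STL vertex welding is by exact coordinate match (STL repeats vertices per
  facet); no tolerance parameter. Binary STL stores float32; round trips
  preserve geometry to float precision.
* `cut_with_plane()` clips triangles exactly at the plane
  (Sutherland-Hodgman per triangle), conserves total area to 1e-6
  relative, drops zero-area slivers, leaves open boundaries, and warns if
  the plane misses the mesh (returning one empty part).
* `kabsch()` rejects collinear configurations (second singular value below
  1e-9 of the first); ICP raises a trimming-collapse error below 3
  retained correspondences; `restrict_to_region()` errors on empty
  selections, with the failing stage named in `measure_errors()`.
* Closest-point queries are exact point-to-triangle (compiled), with a
  centroid-radius lower-bound rejection test; correspondences are
  meaningful between unrelated tessellations.
* Mirroring is handled as a flagged improper transform; meshes mirrored
  with `mirror_mesh()` have their winding re-flipped so outward normals
  survive, and mirroring twice is the identity.

## Known limitations

* The ICP has no global initialisation; a grossly wrong initial pose can
  converge to a wrong basin. The clinical workflow (and the generator)
  always supplies a rough pose.
* The commercial software's rotation sequence, ADE formula and automatic
  threshold are unpublished; the package's recorded dialects are
  internally consistent but need not match those tools numerically.
* The post-hoc power approximation is not a reimplementation of any
  specific desktop tool.
* Residual errors are sampled independently per parameter; correlated
  error structures (e.g. tilt-shortening coupling through plate seating)
  are not modelled.
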