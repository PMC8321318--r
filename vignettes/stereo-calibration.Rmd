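---
title: "Geometry calibration of stereo cone-beam X-ray CT: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry calibration of stereo cone-beam X-ray CT: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereocal)
```

## The problem

A stereo cone-beam CT system views a sample on a rotation stage with two
independent X-ray source/detector pairs. In modular setups every component
— sources on gantries, detectors on trolleys, the stage on a tripod — is
repositioned between experiments, so the acquisition geometry is only
coarsely known: the source-to-axis (SOD) and source-to-detector (SDD)
distances are measured by hand, the stereo angle between the two optical
axes is nominal, and detector orientations are set by eye. Reconstructing
with such a geometry produces blurred, doubled structures; combining the
two systems into one reconstruction (for dual energy, faster scans, or
filling a missing wedge) additionally requires the stereo angle to be
known accurately.

`stereocal` estimates the full stereo geometry from radiographs of a
marker phantom: a stack of interlocking toy bricks carrying small steel
beads. Bricks are molded to micrometre tolerances, so bead positions are
*computed* from the lattice dimensions instead of being measured with a
coordinate-measuring machine.

## Geometry model and conventions

The world frame has its origin at the rotation center, $+x$ along pair 1's
nominal optical axis (source $\to$ detector), $+y$ along the rotation axis
(up), and $+z$ completing a right-handed frame. Where a convention is not
dictated by the physics it is fixed here by fiat and used consistently:

* **Euler order.** Orientation triples (roll $\theta$ about $x$, yaw
  $\phi$ about $y$, pitch $\eta$ about $z$) compose as
  $R = R_z(\eta)\,R_y(\phi)\,R_x(\theta)$. All interface angles are in
  degrees; radians appear only internally.
* **Stage rotation.** Positive stage angles rotate the sample
  counter-clockwise about $+y$ viewed from above. A marker at local
  position $p$ sits at $R_{axis}(a)\,(R_o\,p + t_o)$ in the world: the
  phantom pose (orientation then translation) is applied first, so the
  phantom's translation offsets are room-frame quantities that ride on the
  stage.
* **Detector frame.** Detector coordinates $(u, v)$ are in mm with origin
  at the panel center, $u$ horizontal ($+z$ for an aligned pair 1), $v$
  vertical ($+y$). Pixel indices are 0-based, column 0 left, row 0 top;
  the center of pixel $(0,0)$ lies at $(-(n_u-1)/2, +(n_v-1)/2)$ pixel
  pitches. Detector translation offsets are expressed in the nominal
  (pre-misalignment) detector frame; detector rotations act about the
  detector center.
* **SOD offset.** A positive $\Delta sod$ moves the source away from the
  rotation axis; the detector keeps its *measured* distance SDD from the
  source, because SDD is held fixed at its measured value throughout.
* **Stereo angle.** Pair 2's entire nominal frame is pair 1's rotated by
  $\alpha$ about the rotation axis; nominally $\alpha = 90^\circ$.

The misalignment state is the 21-entry vector
$\beta = \{\Delta x_o, \Delta y_o, \Delta z_o, \theta_o, \phi_o, \eta_o,
\alpha, \Delta sod_1, \Delta sod_2,
\Delta x_{id}, \Delta y_{id}, \Delta z_{id},
\theta_{id}, \phi_{id}, \eta_{id}\}$, $i = 1, 2$ — six phantom-pose DOF,
the stereo angle, and per system one SOD offset plus six detector-pose
DOF. Each entry carries units, bounds and a fixed/free mask
(`parameter_vector()`).

## The phantom

`build_phantom()` converts a brick-lattice description into marker
coordinates by pure lattice arithmetic. The default calibration phantom is
eight layers tall on a single 6×2-stud footprint with five beads. Two
measured quantities anchor the dimensions: a caliper width of 47.7 mm over
six studs (stud pitch 7.95 mm) and a total height of 76.2 mm over eight
layers (layer pitch 9.525 mm). The commonly quoted brick height is
9.6 mm; the 9.525 mm default reproduces the measured stack height and the
discrepancy is deliberately left visible as a configurable pitch rather
than resolved.

Beads bear in the hollow cylinders on the brick undersides (at stud-grid
midpoints) and are pressed in exactly one diameter deep. "One diameter
deep" is read as bounding the *top* of the sphere, so the bead center sits
1.5 diameters below the cylinder mouth (`depth_fraction = 1.5`,
overridable). The phantom frame origin is the geometric center of the
bounding box; the exact five placements of the original phantom are not
published, so the default placement follows the stated rules — no two
beads in the same layer, beads near the facets — without claiming to be
identical to it.

Two placement rules are enforced by `validate_placement()`: sharing a
vertical layer is an error (beads would overlap in projection near the
half-turn view); a bead far from every facet is a warning (its trajectory
covers little of the detector).

## Radiograph simulation

`simulate_dataset()` generates synthetic stereo datasets for validation:
for every stage angle and system it can render a radiograph and always
tabulates exact analytic projections of the bead centers (the same forward
model used by the calibrator, `project_all()`). Beads are rendered as
attenuating spheres: each pixel-center ray gets intensity
$b\,\exp(-\mu\,\ell)$ with $\ell$ the analytic chord length through the
sphere. Defaults: background $b = 10000$ counts, $\mu$ chosen so the
central chord transmits 5%, no noise; Poisson noise at the stated counts
is available and seeded. Optional $3\times3$ per-pixel supersampling
refines edge pixels for sub-pixel fidelity studies.

The simulator deliberately emulates only what the detection chain needs:
bead contrast on a flat background, cone-beam magnification, field-of-view
clipping, optional photon noise. It does *not* model the brick plastic,
polychromatic spectra, scatter, detector blur or image-intensifier
distortion. Passing detection tests therefore demonstrate the geometric
correctness of the pipeline on ideal bead images, not robustness to every
artifact of real radiographs (real-data preprocessing such as distortion
correction is out of scope).

## Bead detection

Measured centers come from a classical three-step chain
(`detect_dataset()`):

1. **Flatfield/log correction** — $-\ln((raw - dark)/(flat - dark))$,
   clipped below at zero, turning beads into positive peaks.
2. **Template matching** — zero-normalized cross-correlation against the
   synthetic chord-profile template of the expected projected bead radius
   (computed from nominal SOD/SDD and the bead diameter); peaks above a
   0.5 score are kept and non-maxima suppressed within one template
   diameter.
3. **Sub-pixel refinement** — intensity-weighted centroid in a window
   around the peak after subtracting the median of the window's border
   ring. A learned center refiner could be slotted in here; the centroid
   meets the 0.1 px closure target on noiseless renders without trained
   weights.

Marker identities across views are not observable from a single bead
image, so correspondences are established against the projections
predicted by an initial geometry: per view, the assignment minimizing the
total candidate-to-prediction distance (Hungarian algorithm), with two
safeguards — assigned pairs farther than a gating radius (default 5
template radii) are dropped, and markers whose *predictions* approach each
other within the gate are dropped for that view only, since overlapping
beads are not deblended. This predicted-projection gating is a documented
package choice; with grossly wrong initial geometries the image pipeline
re-matches once against a first calibration estimate.

## The calibration cost and staged estimation

The cost of a parameter vector $\beta$ is the total Euclidean distance
between model-predicted and measured bead centers over all valid records,

$$C(\beta) = \sum_{n}\sum_{k}
  \sqrt{(u^{ref}_{nk}(\beta) - u^{mea}_{nk})^2 +
        (v^{ref}_{nk}(\beta) - v^{mea}_{nk})^2},$$

evaluated in mm by default (a pixel mode is provided; the two differ only
by per-system scale factors). Predictions falling outside the field of
view stay in the sum at their computed coordinates, so the optimizer
cannot profit from pushing beads off the panel. A sum-of-squares variant
exists as an option. For optimization the summands are smoothed to
$\sqrt{r^2 + \varepsilon^2}$ with $\varepsilon = 10^{-9}$ mm, making the
cost differentiable at zero residual; `calib_cost()` reports the exact
(unsmoothed) sum.

Because a blind start (everything 0, $\alpha = 90^\circ$) is far from the
optimum and the yaw $\phi_o$ is entirely unknown, estimation is staged
(`default_schedule()`), each stage a bound-constrained L-BFGS-B
minimization over a subset with central finite differences (steps
$10^{-4}$ mm, $10^{-5}$ deg):

1. $\{\phi_o, \Delta y_o\}$ on system 1, preceded (first pass only) by a
   coarse scan of $\phi_o$ over $[0, 360)^\circ$ in 5° steps with
   $\Delta y_o$ re-solved at each grid point — the cost is highly
   multimodal in the yaw;
2. phantom translations, then 3. phantom orientations (system 1);
4. phantom 6-DOF plus $\alpha$ on both systems;
5./6. $\Delta sod_i$ alone, then jointly with detector $i$'s six DOF
   (the joint-vs-sequential split is configurable);
7. all free DOF jointly on both systems.

Default bounds: translations ±100 mm, $\Delta sod$ ±50 mm, detector and
phantom roll/pitch ±45°, $\phi_o$ unbounded (360°-periodic; adding a full
turn gives an equivalent optimum), $\alpha$ within ±30° of nominal.

The outer loop repeats the schedule until *either* the cost decrease *or*
the largest parameter update falls below $10^{-6}$ (mm/deg), capped at 30
iterations. Accepted stage solutions never increase the cost: a stage
ending worse than it started is discarded with a warning.

### Levenberg–Marquardt refinement

The $(\Delta sod_i, \Delta x_{id})$ pairs are nearly degenerate — both
act on the magnification $M_i = (SDD_i + \Delta x_{id})/(SOD_i +
\Delta sod_i)$ — so the cost has two valley directions along which
coordinate-wise and quasi-Newton steps crawl. The staged schedule alone
stalls there with residuals far above what the data support. Each outer
iteration therefore ends with a Levenberg–Marquardt step on the full
residual vector over the free parameters, accepted only when it lowers
the (sum-of-distances) cost and respects the bounds. The step is a pure
accelerator: the next outer iteration re-runs the staged minimization of
the configured cost from the refined point, so the final estimate remains
an optimum of the default cost and the outer cost trace stays
non-increasing. With exact synthetic measurements this refinement
recovers all 21 parameters to machine precision; with noisy measurements
it is typically rejected near convergence and the staged estimate stands.

### Degeneracy and the real-data mode

The magnification degeneracy is quantitative: shifting the source by
$\delta$ ($\Delta sod_i$) and the detector along the optical axis by
$\delta\,SDD_i/SOD_i$ changes the cost more than an order of magnitude
less than either shift alone, and the two flattest eigenvectors of the
cost Hessian at the optimum lie almost entirely in the
$(\Delta x_{id}, \Delta sod_i)$ subspace. Consequently those parameters
are only recovered to millimetres even from perfect data — and their
errors cancel in reconstruction. For real acquisitions the recommended
mode eliminates the redundancy: fix both SOD offsets at zero
(`fix_parameters(beta, c("dsod_1", "dsod_2"))`, 19 free DOF) and let
$\Delta x_{id}$ carry the magnification correction alone.

## Exporting geometry for reconstruction

A calibrated stereo scan of $N$ angles per system can be treated as a
single-source scan of $2N$ views: `merge_stereo_angles()` expresses each
static pair frame in the rotating sample frame, whereby pair 2's views
become pair-1-style views at angles shifted by $\alpha$.
`export_cone_vectors()` writes each view as 12 numbers (source, detector
center, pixel-step vectors along $u$ and $v$) — the per-view vector
format consumed by cone-beam reconstruction engines.

## Validation, problem sizes, limitations

The package validates itself against a simulated stereo study: 61 angles
per system, 2048² panels at 142 μm, measured SOD/SDD {779, 1123} and
{783, 1141} mm, the default five-bead phantom, and a known ground-truth
misalignment (`sim_study_config()`) including a 187° phantom yaw and a
94.1° stereo angle. From a blind start on exact centers the staged
calibration recovers every orientation parameter to well below 0.1°, the
stereo angle to below 0.008°, and the non-optical translations to well
below 170 μm (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`). Unit tests exercise the same machinery at 9–15
angles and on 512² renders to keep the default test run fast; the noise
robustness check (0.1 px Gaussian center noise, five seeds) runs at the
full 61-angle size because its 0.1° criterion is statistical.

Known limitations: circular trajectories and flat panels only (no
curved image-intensifier model, no distortion correction), beads-only
rendering, no global optimizers beyond the yaw scan, and the optical
translations $(\Delta x_{id}, \Delta sod_i)$ are structurally
ill-determined — by design they are reported as estimated but should be
interpreted jointly through the magnification they imply.
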