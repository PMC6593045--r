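---
title: "Quantifying rat hindlimb gait from marker-based motion capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rat hindlimb gait from marker-based motion capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Volumetric muscle loss (VML) — loss of muscle tissue beyond the body's
regenerative capacity — leaves a permanent functional deficit. In the rat
model used to evaluate regenerative therapies, roughly 20% of the tibialis
anterior (the main ankle dorsiflexor) is excised and function is tracked
over weeks. Isometric torque testing measures what the muscle *can* produce;
treadmill gait analysis measures what the animal actually *does* with it:
compensation patterns such as delayed joint-angle trajectories, reduced
excursions, faster cadence and shortened swing.

`ratgait` implements the full measurement chain for such studies: a scaled
rigid-body model of the rat hindlimb, weighted least-squares inverse
kinematics (IK), automated treadmill gait-event detection, cycle
normalization, spatiotemporal and phase-shift metrics, one-dimensional
statistical parametric mapping (SPM) with permutation inference, and the
torque-sweep reduction. Because the underlying animal recordings of such
studies are rarely deposited, the package also ships a forward simulator
that produces marker data with *known* ground truth; every stage of the
pipeline is validated against it.

## The hindlimb model

Four segments — pelvis, femur, tibia, foot — form a chain with 13
generalized coordinates: the pelvis moves freely (3 translations + 3
rotations), the hip and ankle are ball joints (3 rotational DOF each) and
the knee is a hinge (1 DOF). Eight reflective markers drive the model:
SPINE (L6 vertebra), TAIL (5th caudal vertebra), LASI/RASI (iliac crests)
and HIP rigid to the pelvis, KNEE on the femur, ANKLE on the tibia, TOE
(5th metatarsal head) on the foot. Markers are placed over palpated joint
centers with the animal sedated, which lets segment lengths be read
directly off a static frame: femur = |HIP−KNEE|, tibia = |KNEE−ANKLE|,
foot = |ANKLE−TOE|, pelvis width = |LASI−RASI|. `scale_model()` scales each
segment independently by measured/generic length.

Conventions (the literature leaves them open, so they are fixed here once):

* Lab frame: X = belt travel (anterior), Y = up, Z = right-lateral; the
  sagittal plane is X–Y.
* Ball joints rotate intrinsically in the order flexion (about Z),
  adduction (about X), axial rotation (about Y); positive hip rotation is
  external. The knee hinge flexes about −Z so positive knee flexion moves
  the ankle posteriorly, with 0° = full extension.
* Neutral pose: pelvis axes on the lab axes, femur and tibia along −Y,
  foot along +X, all joint angles zero.
* Joint limits: ±90° for hip DOFs and ankle flexion, 0–160° knee flexion,
  ±15° for the non-sagittal ankle DOFs. The ball ankle is retained for the
  13-DOF count, but rat treadmill gait is essentially sagittal at the
  ankle, and a single on-axis toe marker cannot observe ankle
  inversion/eversion when axial rotation is zero; the tight limits and the
  solver's neutral prior (below) keep these coordinates at zero unless the
  data genuinely move them.
* Generic segment lengths (pelvis 25, femur 35, tibia 40, foot 28 mm) are
  placeholders of realistic adult-rat magnitude; they are replaced by
  per-animal scaling and never enter results directly.

## Inverse kinematics and the knee skin artifact

Each frame solves

$$\min_q \sum_m w_m \lVert p_m^{obs} - \mathrm{FK}_m(q) \rVert^2$$

by damped Gauss–Newton (Levenberg-style multiplicative damping,
finite-difference Jacobian, joint limits enforced by projection, only
objective-decreasing steps accepted). Frames are warm-started from their
predecessor; a stalled or high-residual solve is retried from a small fixed
grid of flexion initializations, so the solver is deterministic end to end.
Convergence is declared when the gradient ∞-norm falls below 1e−8 or steps
shrink below 1e−9 (a one-shot central-difference "polish" pass runs when
forward differences stall first).

Two numerical details matter:

* **Neutral prior.** A very weak quadratic pull (weight 1e−8 mm²/deg²)
  draws the seven joint-angle coordinates toward neutral. It is invisible
  for observable coordinates (displacement ≪ 1e−4°) but pins
  marker-unobservable directions — ankle inversion with the toe on the
  flexion axis — instead of letting them random-walk along the null space
  across warm-started frames. A final exact relaxation snaps any coordinate
  whose curvature is prior-only back to neutral when that provably leaves
  the marker fit unchanged.
* **Knee down-weighting.** Skin slides over the rat knee, so the KNEE
  marker carries by far the largest soft-tissue artifact. The default
  weights are 1 for all markers and 0.1 for KNEE: the sagittal knee angle
  is then driven mainly by the HIP and ANKLE markers through the rigid
  two-link chain. With the knee weight at exactly 0 the recovered knee
  flexion reduces to the law-of-cosines closed form
  `knee_angle_two_link(femur, tibia, |HIP−ANKLE|)`, which serves as an
  independent oracle in the test suite. One caveat is intrinsic to the
  geometry, not the solver: the two-link map from hip–ankle distance to
  knee angle has unbounded condition number at full extension, so near
  extension micrometer-scale marker differences separate poses several
  knee-degrees apart and the angle is effectively unidentifiable from
  marker data (the flat objective also slows the solver there); a similar
  flat-objective degeneracy arises at the hip-adduction gimbal (±90°,
  where the flexion and rotation axes align). Oracle agreement is
  therefore claimed, and tested, on the non-degenerate interior of the
  joint space — knee flexion 10–160°, hip adduction within ±80° — where
  sub-0.5° agreement needs only ~0.03 mm of fit precision. Rat treadmill
  gait sits deep inside that interior. The value 0.1 (the literature says
  only "reduced") retains a weak stabilizing pull; an anterior knee
  artifact growing with knee flexion produces strictly smaller knee-angle
  errors at weight 0.1 than at weight 1 across 1–10 mm artifact amplitudes.

## Event detection and cycle normalization

Treadmill stance has a crisp kinematic signature: the toe is carried
backward at belt speed while staying on the belt. `detect_events()` marks
coarse stance frames where the smoothed anterior toe velocity lies within
30% of −belt speed *and* the toe is below the 25th height percentile +
2 mm, closes/removes runs shorter than 50 ms, then refines each edge
against a robustly fitted belt line `x(t) = a − v_{belt} t` (median
intercept, MAD scale): the edge moves to the outermost frame still on the
line. The refinement matters because smoothing and central differences
smear the velocity corner at contact by 2–3 frames; the deviation of the
swinging toe from the belt line grows quadratically with time-to-contact
and localizes the edge to about a frame. Heel strike is a stance onset,
toe off a stance offset; boundary transitions are not emitted. Against
simulator ground truth the detector stays within ±1 frame (8.3 ms at
120 Hz) at belt speeds 20–60 cm/s under 0.5 mm marker noise.

Cycles (right-leg heel strike to heel strike, containing their toe off)
are resampled by cubic spline onto the standard 101-node 0–100% continuum.
Stance fraction is (TO − HS)/(HS′ − HS); stance and swing fractions sum to
one by construction.

**Filtering.** The pipeline low-pass filters the IK angle series before
cycle cutting (4th-order zero-phase Butterworth). The default cutoff is
15 Hz, not the 6 Hz customary in human gait: rat strides run at ~3 Hz, so
6 Hz sits on the second stride harmonic and visibly shrinks joint
excursions (and, worse, attenuates control and injured groups differently
when their stride rates differ). 15 Hz passes the first 4–5 harmonics
essentially untouched while suppressing frame-to-frame marker noise, whose
extrema would otherwise inflate per-cycle ranges of motion by several
degrees at 0.5 mm marker noise. The low-level functions default to no
filtering; the pipeline configuration enables it.

## Metrics

* `spatiotemporal()`: stride time (mean HS→HS), cadence = 60/stride time,
  swing % = mean of 100·(HS′−TO)/(HS′−HS). Cadence is *per stride*: the
  treadmill values this package is calibrated to (~172 "steps"/min at
  0.352 s stride time) are only consistent with strides per minute, and the
  package standardizes on stride-based definitions.
* `range_of_motion()`: max − min of a cycle curve. The per-animal summary
  averages per-cycle ROMs (an "average range of motion"); the ROM of the
  mean curve is also reported and is systematically smaller under
  imperfect alignment.
* `phase_shift()`: the circular lag (integer % of cycle, −50…+50)
  maximizing the Pearson correlation between a reference and a test curve,
  positive = test delayed, ties toward the smallest |lag| (positive on an
  exact ± tie). The printed delay percentages of VML studies are
  reproduced by applying this to the control vs injured group mean curves.

## Curve statistics

`spm_ttest2()` computes the pointwise two-sample pooled-variance t
statistic along the 101-node continuum and controls family-wise error with
the permutation distribution of max\|t\| over group relabelings — exact
enumeration whenever the count (e.g. C(12,4) = 495 for 8 vs 4 curves) fits
the permutation budget, otherwise seeded random permutations including the
observed labeling. The critical value is the ⌊(1−α)B⌋-th order statistic of
the B max statistics; rejection requires strictly exceeding it, giving a
rejection probability of 25/495 ≈ 0.0505 at α = 0.05 under full 8-vs-4
enumeration. Supra-threshold clusters get p = (b+1)/(B+1) from the same
distribution (never zero). Permutation rather than random-field theory was
chosen because it is exact at the n = 4–8 of rodent studies and requires no
smoothness estimation; cluster inference uses the cluster-max statistic.
`spm_paired()` does the same with sign-flips of difference curves.
Scalar comparisons use the classical paired t-test and one-way ANOVA with
Fisher's LSD post-hoc tests (unadjusted pairwise p at df = N − k, computed
from MS_within of the `aov` fit).

## The simulator and what passing its tests means

`generate_joint_curves()` builds each of the five reported angles (hip
flexion/adduction/rotation, knee flexion, ankle flexion) from three Fourier
harmonics: fixed relative amplitudes and phases give a gait-like shape
(single-peak hip, double-bump knee/ankle), rescaled so the peak-to-peak
range equals the target ROM and offset to the target mean. Defaults are
calibrated to healthy rat treadmill walking at 40 cm/s and 120 Hz: stride
0.352 s, swing 45.71%, flexion ROMs 39.24/52.88/53.88° (hip/knee/ankle).
Frontal/transverse hip ROMs are not tabulated in the rat literature the
package targets; 12° and 15° are used as modest physiological defaults.
Published curve *shapes* exist only as figures, so shapes are qualitative
and only the printed scalars are calibration targets — a stated limitation.

The contact schedule is prescribed, not emergent: during stance the toe
moves at −belt speed on the belt (y = 0); during swing a quintic profile
returns it with C1-continuous belt-speed matching at both ends, steep edge
curvature (so the detector's velocity band is entered/left within ~1 ms)
and a sin² lift to 10 mm clearance. Pelvis translations absorb the
difference between this toe path and the toe position implied by the joint
angles, so the pelvis bobs periodically with zero mean velocity — treadmill
kinematics, not overground. True HS/TO times follow exactly from the
schedule; trials are padded with 0.15 s of continued walking at each end so
every true event is interior.

Measurement noise: isotropic Gaussian marker noise (default σ = 0.5 mm,
typical of small-volume optical capture), an anterior knee skin artifact
proportional to instantaneous knee flexion (default 3 mm peak), and smooth
windowed per-cycle waveform perturbations (default σ = 1°) emulating
cycle-to-cycle variability. The injury transformation applies per-angle
circular delays (defaults 3/2/3/5/4% of cycle), ROM scaling (defaults
0.9/0.9/0.9/0.85/0.85), a stride-time factor (0.314/0.352) and a swing
offset (−3.89 points) — the week-8 deficit pattern of a 20% TA VML injury.
Between-animal variability perturbs stride time (sd 0.034 s), swing (sd
3.23 points), ROMs (sd 6.99/2/3/10.21/10.07°) and segment lengths (sd 5%).

`generate_cohort()` defaults to 4 control + 4 injured animals and one
60-cycle trial (~21 s of walking) per animal. The bout length is a power
choice: with 12-cycle trials the Monte-Carlo error of the cross-correlation
delay estimate for the noisiest angle (hip rotation, whose lever arm is
weakest in IK) is ~0.5% of cycle — too large to claim recovery at the 1%
reporting resolution; at 60 cycles it drops to ~0.2%, small relative to
the resolution, while staying a tiny fraction of a typical 15-minute
treadmill session.

What passing means — and does not. The simulator shares the analysis
model's skeleton, so IK inversion tests demonstrate solver correctness,
not model validity for real rats. Real data add soft-tissue motion at every
marker (not just the knee), marker occlusions and relabeling errors,
non-stationary gait and shape changes under injury beyond delay + scaling
(reachable via per-harmonic configuration but not defaulted). The
statistical modules are validated independently of the kinematic chain
(type-I error calibration on smooth random curves; closed-form oracles),
so their guarantees do carry to real data.

## Degenerate inputs and numerical choices

* TRC files: tab-delimited, mm/cm/m units (converted to mm), blank cells =
  missing samples; header/row-count inconsistencies are errors with line
  numbers. Round-trips are lossless at the written 6-decimal precision.
* Missing markers in a frame drop to weight 0; frames with < 3 usable
  markers are flagged and linearly interpolated across gaps ≤ 5 frames
  (~42 ms), longer gaps stay `NA`.
* Standing still on a stopped belt yields a single stance and an
  empty-events warning rather than fabricated cycles.
* Zero-variance curves make phase shifts and t statistics undefined; these
  raise classed errors instead of returning NaN.
* Fewer than 3 cycles per animal sets a below-minimum flag (the usual
  three-step minimum), mirrored as a warning in the pipeline manifest.

## Reproducibility

Every stochastic component takes an explicit seed and restores the RNG
state on exit; cohorts, torque studies and pipeline runs are pure
functions of (parameters, seed). `run_pipeline()` writes per-stage CSVs,
SPM reports per angle, and a JSON manifest with seeds, parameters, warnings
and MD5 checksums of all outputs; re-running a configuration reproduces
identical files.

```{r, eval = FALSE}
library(ratgait)
study <- run_pipeline(run_config(seed = 17, out_dir = "run1"))
print(study)
study$phase_delays          # recovered injured-vs-control delays, % of cycle
study$spm$ankle_flexion     # SPM result with clusters and permutation p
```
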