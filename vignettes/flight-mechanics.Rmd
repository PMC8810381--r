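---
title: "Flight mechanics of bristled-wing microinsects: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flight mechanics of bristled-wing microinsects: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bristlewing)
library(ggplot2)
```

## The problem

Sub-millimetre insects such as featherwing beetles (Ptiliidae) fly at
Reynolds numbers near 10, where viscous friction dominates over air
inertia. Many of them carry bristled wings - a narrow blade fringed
with long setae ("ptiloptery") - instead of a continuous membrane, and
beat them in a wide, self-intersecting figure-of-eight with near-claps
above and below the body. bristlewing implements the analysis chain
that turns rigid-body wing/elytra kinematics and per-part aerodynamic
force records of such an insect into its mechanically meaningful
summaries:

* wing mass, centre of mass and inertia tensor from composite geometry
  (membrane patches + setal rods), for the bristled wing and for
  hypothetical membranous substitutes with the same outline;
* stroke-plane frame, wingbeat cycles, phase averages, angle of attack
  (AoA), Reynolds number and clap distance from Euler-angle series;
* lift/drag decomposition of aerodynamic forces and a per-part
  vertical-force account;
* aerodynamic, inertial and total mechanical power with
  elastic-storage scenarios;
* single-axis body-pitch dynamics with and without the inertial
  braking recoil of the elytra.

A seed-deterministic synthetic-data module generates kinematics,
morphologies and force series with the phase structure the analysis
assumes, so that every stage is testable without recordings.

## Units and conventions

All internal computation uses a micro-scale unit system - micrograms,
micrometres, milliseconds - in which the numbers describing a beetle
of body mass 2.43 ug are of order one: forces come out in nN, torques
in fN m, powers in pW, and gravitational acceleration is numerically
9.81. Exact converters to SI are exported (`force_internal_to_si()`
and friends). Angles are stored in degrees, converted to radians only
inside trigonometry.

The lab frame is right-handed with z up; the pitch axis is y, with
nose-down torque positive. Each moving part (wing or elytron) has a
*stroke frame*: a right-handed orthonormal triple (u, v, n) with n the
stroke-plane normal, anchored at the articulation point. The Euler
sequence is the standard hovering-insect order: positional angle phi
about the normal, stroke deviation theta out of the plane, pitch psi
about the spanwise axis. Right-side frames are constructed as
(Mu, Mv, -Mn) for the sagittal mirror M, which keeps them right-handed
(so angular velocities and torques are ordinary vectors, with no
pseudo-vector bookkeeping) and makes the mirror map on angles simply
(theta, phi, psi) -> (-theta, phi, -psi); that map is what
`phase_average()` applies to the right side before averaging. Whether
a bilateral average should mirror the right side at all is a
convention; mirroring is assumed here and documented.

The AoA convention: the angle between the wing chord plane and the
velocity of the radius-of-gyration (Rg) point, 0 deg for feathered
(edge-on) motion and 90 deg for flat-on motion, signed by the
chordwise velocity component so opposite stroke directions plot with
opposite signs. Where the speed vanishes (stroke reversals) the AoA is
undefined and reported as a gap, never interpolated - the decomposition
of force into drag and lift divides by the speed, so the same gaps
propagate there by design.

## Mass properties

Setae are thin rods with uniform linear density; their tensors use the
closed thin-rod formula and the parallel-axis theorem. The default
linear density 9.6e-7 ug/um (0.96 ug/m) is a measured value for setae
carrying secondary outgrowths - the outgrowths are not modelled
geometrically but absorbed into this density, as is standard for this
wing type. Membrane patches (petiole, blade, substitutes) use a
midpoint quadrature on a square grid with boundary cells weighted by
an area fraction estimated on a 4x4 subgrid; the result converges to
the exact polygon integrals as the step shrinks. The default step is
2 um: a 50 um step, sometimes quoted for such calculations, would
under-resolve a ~30 um petiole, so the coarse value is available only
as an explicit argument. Cuticle density defaults to 1,200 kg m^-3
(1.2e-6 ug/um^3), configurable by about +/-100 kg m^-3 for error
propagation.

The membranous substitute of a bristled wing is a membrane whose
perimeter follows the proximal wing-root margin and then the polyline
through the seta tips, in the listed seta order (the caller is
responsible for margin order; self-intersecting outlines are rejected
with the offending segment pair named). Substitute mass is exactly
linear in the chosen thickness; the defaults 0.73, 0.85 and 1.12 um
are the minimal membrane thicknesses measured in the smallest known
membranous-winged insects.

Every tensor is validated (symmetry, positive semi-definiteness,
triangle inequalities on the principal moments) and is tested against
brute-force point-mass discretisations at a million samples.

## Kinematics

The stroke plane is fit by a total-least-squares (major-axis)
criterion: the plane through the wing base whose normal is the
smallest principal direction of the tip cloud - preferred over an
ordinary regression because wide figure-of-eight tip paths form broad
scatter clouds. Cycles are the rising zero crossings of phi(t),
located by root finding on a cubic-spline interpolant; the period is
the mean boundary spacing. Series are resampled on uniform grids by
cubic splines with Forsythe-Malcolm-Moler end conditions (polynomials
up to cubics reproduce exactly). Phase averages spline each detected
cycle onto a common t/T grid, average across cycles, then across
mirrored sides.

Differentiating phase-averaged estimates needs care: a noisy average
is not exactly periodic at the wrap point, and differentiating through
the seam produces large spurious spikes. `bristlewing` therefore
differentiates periodic series spectrally after (i) removing the seam
jump - estimated from the second difference across the wrap, which is
O(h^2) for genuinely smooth data - as a linear ramp, and (ii)
discarding harmonics above a cutoff (default 16): phase averages of
video-rate recordings carry no legitimate content beyond the per-cycle
Nyquist of the original sampling, while the seam artefact lives at the
highest frequencies. For band-limited inputs (such as the synthetic
protocols, which are finite Fourier series) the spectral derivative is
exact. The inertial-power routine band-limits the angular velocity
with the same filter it uses for the acceleration, so the computed
power is exactly the rate of change of the kinetic energy of the
band-limited motion and integrates to zero over a cycle to round-off.

The planform scalars R, S, mean chord S/R and Rg are *area-based*
properties of the aerodynamically effective outline (the substitute
boundary), because they serve aerodynamic velocity scaling; Rg is the
root of the polar second area moment about the base. Body speed is
finite-differenced from the tracked body centre and loess-smoothed
(span 0.25 by default; the span is a free parameter).

## Forces

`decompose()` implements the projection definition: drag is the
component of the total aerodynamic force along the direction of the
Rg-point velocity, lift is the vector remainder; both are projected on
the vertical axis for the weight-support account. Exactness
(drag + lift = total) and orthogonality (lift . v = 0) are asserted on
every call at 1e-9 relative, and tested at 1e-12 on random data.
`vertical_breakdown()` averages each part's vertical force over the
cycle, expresses it as weight-equivalent mass, splits the wing
contribution into drag and lift percentages (they sum to 100 exactly),
and reports the implied steady vertical acceleration.

When no computed (CFD) force file is available, a quasi-steady
blade-element surrogate generates per-part series: drag of magnitude
0.5 rho cd(AoA) S U^2 exactly anti-aligned with the Rg velocity, plus
lift perpendicular to the velocity in the chord-velocity plane,
pushing away from the struck face, with a (1 + k/Re) low-Reynolds
inflation. The default coefficient table (flat-plate-like cd rising
monotonically from 0.8 edge-on to 3.4 flat-on, cl peaking at 0.9 near
45 deg) is a desk-scale stand-in chosen for plausible magnitudes and
phase structure, not a calibrated reference; every entry is
caller-replaceable. Loaded force files must declare units and the
torque reference point; torques are re-referenced with the concurrent
force via the moment-transfer law.

## Power and elastic storage

Aerodynamic power is `-tau_b . omega` per part (base torque dot
angular velocity; positive when the part works on the air), summed
over wings and elytra - the wing and elytra totals are also available
separately, since conventions differ on whether a "flight power"
figure includes the elytra. Inertial power is the rate of change of
rotational kinetic energy, `omega . (I alpha + omega x (I omega))` in
wing-fixed axes. The storage scenarios follow from rectification:
muscles without elastic storage cannot absorb negative power, so the
required mean is `mean(max(P, 0))`; perfect storage recovers all of
it, giving `mean(P)`. When the total power never goes negative the two
coincide and elastic storage is obsolete - this is precisely what low
wing inertia buys a bristled wing, and on the default synthetic beetle
the bristled budget stays positive through the cycle while the
membranous substitutes (9-18 times the Izz) develop large negative
phases.

## Pitch dynamics and the elytra brake

The body-pitch model is a single-axis torque balance
`I_b chi'' = tau_aero(t) + tau_recoil(t)` with prescribed periodic
forcing, integrated by fixed-step classical Runge-Kutta (`deSolve`)
over several cycles; body-pitch feedback onto the wing kinematics is
deliberately not modelled (kinematics are prescribed in the lab
frame). The recoil torque of each elytron is the reaction to its
angular-momentum change, `-d/dt (R I omega_local)`, projected on the
pitch axis; "flight without elytra" zeroes only this recoil term,
keeping the (negligible) elytra aerodynamic torque - removing the
elytra entirely is available by dropping their force series.

Two measurement details matter in an undamped double integrator.
First, the cycle-mean of the prescribed aerodynamic torque is
subtracted before integration (`trim_mean = TRUE`): a hovering animal
is trimmed on average, and any residual mean would accumulate a
quadratic drift that swamps the oscillation. Second, the first cycle
is discarded as a start-up transient and the remaining trajectory is
detrended by a line fitted through the per-cycle means - the cycle
mean of the periodic component is a constant, so this removes exactly
the linear drift the start-up conditions inject - before peak-to-peak
amplitudes and their with/without-recoil ratio are measured. Against
the closed-form forced-oscillator solution this procedure is accurate
to well under 1%, and halving the integration step changes the
amplitudes by less than 0.1%.

The body pitch moment of inertia is not something that can be read off
a typical study's main text; the default, 3.2e4 ug um^2, is a
slender-body estimate m L^2 / 12 for a 2.43 ug, 395 um body, and is a
plain configuration input.

## The synthetic study conditions

The generator's defaults *are* the study conditions; they are not
tuned per test. The default morphology: wing length 493 um, 45 setae
of linear density 9.6e-7 ug/um fanning +/-80 deg from a lens-shaped
blade behind a petiole, cuticle density 1,200 kg m^-3, substitute
thicknesses (0.73, 0.85, 1.12) um. The resulting bristled wing weighs
about 0.019 ug (under 1% of body mass, Izz about 900 ug um^2) with
the setal fringe occupying about 95% of the effective area; the
substitutes weigh 0.12-0.18 ug with Izz 10,600-16,200 ug um^2. These
track the published morphology of the smallest featherwing beetles
(wing mass about 0.024 ug, Izz 1,600 vs 13,800-20,800 ug um^2) at the
level a synthetic fixture can.

The default protocol: positional angle `phi = Phi (sin 2 pi x -
0.12 sin 4 pi x)` (down-fast/up-slow asymmetry; x = t/T), deviation
`theta = 15 sin(4 pi x + 50 deg)` (the double-frequency term that
makes the sagittal tip path a self-intersecting figure-of-eight),
pitch `psi = 86 cos 2 pi x + 3 cos 4 pi x` (flat-on at both fast
phases, feathered at the claps), stroke plane pitched 40 deg to the
horizon, wing bases 150 um apart. Two parameters are calibrated at
generation time rather than fixed: the positional amplitude Phi by
root-finding so the ventral near-clap reaches a 30 um tip separation,
and the wingbeat frequency so the cycle-averaged Reynolds number is 9
(Re is exactly linear in f for a fixed protocol shape; the default
lands near 236 Hz, consistent with video-rate observations of such
beetles). Elytra sweep 80 deg peak-to-peak in the sagittal plane with
a phase chosen so their recoil opposes the fundamental of the wing
pitch torque - emulating the observed synchrony in which the elytra
close as the wings start their downstroke - and their pitch oscillates
52 deg peak-to-peak in antiphase to the wing sweep. Angle noise is
i.i.d. Gaussian (default 1 deg), the simplest model consistent with
manual frame-by-frame pose registration; sampling emulates a 3,845
frame-per-second camera over four wingbeats.

One deliberate simplification: in the real animal both half strokes
produce net upward force through a strongly three-dimensional path,
whereas the generator realises net positive cycle-averaged vertical
force through the down-fast/up-slow speed asymmetry with flat-on pitch
at both fast phases. This satisfies every structural property the
analysis relies on (force peaks inside the power-stroke windows, net
drag-based weight support, claps, figure-of-eight) with a much simpler
harmonic description. Consequences of the synthetic idealisation in
general: passing tests demonstrate the correctness of the analysis
operators on data with this structure, not the fidelity of any real
recording; real data add wing flexibility, tracking outliers and
non-stationary cycles that the generator does not emulate.

## What a default run looks like

```{r pipeline, eval = FALSE}
report <- run_pipeline(run_config(seed = 1))
report
glance(report)

# figures
autoplot(report$power$bristled)
autoplot(report$pitch)
plot_angles(report$averaged$wing)
plot_tip_path(report$kin$left_wing)
```

On the default conditions the run reports, among other quantities, a
cycle-averaged Reynolds number of about 9 with power-stroke peaks
near 16, power-stroke AoA around +/-70 deg, total vertical force near
2.5 ug weight-equivalent split roughly 20-30% drag / 70-80% lift,
a bristled power budget that stays positive over the whole cycle
(mean about 35 W/kg, peak about 120 W/kg) against membranous
substitutes that require elastic storage, and an elytra recoil that
cuts the body-pitch oscillation roughly in half. All of these are
computed, not asserted; `scripts/acceptance.R` re-derives them from
scratch for any seed.

## Numerical choices and limitations

* Quadrature: midpoint with 4x4 boundary-fraction subsampling;
  cell self-moments are neglected (relative error ~ step^2 / Rg^2,
  about 1e-5 at the defaults).
* Problem sizes: 512-point phase grids, four-cycle protocols,
  million-point oracles in the test suite; these resolve every
  reported quantity to well inside its stated tolerance while keeping
  a full run in seconds.
* Cycle detection assumes phi crosses zero twice per beat in a
  consistent direction; hovering protocols guarantee this, strongly
  asymmetric forward flight may not.
* The quasi-steady surrogate has no wing-wake or wing-wing
  interaction, no added-mass force, and a non-reference coefficient
  table; computed (CFD) force files should replace it whenever
  available. Loaded forces already contain whatever unsteady physics
  the solver resolved.
* The pitch model is single-degree-of-freedom with prescribed
  kinematics; it measures the inertial-brake effect, not free-flight
  stability.
* Gimbal lock: at |theta| = 90 deg the positional angle is
  indeterminate; the inverse pose map flags it rather than guessing.
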