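---
title: "Reconstructing pedestrian-vehicle collisions by multiobjective optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing pedestrian-vehicle collisions by multiobjective optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The inverse problem

After a vehicle strikes a pedestrian, the scene preserves a handful of
physical marks: a spiderweb fracture on the windscreen where the shoulder
hit, an imprint on the bumper or bonnet leading edge from the thigh, a
scuff low on the bumper from the calf, and the point where the head struck
the road. The pre-impact conditions — how fast the car was going and where
and how the pedestrian was standing — are unknown. Reconstruction treats
them as the decision vector of an optimization problem: find the initial
conditions whose simulated collision reproduces the observed marks.

The decision vector has five components:

| symbol | meaning | units | search range |
|---|---|---|---|
| V | vehicle impact speed | m/s | 16 – 20 |
| D | pedestrian lateral offset from the vehicle's long axis | m | 0.14 – 0.54 |
| alpha | pedestrian yaw relative to the vehicle heading | rad | 0.30 – 0.70 |
| beta | head pitch (up–down) | rad | −0.20 – 0.20 |
| gamma | head yaw (left–right) | rad | −0.20 – 0.20 |

The speed range comes from a surveillance-video estimate
(`speed_from_video()`: a reference distance divided by the elapsed frame
time, snapped outward to a 1 m/s grid by `speed_bounds()`); the remaining
ranges bracket the posture visible in the video frame before impact.

Each candidate design is simulated forward. For each of four marker pairs
(I shoulder–windscreen, II thigh–bonnet leading edge, III calf–bumper,
IV head–ground) the subobjective is the Euclidean distance between the
pedestrian-body marker and the recorded mark, evaluated at the instant the
designated body segment first touches the designated surface. The
aggregate objective is the plain sum of the group's subobjectives, and
each subobjective is constrained to the band 0–2 m: a mark mismatch beyond
2 m is treated as not corresponding to reality. The optimizers search the
subobjective vector as a true multiobjective problem; the reported global
optimum is the feasible evaluation minimizing the sum, which keeps the
reported quantity identical to the scalar objective a practitioner would
quote.

Two design choices here were genuinely open. First, "the time of impact"
for a pair is taken as the *first* contact of its segment–surface pair
(not the instant of peak force): the physical mark is made when contact
begins, and first contact is well defined even when a segment bounces.
Second, when a candidate design never produces a pair's contact, the
subobjective falls back to the minimum marker distance over the whole
simulation, flagged infeasible, rather than a flat penalty: the fallback
preserves a gradient-like signal that lets the optimizer climb toward
designs that do make contact. A hard penalty of 10 m per pair is reserved
for candidates whose simulation fails numerically, so they are strictly
dominated by every physically meaningful candidate.

## The forward model

The pedestrian is an articulated chain of 11 rigid ellipsoids — head,
neck, upper torso, mid torso, pelvis, and per-side merged arm, thigh, and
leg+foot — connected by penalty joints. Segment lengths scale linearly
with stature and masses with body mass from a fixed proportion table
(masses sum exactly to the input body mass); a full anthropometric
regression generator would add parameters the reconstruction cannot
identify anyway. The default posture is a mid-stride walking stance with
the arms bent and hands in pockets, right leg leading, torso leaning
slightly left; the design angles beta and gamma are composed onto the
head–neck joint, and alpha yaws the whole body about the vertical.

The vehicle front is a planar polyline (x forward, z up) extruded over the
vehicle's width, divided into five zones — bumper, bonnet leading edge,
bonnet middle, bonnet rear, windscreen — each with a piecewise-linear
force–deflection curve in the stiffness ranges of the EuroNCAP legform,
upper-legform, and headform subsystem tests, plus linear contact damping.
The curves are configuration data, not code, so measured curves for a
specific vehicle can be substituted. The vehicle follows a prescribed
motion: constant speed V until the nominal impact instant, then an
optional braking deceleration defaulting to mu_vehicle_ground x g (a
braking driver on wet asphalt). Prescribed motion is justified by the mass
ratio — the pedestrian cannot appreciably decelerate the car.

Contact uses ellipsoid support points against the ground plane and the
vehicle patches: penetration depth feeds the zone curve (or a linear
ground stiffness), a damping term near the critical value for the struck
segment mass makes impacts nearly plastic (body-panel and body-ground
restitution is well below 0.3 — with light damping the model catapults the
pedestrian unrealistically high), and Coulomb friction is regularized by a
tanh slip-velocity law with a 0.05 m/s reference velocity. The friction
triplet (vehicle–ground 0.55, pedestrian–ground 0.6, pedestrian–vehicle
0.3) is the wet-asphalt default.

Integration is fixed-step semi-implicit Euler with quaternion attitude,
default step 2e-5 s, terminating at 1.8 s; outputs are decimated to 1 kHz.
Penalty-joint gains are capped by the stability limits of both the
translational (force/mass) and rotational (force x lever / inertia)
channels at a reference step of 5e-4 s, so the same model constants
integrate stably at the coarse step used for optimization studies and the
fine default step, and refining dt changes the final head position by
millimetres (the convergence test asserts < 5 mm per step halving).
Free flight matches the closed-form parabola to better than 1e-3 m over
0.5 s, and mechanical energy is non-increasing during contact-free motion
to within the integrator tolerance.

## The optimizers

All three algorithms are real-coded, run a population (or swarm) of 20 for
20 generations (iterations) — exactly 400 forward simulations per run, the
study's budget — and log every evaluation:

* **NSGA-II**: fast nondominated sorting, crowding distance, binary
  tournament with feasibility-first constraint handling (a feasible
  candidate beats an infeasible one; among infeasible, the smaller total
  band violation wins), simulated binary crossover (eta = 15, p = 0.9),
  polynomial mutation (eta = 20, p = 1/5), and elitist (mu + lambda)
  environmental selection.
* **NCGA**: same variation operators, but mating uses neighbourhood
  cultivation — each generation the population is sorted along one
  objective (cycling through objectives across generations) and adjacent
  individuals are paired — plus an external nondominated archive merged
  into environmental selection.
* **MOPSO**: an external repository of nondominated particles with an
  adaptive grid (7 divisions per objective) over objective space; leaders
  are drawn by roulette inversely weighted by grid-cell occupancy;
  velocities are clamped to 20% of each variable range, positions reflect
  at the bounds, and a uniform mutation probability decays quadratically
  from 0.5 to 0.
* The constraint-handling mechanism, the hyperparameters above, and the
  archive sizes are not pinned down by the study design; the published
  algorithm descriptions were followed and every value is a documented,
  user-settable argument.

`classify_history()` mirrors the study's solution taxonomy: *noninferior*
solutions are Pareto-nondominated over the entire 400-evaluation history;
*inferior* solutions have some subobjective beyond the 2 m band; *locally
optimal* solutions — a term the taxonomy uses without a formal definition
— are defined here as nondominated within their own generation but
dominated globally. The global best is the feasible evaluation with the
minimal objective sum.

On the Schaffer bi-objective benchmark (f1 = x², f2 = (x−2)², Pareto set
[0, 2]) at the study budget, NSGA-II places ≥ 90% of its final front in
the Pareto set, NCGA ≥ 80% of its archive, and the MOPSO repository covers
≥ 70% of the front image — the package's regression floor for optimizer
quality.

## Synthetic ground truth

Because the real case's evidence, vehicle geometry, and proprietary
human model are unavailable, validation is closed-loop: `generate_case()`
samples a true design uniformly within the study bounds, simulates it, and
records the evidence the way a scene investigator would — the world
position of each pedestrian marker at its pair's first-contact instant,
expressed in the vehicle frame for vehicle-borne marks (so a candidate's
mark moves with the candidate's vehicle) and in world coordinates for the
head-ground mark. Optional isotropic Gaussian noise models measurement
error. Truths that fail to produce all four contacts within 1.8 s are
resampled, mirroring the fact that only cases where all marks exist get
reconstructed.

What the generator emulates: the geometry of mark formation, per-pair
contact timing, the information asymmetry between vehicle-frame and
ground-frame marks. What it does not: video pixel evidence, vehicle
deformation depth, soft-tissue injury patterns, fracture mechanics, or
scene-measurement systematics beyond isotropic noise. Passing recovery
tests therefore demonstrates that the estimation machinery can invert the
package's own forward model at the stated budget — a necessary condition —
not that the simplified model matches any particular real vehicle.

Two closed-loop properties are asserted as tests. With the full marker
group, NSGA-II at the 400-evaluation budget recovers a noise-free truth to
a median best objective ≤ 0.2 m and a median speed error ≤ 0.5 m/s over
five seeds. As rank properties over ten seeds on the reference case:
NSGA-II's median best objective does not exceed MOPSO's — though on this
smooth desk-scale landscape the two algorithms run much closer than on a
rugged industrial simulator, and the ordering can flip on individual
cases — and dropping the head-ground pair
(reconstructing from vehicle marks alone) increases the median error of
the predicted head landing point — the synthetic analogue of the study's
observation that vehicle-only marker groups leave the reconstruction
underdetermined, visible directly in the objective landscape: the
vehicle-frame subobjectives are nearly flat in V, while the head-ground
distance varies by roughly a metre per m/s.

## Injury criteria

`hic()` implements the Head Injury Criterion,
HIC = max over windows (t2−t1) · (mean resultant acceleration)^2.5 with
acceleration in g, maximized over all windows up to 36 ms (15 ms
optional), using a cumulative trapezoidal integral; a brute-force window
scan is the test oracle. `femur_assessment()` bands the peak absolute
femur axial force against the published 3–10 kN fracture range: below
3 kN, within [3, 10] kN (both boundaries inclusive), above beyond 10 kN;
peaks at or above 3 kN are flagged consistent with fracture. No
HIC-to-injury-probability curve is implemented: the published risk curves
differ enough that picking one silently would suggest a precision the
package does not have.

## Problem sizes and numerical choices

The optimization studies (recovery, algorithm comparison, marker-subset
comparison) use the coarse step 5e-4 s — stable by the joint-gain design
above and ~25x faster than the default step — with the full 1.8 s horizon
and the standard 400-evaluation budget per run; five to ten optimizer
seeds per condition. The default fine step 2e-5 s is used for the
integrator-accuracy tests. Ties in dominance comparisons are broken by
evaluation order; personal bests in MOPSO keep the incumbent with
probability 1/2 under mutual nondominance. Degenerate inputs are defined,
not special-cased: zero objective ranges contribute zero crowding
distance, an all-identical front is a single nondominated layer, a zero
acceleration trace has HIC 0, and equal-mean zero-variance ANOVA groups
give F = 0.

## Limitations

The pedestrian has no active musculature and no injury-dependent joint
failure; the vehicle front is a width-uniform extrusion, so marks carry no
lateral curvature information; prescribed vehicle motion ignores
pitch-under-braking; and the evidence model records marker positions, not
mark shapes. The identification results quantify what the marker-distance
objective can and cannot constrain under these simplifications — most
visibly, that impact speed is identified almost entirely by the
head-ground mark.
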