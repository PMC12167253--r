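---
title: "Safe dual-device navigation: models, surrogates and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Safe dual-device navigation: models, surrogates and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endonav)
```

## The task

The second stage of mechanical thrombectomy navigates a micro-guidewire and
micro-catheter from a stable guide-catheter platform in the cervical
internal carotid artery (ICA) to a target in the middle cerebral artery
(MCA). The difficulties are the tortuous distal ICA and branch selection at
the carotid terminus: the guidewire tip is pre-curved, and rotating it about
the device axis points the curve toward the intended branch; a wrong choice
catheterizes the anterior cerebral artery (ACA) instead. A controller
observes only what fluoroscopy could provide — planar tracking coordinates
of three points spaced 2 mm along each device, the target position, and its
own previous action — and commands rotation and translation speeds for both
devices, clamped to 180 °/s and 40 mm/s. An episode succeeds when the
guidewire tip comes within 5 mm of the target; it truncates after 200 steps
of 0.135 s (the step length follows from a 200-step budget spanning
approximately 27 s).

## Synthetic vasculature

Patient meshes are not distributable, so the package generates labelled
planar centerline trees: an ICA-like trunk (default 60 mm, sinusoidal
tortuosity of 4 mm amplitude and 1.5 cycles) that splits at the terminus
into an MCA-like target branch (35 mm, lateral) and an ACA-like distractor
(30 mm, medial), with lumen radii tapering from 2 mm in the trunk to
1.3 mm / 1.1 mm in the branches — dimensions in the range of adult cerebral
vessels. A seeded jitter of ±10 % on lengths and angles stands in for
across-patient variability; left-sided cases mirror the right-sided
parameterization, and training applies anisotropic scaling augmentation in
[0.7, 1.3] per axis. Centerlines are resampled at 0.5 mm so that the ≤1 mm
node-spacing invariant holds with margin. Targets are drawn uniformly from
ten equally spaced points on the target branch, and a target on one side is
only ever navigated from that side's trunk.

`pathlength`, the quantity whose per-step change drives the dense reward,
is measured **along the centerline** (graph distance on the resampled tree
after projecting the tip to its nearest node). The along-centerline reading
is adopted because it is the only one that decreases monotonically along a
correct route past the bifurcation — straight-line distance to an MCA
target can *decrease* while advancing into the ACA. A Euclidean option
remains available via `env_config(pathlength_metric = "euclidean")`.

## The kinematic surrogate

The original experiments run a finite-element beam simulation of both
devices. The learning method, however, consumes only 2-D tracked points and
a scalar tip force, so the package replaces the beam physics with a
follow-the-leader surrogate: the device body occupies the centerline route
from the insertion root to the tip; translation advances or retracts the
tip along that route; the catheter trails over the wire and is clamped so
the guidewire leads. The curved tip maps into the plane as an effective
deflection `tip_curve_angle * cos(rotation)` — rotation at 90° leaves the
curve out of plane (straight in projection), 0° and 180° curl it fully to
either side — and at a bifurcation the environment commits to the child
branch whose tangent best aligns with the deflected tip direction.
Retracting below the bifurcation un-commits the choice, so recovery from a
wrong branch is possible, as it is clinically.

The tip force is a linear penetration proxy: the endpoint of a straight
6 mm distal segment, pointed along the deflected tip direction, is tested
against the lumen; the force is `wall_stiffness` (0.35 N/mm) times the
depth by which that endpoint exceeds the local radius, directed along the
inward normal. At a vessel end the lumen is treated as continuing along the
terminal tangent, since the real vasculature does not end there. The two
constants were calibrated jointly against the behavioral anchors reported
for the original system: the scripted demonstrator's forces stay at or
below 0.80 N across a 40-episode protocol (measured 0.74 N maximum), while
badly steered navigation peaks near 1 N and a random policy spends about
12 % of its steps above the 0.85 N penalty threshold. Device stiffness
values (Young's moduli 47 and 43 MPa) are carried in the configuration for
reference but the surrogate does not integrate beam mechanics.

What the surrogate deliberately omits: device–device interaction forces,
friction, prolapse and buckling, out-of-plane motion, and vessel
elasticity (the original simulation also assumed rigid walls). Tests that
pass on this surrogate therefore validate the *learning machinery and task
logic*, not device mechanics.

## Rewards

The six reward functions are exact transcriptions with all constants
overridable in `reward_config()`: a dense shaping term
`-0.005 - 0.001 * delta_pathlength` plus a terminal bonus of 1.0; the
IRL-derived reward evaluated by the model ipsilateral to the target; their
combination with scale `alpha = 0.001`; and force-penalized versions that
subtract `0.01 * (||P|| - 0.85)` when the tip force exceeds 0.85 N.
`delta_pathlength` is current minus previous, so progress is negative and
the −0.001 coefficient rewards it; flipping both the convention and the
sign would be behaviorally identical, and the chosen transcription is the
one under which the printed coefficient rewards progress. The terminal
bonus is granted exactly once, on the terminating step, using the
environment's 5 mm criterion.

## Demonstrations

A scripted, privileged demonstrator replaces human keyboard navigation for
reproducibility: translation proportional to the remaining pathlength,
rotation aligning the curved tip with the child branch that shortens the
distance to the target, a gradual curl-in on approach (a full curl far from
the ostium would drag the stiff tip along the trunk wall), relaxation to
neutral once inside the branch, and retraction if the distractor was
entered. Small seeded action noise (sd 0.05) makes repeated navigations of
one target distinct, as a human's would be. The recording protocol is two
targets per vasculature, each navigated twice — four navigations per case,
40 demonstrations across ten cases — split by target side for per-branch
IRL training; timed-out demonstrations are flagged and excluded from
training.

## Maximum-entropy IRL

The reward model is a feedforward network of four fully connected layers
from the flattened observation to a scalar, trained so demonstrations are
likely under the maximum-entropy trajectory distribution
`p(tau) ∝ exp(score(tau)/alpha)` with `alpha = 0.1`, where a trajectory's
score is its summed state rewards minus a 0.01 per-step length penalty.
The partition term is estimated from background trajectories supplied by a
sampler that receives the current reward — soft-optimal rollouts on
enumerable problems, environment rollouts on the navigation task — and the
default gradient treats those backgrounds as samples from the current
maximum-entropy distribution (uniform weighting); softmax importance
weighting is available for samplers drawing from an unrelated proposal.
Because the likelihood fixes rewards only up to monotone rescaling and
keeps sharpening them, the output head squashes rewards to a configurable
bound (scaled tanh) and plain gradient steps are the default optimizer:
as rewards approach the bound the gradient vanishes and the weights
settle, whereas scale-normalized (Adam) steps keep drifting through the
saturated region. The documented full setting is 1e6 iterations at
learning rate 1e-2; desk-scale validations use a few thousand iterations,
which suffice on the gridworld recovery problem (the test suite fits
3,000 iterations in under a minute).

## Soft Actor-Critic

The policy encodes observation sequences with an LSTM (16 units by
default) feeding a feedforward trunk and a Gaussian head that emits mean
and standard deviation per action dimension, squashed to [−1, 1] by tanh;
evaluation uses the squashed mean deterministically. Twin feedforward soft
Q-networks take (observation, action); the observation already contains
the previous positions and previous action, so the critics operate on a
near-Markov summary while the recurrence helps the policy disambiguate
branches. Replay stores whole episodes and samples contiguous chunks
(default 8 transitions) that never span episode boundaries; shorter
episodes are padded and masked. The entropy temperature is auto-tuned
toward a target entropy of −4 (one per action dimension). Timeout
truncation bootstraps through the final state; only target-reaching
terminates the value recursion.

One scaling choice matters: the navigation rewards are numerically tiny
(0.005 per step, 1.0 at the terminal), and with an unscaled critic the
entropy bonus `alpha * H / (1 - gamma)` in the soft value dwarfs the task
signal — reaching the target ends the entropy income, so the soft-optimal
policy learns to avoid terminating and evaluation success collapses after
an initially correct policy forms. Rewards therefore enter the replay
buffer multiplied by `reward_scale` (default 20), a standard SAC
adjustment that leaves the reward definitions untouched. Desk-scale runs
also use `gamma = 0.95`, matching the 10–30-step episode lengths of the
synthetic tasks.

The documented full protocol — 1e7 exploration steps with deterministic
evaluations of 80 episodes every 2.5e5 steps — is retained as the default
configuration; the validated desk-scale profile uses 2e4 steps on the
straight-vessel task and 6e3 steps on the fixed Y-tree task, with
evaluations of 12–20 episodes, sizes chosen so the full suite runs on one
CPU in well under half an hour. As in the original protocol, comparisons
between reward functions use each run's highest-success-rate checkpoint.

## What the validations show

- Reward transcription is exact to 1e-12 on randomized contexts, and the
  force-penalized/unpenalized difference depends only on ‖P‖.
- The critic's learned soft Q agrees with exact value iteration within
  0.05 on a two-state task at near-zero temperature.
- IRL on a 5×5 gridworld with shortest-path demonstrations recovers a
  reward whose induced soft-optimal policy matches the expert in ≥95 % of
  states (absorbing-goal, fixed-horizon formulation, so trajectory lengths
  are equal and the likelihood gradient is purely discriminative).
- The environment keeps every tracked point inside the lumen, maintains
  the 2 mm spacing, enforces the 200-step cap and 5 mm criterion, and is
  bitwise reproducible under fixed seeds.
- Scaled-down SAC with the dense reward solves the straight-trunk task
  (≥90 % deterministic success in at least 2 of 3 seeds at 2e4 steps).
- Across five paired seeds on a fixed Y-tree task, agents trained with the
  force-penalized dense reward show lower mean tip force than dense-only
  agents (one-sided paired t test) — the direction of the safety effect,
  with no claim about its magnitude on patient anatomy.

## Limitations

The planar geometry has a single bifurcation and cannot represent Circle
of Willis variants; the kinematic surrogate omits device mechanics, so
neither absolute forces nor procedure times are comparable to bench or
clinical values; the IRL background sampler at desk scale uses short
random rollouts rather than a converged soft policy; and the headline
performance numbers of the original system on patient-specific anatomy are
out of scope for this package's synthetic tasks.
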