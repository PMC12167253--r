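# endonav

Safe reinforcement learning for dual-device navigation in mechanical
thrombectomy (MT).

In the second stage of MT, a micro-guidewire and micro-catheter are steered
from a stable guide-catheter platform in the internal carotid artery (ICA)
to a clot site in the middle cerebral artery (MCA), rotating the curved
guidewire tip to avoid catheterizing the anterior cerebral artery. `endonav`
implements the learning method for automating this navigation while
accounting for vessel-wall contact forces, exercisable end to end on
synthetic planar vascular trees at desk scale:

- **Synthetic vasculature** — seeded generator of ICA-like trunks
  bifurcating into an MCA-like target branch and an ACA-like distractor,
  with left/right mirroring, 0.7–1.3 anisotropic scaling augmentation, and
  a line-oriented `.ctl.tsv` centerline format.
- **Navigation environment** — a kinematic follow-the-leader surrogate for
  the two devices with the task's published contract: 4-D actions
  (rotation/translation per device) clamped to 180 °/s and 40 mm/s,
  observations of three tracked points 2 mm apart per device (current and
  previous) plus target and previous action, a 5 mm success threshold, and
  a 200-step (≈27 s) timeout. A linear penetration proxy on the stiff tip
  segment supplies the contact-force magnitude ‖P‖.
- **Reward functions** — the six shaped rewards:

  R₁ = −0.005 − 0.001·Δpathlength + 1.0·[target reached]
  R₂ = the side-matched IRL-derived reward (R_RICA or R_LICA)
  R₃ = R₁ + α·R₂ with α = 0.001
  Rⱼ = Rⱼ₋₃ − 0.01·(‖P‖ − 0.85) for ‖P‖ > 0.85 N, j = 4, 5, 6

- **Maximum-entropy IRL** — per-branch reward models (four fully connected
  layers) learned from demonstrations recorded by a scripted
  centerline-following demonstrator; trajectory distribution
  ∝ exp(score/α) with α = 0.1 and a 0.01 per-step length penalty.
- **Recurrent Soft Actor-Critic** — LSTM state encoding, Gaussian μ/σ
  policy squashed to [−1, 1]⁴, twin soft Q-networks, episode replay with
  sequence chunks, auto-tuned entropy temperature; stochastic actions for
  exploration, deterministic μ for evaluation.
- **Evaluation** — success rate, procedure time (successes only), path
  ratio, and mean tip force, with paired two-tailed t tests and one-way
  ANOVA at p = 0.05.

## Worked example

```r
library(endonav)

tree <- generate_tree(tree_params(side = "right"), seed = 1)
tree
#> <centerline_tree> case_001 (right side), 255 nodes, seed 1
#>   trunk 60.5 mm, target branch 37.9 mm, distractor 28.2 mm

target <- sample_target(tree, seed = 2)
env <- nav_env(tree, target)
ep <- run_episode(env, oracle_policy, seed = 3)
ep$success; ep$steps; max(ep$forces)
#> [1] TRUE
#> [1] 18
#> [1] 0.317808
```

The scripted demonstrator reaches the mid-branch target in 18 steps
(≈2.4 s of simulated time at 0.135 s/step) with a peak tip force of
0.32 N, well below the 0.85 N penalty threshold.

Training a controller on the minimal straight-vessel task:

```r
tr <- straight_tree()
fac <- function(i) nav_env(tr, sample_target(tr, seed = i))
cfg <- sac_config(total_steps = 2e4, eval_every = 1e4, eval_episodes = 20,
                  update_every = 4, gamma = 0.95, seed = 1)
run <- train_sac(fac, "R1", cfg)
run$log[, 1:5]
#>    step success_rate procedure_time path_ratio mean_force
#> 1 10000          100         1.3095        100 0.20099241
#> 2 20000          100         1.3095        100 0.02021818
```

Both evaluations (20 deterministic episodes each) succeed on every episode;
the converged policy covers the ~55 mm course in about 1.3 s, and by the
second evaluation it has also learned to hold the tip off the wall (mean
force 0.02 N) even though the dense reward never penalizes contact.

A shell entry point wrapping these functions is installed at
`system.file("cli", "endonav", package = "endonav")`, with subcommands
`generate-vessels`, `record-demos`, `train-irl`, `train-rl` and `evaluate`.

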