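# The six reward functions. R1 is the dense shaping reward; R2 evaluates the
# side-matched IRL-derived reward model; R3 combines them with a small scale
# on the IRL term; R4-R6 add a guidewire tip-force penalty active above a
# force threshold, to the corresponding base reward.

#' Reward constants
#'
#' Defaults are the published constants of the method: per-step penalty
#' -0.005, pathlength coefficient -0.001 per mm, terminal bonus +1.0,
#' IRL scale alpha 0.001, tip-force threshold 0.85 N with slope 0.01 per N.
#' All are overridable for reward-weight tuning experiments.
#'
#' @param step_penalty Constant added every step.
#' @param pathlength_coeff Coefficient on the per-step change in
#'   tip-to-target pathlength (mm).
#' @param terminal_bonus Bonus on the step the target is reached.
#' @param irl_scale Scale `alpha` on the IRL reward inside the combined model.
#' @param force_threshold Tip-force magnitude (N) above which the penalty
#'   activates.
#' @param force_slope Penalty slope (per N above threshold).
#' @return A `reward_config` list.
#' @export
reward_config <- function(step_penalty = -0.005,
                          pathlength_coeff = -0.001,
                          terminal_bonus = 1.0,
                          irl_scale = 0.001,
                          force_threshold = 0.85,
                          force_slope = 0.01) {
  structure(list(step_penalty = step_penalty,
                 pathlength_coeff = pathlength_coeff,
                 terminal_bonus = terminal_bonus,
                 irl_scale = irl_scale,
                 force_threshold = force_threshold,
                 force_slope = force_slope),
            class = "reward_config")
}

#' Per-step reward context
#'
#' @param delta_pathlength Current minus previous tip-to-target pathlength
#'   (mm); progress toward the target is negative.
#' @param reached Whether the target was reached on this step.
#' @param force_magnitude Guidewire tip-force magnitude `||P||` (N).
#' @param observation Agent observation (list or numeric vector), consumed by
#'   the IRL reward models.
#' @param target_side `"left"` or `"right"`.
#' @return A `reward_context` list.
#' @export
reward_context <- function(delta_pathlength = 0, reached = FALSE,
                           force_magnitude = 0, observation = NULL,
                           target_side = "right") {
  if (force_magnitude < 0) stop("force_magnitude must be >= 0", call. = FALSE)
  structure(list(delta_pathlength = delta_pathlength, reached = reached,
                 force_magnitude = force_magnitude,
                 observation = observation, target_side = target_side),
            class = "reward_context")
}

#' Dense shaping reward (R1)
#'
#' `step_penalty + pathlength_coeff * delta_pathlength`, plus the terminal
#' bonus on the step the target is reached.
#'
#' @param ctx A [reward_context()].
#' @param cfg A [reward_config()].
#' @return Scalar reward.
#' @export
reward_dense <- function(ctx, cfg = reward_config()) {
  if (!is.finite(ctx$delta_pathlength)) {
    stop("delta_pathlength must be finite", call. = FALSE)
  }
  cfg$step_penalty + cfg$pathlength_coeff * ctx$delta_pathlength +
    if (isTRUE(ctx$reached)) cfg$terminal_bonus else 0
}

#' IRL-derived reward (R2)
#'
#' Evaluates the reward model ipsilateral to the target: the left-side model
#' for left-sided targets, the right-side model otherwise. The contralateral
#' model is never invoked.
#'
#' @param ctx A [reward_context()]; `target_side` selects the model.
#' @param models Named list with `left` and `right` IRL reward models (see
#'   [irl_reward()]).
#' @return Scalar reward.
#' @export
reward_irl <- function(ctx, models) {
  side <- ctx$target_side
  if (is.null(models[[side]])) {
    stop("no IRL reward model registered for side \"", side, "\"",
         call. = FALSE)
  }
  irl_reward(models[[side]], ctx$observation)
}

#' Combined reward (R3)
#'
#' `R1 + irl_scale * R2`.
#'
#' @inheritParams reward_irl
#' @param cfg A [reward_config()].
#' @return Scalar reward.
#' @export
reward_combined <- function(ctx, cfg = reward_config(), models) {
  reward_dense(ctx, cfg) + cfg$irl_scale * reward_irl(ctx, models)
}

#' Guidewire tip-force penalty
#'
#' Zero for `||P|| <= force_threshold`; otherwise
#' `-force_slope * (||P|| - force_threshold)`.
#'
#' @param force_magnitude Tip-force magnitude (N), non-negative.
#' @param cfg A [reward_config()].
#' @return Non-positive scalar.
#' @export
force_penalty <- function(force_magnitude, cfg = reward_config()) {
  if (any(force_magnitude < 0)) {
    stop("force_magnitude must be >= 0", call. = FALSE)
  }
  ifelse(force_magnitude > cfg$force_threshold,
         -cfg$force_slope * (force_magnitude - cfg$force_threshold), 0)
}

#' Force-penalized rewards (R4, R5, R6)
#'
#' Adds the tip-force penalty to the corresponding base reward: R4 = R1 +
#' penalty, R5 = R2 + penalty, R6 = R3 + penalty.
#'
#' @param base `"R1"`, `"R2"` or `"R3"`.
#' @inheritParams reward_combined
#' @return Scalar reward.
#' @export
reward_with_force <- function(base = c("R1", "R2", "R3"), ctx,
                              cfg = reward_config(), models = NULL) {
  base <- match.arg(base)
  b <- switch(base,
              R1 = reward_dense(ctx, cfg),
              R2 = reward_irl(ctx, models),
              R3 = reward_combined(ctx, cfg, models))
  b + force_penalty(ctx$force_magnitude, cfg)
}

#' Build a reward function by name
#'
#' @param name One of `"R1"` to `"R6"`.
#' @param cfg A [reward_config()].
#' @param models Per-side IRL models, required for R2/R3/R5/R6.
#' @return A function of a [reward_context()] returning a scalar.
#' @export
make_reward <- function(name, cfg = reward_config(), models = NULL) {
  name <- match.arg(name, paste0("R", 1:6))
  if (name %in% c("R2", "R3", "R5", "R6") && is.null(models)) {
    stop("reward ", name, " requires per-side IRL models", call. = FALSE)
  }
  switch(name,
         R1 = function(ctx) reward_dense(ctx, cfg),
         R2 = function(ctx) reward_irl(ctx, models),
         R3 = function(ctx) reward_combined(ctx, cfg, models),
         R4 = function(ctx) reward_with_force("R1", ctx, cfg),
         R5 = function(ctx) reward_with_force("R2", ctx, cfg, models),
         R6 = function(ctx) reward_with_force("R3", ctx, cfg, models))
}
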