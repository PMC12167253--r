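# Evaluation metrics: per-episode results and run-level summaries matching
# the reporting conventions of the method (success rate, procedure time on
# successful episodes, path ratio, mean tip force), plus the paired t-test /
# ANOVA comparisons.

#' Construct an episode result
#'
#' @param success Whether the target was reached.
#' @param steps Episode length in steps.
#' @param dt Seconds per step (procedure time = `steps * dt`, defined for
#'   successful episodes only).
#' @param initial_pathlength,final_pathlength Tip-to-target pathlength (mm)
#'   at episode start and end.
#' @param forces Per-step tip-force magnitudes (N).
#' @return An `episode_result` list with `mean_force` and `max_force`
#'   derived from `forces`.
#' @export
episode_result <- function(success, steps, dt, initial_pathlength,
                           final_pathlength, forces) {
  structure(list(success = success, steps = as.integer(steps),
                 procedure_time = if (success) steps * dt else NA_real_,
                 initial_pathlength = initial_pathlength,
                 final_pathlength = final_pathlength,
                 forces = forces,
                 mean_force = mean(forces), max_force = max(forces)),
            class = "episode_result")
}

#' Path ratio of an episode
#'
#' Percentage of the initial tip-to-target distance covered:
#' `100 * (initial - final) / initial`, clipped to `[0, 100]`; successful
#' episodes report 100.
#'
#' @param episode An [episode_result()].
#' @return Percentage in `[0, 100]`.
#' @export
path_ratio <- function(episode) {
  if (episode$initial_pathlength <= 0) {
    stop("degenerate episode: initial pathlength must be > 0", call. = FALSE)
  }
  if (episode$success) return(100)
  clamp(100 * (episode$initial_pathlength - episode$final_pathlength) /
          episode$initial_pathlength, 0, 100)
}

#' Summarize a set of evaluation episodes
#'
#' Success rate over all episodes (percent); procedure time mean +/- sd over
#' successful episodes; path ratio mean +/- sd over all episodes (successes
#' contribute 100); mean force over all steps of all episodes.
#'
#' @param episodes Non-empty list of [episode_result()] objects.
#' @param exploration_steps Optional training-step count recorded alongside.
#' @return A `run_summary` list.
#' @export
summarize_run <- function(episodes, exploration_steps = NA_integer_) {
  if (length(episodes) == 0L) stop("no episodes to summarize", call. = FALSE)
  succ <- vapply(episodes, function(e) e$success, logical(1))
  pt <- vapply(episodes, function(e) e$procedure_time, numeric(1))
  pr <- vapply(episodes, path_ratio, numeric(1))
  all_forces <- unlist(lapply(episodes, function(e) e$forces))
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  structure(list(
    n_episodes = length(episodes),
    success_rate = 100 * mean(succ),
    procedure_time_mean = if (any(succ)) mean(pt[succ]) else NA_real_,
    procedure_time_sd = if (any(succ)) sd0(pt[succ]) else NA_real_,
    path_ratio_mean = mean(pr), path_ratio_sd = sd0(pr),
    mean_force = mean(all_forces), mean_force_sd = sd0(all_forces),
    max_force = max(all_forces),
    exploration_steps = exploration_steps), class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<run_summary> %d episodes\n",
    "  success rate   %.1f %%\n",
    "  procedure time %.1f +/- %.1f s\n",
    "  path ratio     %.1f +/- %.1f %%\n",
    "  mean force     %.3f +/- %.3f N (max %.3f)\n"),
    x$n_episodes, x$success_rate,
    x$procedure_time_mean, x$procedure_time_sd,
    x$path_ratio_mean, x$path_ratio_sd,
    x$mean_force, x$mean_force_sd, x$max_force))
  invisible(x)
}

#' Compare per-episode metrics between runs
#'
#' Two groups: two-tailed Student's t test (paired when `paired = TRUE`).
#' More than two groups (pass a list in `a`, leave `b` `NULL`): one-way
#' ANOVA. Significance is flagged at p = 0.05.
#'
#' @param a Numeric vector, or a list of numeric vectors for ANOVA.
#' @param b Second numeric vector (two-group case).
#' @param paired Paired t test (vectors must have equal length).
#' @param alternative Test sidedness for the two-group case.
#' @return List with `statistic`, `p_value`, `significant`, `method`.
#' @export
compare_runs <- function(a, b = NULL, paired = FALSE,
                         alternative = "two.sided") {
  if (is.list(a) && is.null(b)) {
    values <- unlist(a)
    group <- factor(rep(seq_along(a), vapply(a, length, integer(1))))
    fit <- stats::anova(stats::aov(values ~ group))
    out <- list(statistic = fit[["F value"]][1L],
                p_value = fit[["Pr(>F)"]][1L], method = "one-way ANOVA")
  } else {
    if (paired && length(a) != length(b)) {
      stop("paired comparison requires equal-length samples", call. = FALSE)
    }
    if (paired && isTRUE(all.equal(a, b))) {
      # identical paired samples: zero variance of differences; t = 0, p = 1
      out <- list(statistic = 0, p_value = 1, method = "paired t-test")
    } else {
      tt <- stats::t.test(a, b, paired = paired, alternative = alternative)
      out <- list(statistic = unname(tt$statistic),
                  p_value = tt$p.value,
                  method = if (paired) "paired t-test" else "t-test")
    }
  }
  out$significant <- is.finite(out$p_value) && out$p_value < 0.05
  out
}

#' Evaluate a policy over a batch of episodes
#'
#' Runs `n_episodes` episodes under the given policy (deterministic for a
#' trained agent) across a factory of environments and returns the
#' per-episode results.
#'
#' @param env_factory Function `(episode_index) -> nav_env`, cycling trees
#'   and targets.
#' @param policy Function `(observation, env) -> action`.
#' @param n_episodes Number of evaluation episodes.
#' @param seed Base seed; episode `i` uses `seed + i`.
#' @return List of [episode_result()] objects.
#' @export
evaluate_policy <- function(env_factory, policy, n_episodes = 80L,
                            seed = 1L) {
  lapply(seq_len(n_episodes), function(i) {
    env <- env_factory(i)
    ep <- run_episode(env, policy, seed = seed + i)
    episode_result(ep$success, ep$steps, env$cfg$dt,
                   ep$initial_pathlength, ep$final_pathlength, ep$forces)
  })
}
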