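# Demonstration recording. A scripted, privileged centerline-following
# oracle stands in for the human keyboard demonstrator: it sees the tree,
# aligns the curved tip with the correct child branch before crossing the
# bifurcation, and pushes with a translation proportional to the remaining
# pathlength. Small seeded action noise emulates demonstrator variability so
# repeated navigations of one target differ.

# next junction ahead of the tip on the current route direction:
# returns list(arc, node) or NULL when no junction lies ahead
next_junction <- function(env) {
  is_j <- vapply(env$route, function(n) length(env$children[[n]]) > 1L,
                 logical(1))
  j <- which(is_j & env$route_arc > env$gw_len - 1e-9)
  if (length(j)) {
    return(list(arc = env$route_arc[j[1L]], node = env$route[j[1L]]))
  }
  # walk past the route end through single-child chains
  node <- env$route[length(env$route)]
  arc <- env$route_arc[length(env$route_arc)]
  repeat {
    kids <- env$children[[node]]
    if (length(kids) == 0L) return(NULL)
    if (length(kids) > 1L) return(list(arc = arc, node = node))
    arc <- arc + vnorm(env$tree$nodes[kids, ] - env$tree$nodes[node, ])
    node <- kids
  }
}

#' Scripted centerline-following demonstrator policy
#'
#' Privileged policy used to record demonstrations: translation is
#' proportional to the remaining pathlength (saturating at the speed limit);
#' approaching a bifurcation, the guidewire is rotated so its curved tip
#' aligns with the tangent of the child branch that shortens the distance to
#' the target, and translation pauses until aligned; a tip that has entered
#' the distractor branch is retracted below the bifurcation.
#'
#' @param obs Current `nav_observation` (unused; the oracle is privileged).
#' @param env The `nav_env` being navigated.
#' @return A 4-vector action in `[-1, 1]`.
#' @export
oracle_policy <- function(obs, env) {
  cfg <- env$cfg
  path <- env$pathlength
  a_trans <- clamp(path / (cfg$max_translation_speed * cfg$dt), 0.05, 1)
  a_rot <- 0

  tipb <- env$tree$branch[env$route[max(1L,
            min(findInterval(env$gw_len, env$route_arc),
                length(env$route)))]]
  jn <- next_junction(env)

  if (identical(tipb, "distractor_branch")) {
    a_trans <- -1   # wrong branch: retract below the bifurcation
  }
  # with no junction coming up, relax the tip back to neutral (curl out of
  # plane) so the stiff segment tracks the vessel course
  relax <- theta_err(env$gw_rot, 90)
  a_rot <- clamp(relax / (cfg$max_rotation_speed * cfg$dt), -1, 1)
  if (!is.null(jn) && (jn$arc - env$gw_len) < 15) {
    kids <- env$children[[jn$node]]
    best <- kids[which.min(env$dist_to_target[kids])]
    # tangent of the trunk just below the junction
    below <- route_point(env, jn$arc - 1)
    rels <- vapply(kids, function(k) {
      signed_angle(below$tangent,
                   unit(env$tree$nodes[k, ] - env$tree$nodes[jn$node, ]))
    }, numeric(1))
    rel_best <- rels[kids == best][1L]
    # curl only as far past the decision boundary as needed: the alignment
    # rule picks the correct child once the deflection clears the midpoint
    # between the child directions, and a shallower curl presses the stiff
    # tip less into the branch wall after entry
    rel <- if (length(kids) > 1L) {
      mid <- (rel_best + mean(rels[kids != best])) / 2
      mid + 0.5 * (rel_best - mid)
    } else rel_best
    # curl in gradually on approach: a full curl far from the ostium would
    # press the stiff tip segment into the trunk wall
    gap <- jn$arc - env$gw_len
    ramp <- clamp(1 - (gap - 1) / 6, 0, 1)
    delta_star <- clamp(ramp * rel / (cfg$tip_curve_angle * pi / 180), -1, 1)
    theta_star <- acos(delta_star) * 180 / pi   # in [0, 180]
    err <- theta_err(env$gw_rot, theta_star)
    a_rot <- clamp(err / (cfg$max_rotation_speed * cfg$dt), -1, 1)
    if (gap < 10 && a_trans > 0) {
      a_trans <- min(a_trans, 0.25)   # creep toward the ostium
      if (abs(err) > 10 && gap < 4) a_trans <- 0
    }
  }
  a_cath <- clamp((env$gw_len - 4 - env$cath_len) /
                    (cfg$max_translation_speed * cfg$dt), -1, 1)
  c(a_rot, a_trans, 0, a_cath)
}

# smallest signed rotation (deg) taking `theta` to `target` or to `-target`
# (the tip deflection is even in the axial angle)
theta_err <- function(theta, target) {
  cand <- c(target, -target)
  d <- ((cand - theta + 180) %% 360) - 180
  d[which.min(abs(d))]
}

noisy_policy <- function(policy, sd) {
  function(obs, env) clamp(policy(obs, env) + stats::rnorm(4, 0, sd), -1, 1)
}

#' Record demonstration trajectories
#'
#' Follows the demonstration protocol: per vasculature, `targets_per_branch`
#' random targets on its target branch, navigated
#' `navigations_per_case / targets_per_branch` times each (default 2 targets
#' x 2 repeats = 4 navigations per case; 10 cases give 40 demonstrations).
#' Deterministic under `seed`. Timed-out navigations are kept but flagged
#' with outcome `"timeout"` and a warning; IRL training excludes them.
#'
#' @param trees List of `centerline_tree` objects.
#' @param targets_per_branch Targets sampled per case.
#' @param navigations_per_case Total navigations per case (a multiple of
#'   `targets_per_branch`).
#' @param seed Master seed.
#' @param cfg An [env_config()].
#' @param noise_sd Demonstrator action noise (0 for the exact oracle).
#' @return List of `demonstration` objects.
#' @export
record_demos <- function(trees, targets_per_branch = 2L,
                         navigations_per_case = 4L, seed = 1L,
                         cfg = env_config(), noise_sd = 0.05) {
  stopifnot(navigations_per_case %% targets_per_branch == 0L)
  repeats <- navigations_per_case %/% targets_per_branch
  demos <- list()
  for (ci in seq_along(trees)) {
    tree <- trees[[ci]]
    tseeds <- seed * 131L + ci * 17L + seq_len(targets_per_branch)
    # distinct candidate targets per case
    idx <- with_seed(seed * 97L + ci,
                     sample.int(10L, targets_per_branch))
    for (ti in seq_len(targets_per_branch)) {
      cand <- target_candidates(tree, 10L)
      target <- structure(list(position = tree$nodes[cand[idx[ti]], ],
                               branch_side = tree$side,
                               centerline_index = idx[ti] - 1L,
                               node = cand[idx[ti]]),
                          class = "target_spec")
      for (r in seq_len(repeats)) {
        ep_seed <- (tseeds[ti] * 31L + r) %% 2147483647L
        env <- nav_env(tree, target, cfg)
        ep <- with_seed(ep_seed, {
          run_episode(env, noisy_policy(oracle_policy, noise_sd),
                      seed = ep_seed, record = TRUE)
        })
        if (!ep$success) {
          warning("demonstration timed out (case ", tree$case_id,
                  ", target ", idx[ti] - 1L, ", repeat ", r, ")")
        }
        demos[[length(demos) + 1L]] <- structure(
          list(case_id = tree$case_id, side = tree$side, target = target,
               outcome = if (ep$success) "success" else "timeout",
               seed = ep_seed, trace = ep$trace),
          class = "demonstration")
      }
    }
  }
  demos
}

#' Partition demonstrations by target side
#'
#' @param demos List of `demonstration` objects.
#' @return List with `left` and `right` demonstration lists (full coverage,
#'   no overlap).
#' @export
split_by_side <- function(demos) {
  stopifnot(length(demos) > 0L)
  sides <- vapply(demos, function(d) d$side, character(1))
  list(left = demos[sides == "left"], right = demos[sides == "right"])
}

#' Write a demonstration to a `.demo.tsv` file
#'
#' Columnar TSV with a JSON header line (prefixed `#`); fixed numeric
#' formatting makes write/read round-trips byte-identical.
#'
#' @param demo A `demonstration`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_demo <- function(demo, path) {
  meta <- list(schema = 1L, case_id = demo$case_id, side = demo$side,
               outcome = demo$outcome, seed = demo$seed,
               target = list(x = demo$target$position[1],
                             y = demo$target$position[2],
                             centerline_index = demo$target$centerline_index,
                             node = demo$target$node))
  hdr <- paste0("#", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = 10))
  cols <- c("step", paste0("a", 1:4),
            paste0("gw", rep(1:3, each = 2), c("x", "y")),
            paste0("ca", rep(1:3, each = 2), c("x", "y")), "force")
  rows <- vapply(seq_along(demo$trace), function(i) {
    s <- demo$trace[[i]]
    paste(c(i, fmt_num(c(s$action, t(s$gw), t(s$cath), s$force))),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, paste(cols, collapse = "\t"), rows), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read a demonstration written by [write_demo()]
#'
#' @param path `.demo.tsv` file path.
#' @return A `demonstration`.
#' @export
read_demo <- function(path) {
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(sub("^#", "", lines[1L]))
  df <- utils::read.delim(text = lines[-1L])
  trace <- lapply(seq_len(nrow(df)), function(i) {
    list(action = as.numeric(df[i, paste0("a", 1:4)]),
         gw = matrix(as.numeric(df[i, 6:11]), 3, 2, byrow = TRUE),
         cath = matrix(as.numeric(df[i, 12:17]), 3, 2, byrow = TRUE),
         force = df$force[i])
  })
  structure(
    list(case_id = meta$case_id, side = meta$side,
         target = structure(list(position = c(meta$target$x, meta$target$y),
                                 branch_side = meta$side,
                                 centerline_index = meta$target$centerline_index,
                                 node = meta$target$node),
                            class = "target_spec"),
         outcome = meta$outcome, seed = meta$seed, trace = trace),
    class = "demonstration")
}
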