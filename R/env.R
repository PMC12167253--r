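# Two-device navigation environment.
#
# The finite-element beam mechanics of the original simulator are replaced
# by a follow-the-leader kinematic surrogate: the device body occupies the
# centerline route from the insertion root to the tip; translation advances
# or retracts the tip along the route; the curved guidewire tip, mapped into
# the plane by axial rotation, selects the child branch whose tangent best
# aligns with it at bifurcations; a linear penetration proxy on the
# unconstrained tip provides the wall-contact force. The agent sees only 2-D
# tracked points, the target, and its previous action.

#' Environment configuration
#'
#' Defaults are the task's published operating limits: rotation up to
#' 180 deg/s and translation up to 40 mm/s, a 5 mm success threshold, a
#' 200-step timeout at dt = 27 s / 200 = 0.135 s, and three tracked points
#' spaced 2 mm apart per device.
#'
#' @param dt Seconds of simulated time per step.
#' @param max_rotation_speed Degrees per second at action +/-1.
#' @param max_translation_speed mm per second at action +/-1.
#' @param success_threshold Euclidean tip-to-target distance (mm) counting as
#'   target reached.
#' @param timeout_steps Episode truncation limit.
#' @param tracked_point_spacing Arc-length spacing of tracked points (mm).
#' @param n_tracked_points Tracked points per device.
#' @param wall_stiffness Force proxy coefficient (N per mm of penetration of
#'   the unconstrained tip beyond the lumen wall).
#' @param guidewire_stiffness,catheter_stiffness Relative bend resistance of
#'   the two devices (Young's-modulus-informed ratio; informational in the
#'   kinematic surrogate).
#' @param tip_curve_angle Fixed curvature angle of the guidewire tip
#'   (degrees); axial rotation maps it into the plane as
#'   `tip_curve_angle * cos(rotation)`.
#' @param tip_lookahead Length (mm) of the stiff distal tip segment whose
#'   unconstrained endpoint drives the force proxy; calibrated together
#'   with `wall_stiffness` so the scripted demonstrator stays at or below
#'   0.80 N while badly steered navigation peaks near 1 N.
#' @param initial_insertion Guidewire insertion depth at reset (mm),
#'   representing the stable guide-catheter platform at the trunk root.
#' @param pathlength_metric `"centerline"` (default) or `"euclidean"`.
#' @return An `env_config` list.
#' @export
env_config <- function(dt = 0.135,
                       max_rotation_speed = 180,
                       max_translation_speed = 40,
                       success_threshold = 5,
                       timeout_steps = 200L,
                       tracked_point_spacing = 2,
                       n_tracked_points = 3L,
                       wall_stiffness = 0.35,
                       guidewire_stiffness = 47,
                       catheter_stiffness = 43,
                       tip_curve_angle = 45,
                       tip_lookahead = 6,
                       initial_insertion = 5,
                       pathlength_metric = c("centerline", "euclidean")) {
  for (f in c("dt", "max_rotation_speed", "max_translation_speed",
              "success_threshold", "timeout_steps", "tracked_point_spacing",
              "wall_stiffness", "tip_lookahead", "initial_insertion")) {
    check_positive(get(f), f)
  }
  structure(list(dt = dt, max_rotation_speed = max_rotation_speed,
                 max_translation_speed = max_translation_speed,
                 success_threshold = success_threshold,
                 timeout_steps = as.integer(timeout_steps),
                 tracked_point_spacing = tracked_point_spacing,
                 n_tracked_points = as.integer(n_tracked_points),
                 wall_stiffness = wall_stiffness,
                 guidewire_stiffness = guidewire_stiffness,
                 catheter_stiffness = catheter_stiffness,
                 tip_curve_angle = tip_curve_angle,
                 tip_lookahead = tip_lookahead,
                 initial_insertion = initial_insertion,
                 pathlength_metric = match.arg(pathlength_metric)),
            class = "env_config")
}

#' Read an environment configuration from a YAML file
#'
#' Any subset of [env_config()] fields may be given; the rest keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return An `env_config`.
#' @export
env_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(env_config, vals)
}

#' Create a navigation environment
#'
#' @param tree A `centerline_tree`.
#' @param target A `target_spec` from [sample_target()]; its side must match
#'   the tree side.
#' @param cfg An [env_config()].
#' @return A `nav_env` object; call [env_reset()] before stepping.
#' @export
nav_env <- function(tree, target, cfg = env_config()) {
  validate_tree(tree)
  if (!identical(target$branch_side, tree$side)) {
    stop("target side (", target$branch_side,
         ") does not match tree side (", tree$side, ")", call. = FALSE)
  }
  e <- new.env(parent = emptyenv())
  e$tree <- tree
  e$target <- target
  e$cfg <- cfg
  e$children <- tree_children(tree)
  e$dist_to_target <- node_distances(tree, target$node)
  e$root <- which(tree$parent == 0L)
  e$done <- TRUE   # must reset first
  class(e) <- "nav_env"
  e
}

#' @export
print.nav_env <- function(x, ...) {
  cat(sprintf("<nav_env> %s (%s side), target index %d, step %s\n",
              x$tree$case_id, x$tree$side, x$target$centerline_index,
              if (isTRUE(x$done)) "terminal/unreset" else x$step_index))
  invisible(x)
}

# position/tangent/pathlength at arc position s along the current route
route_point <- function(e, s) {
  arc <- e$route_arc
  i <- max(1L, min(findInterval(s, arc), length(arc) - 1L))
  w <- (s - arc[i]) / max(arc[i + 1L] - arc[i], 1e-12)
  w <- clamp(w, 0, 1)
  a <- e$tree$nodes[e$route[i], ]
  b <- e$tree$nodes[e$route[i + 1L], ]
  list(pos = a * (1 - w) + b * w,
       tangent = unit(b - a),
       dist = e$dist_to_target[e$route[i]] * (1 - w) +
         e$dist_to_target[e$route[i + 1L]] * w)
}

# effective in-plane deflection (radians) of the curved guidewire tip at
# axial rotation `theta` (degrees)
tip_deflection <- function(e, theta) {
  e$cfg$tip_curve_angle * pi / 180 * cos(theta * pi / 180)
}

# extend the route past junctions (choosing by tip alignment) so that it
# covers arc position s; clamp s at a leaf
extend_route <- function(e, s) {
  repeat {
    arc_end <- e$route_arc[length(e$route_arc)]
    if (s <= arc_end + 1e-12) return(s)
    last <- e$route[length(e$route)]
    kids <- e$children[[last]]
    if (length(kids) == 0L) return(arc_end)   # vessel end: tip stops
    nxt <- if (length(kids) == 1L) kids else {
      prev <- e$route[length(e$route) - 1L]
      tangent <- unit(e$tree$nodes[last, ] - e$tree$nodes[prev, ])
      delta <- tip_deflection(e, e$gw_rot)
      rel <- vapply(kids, function(k) {
        signed_angle(tangent, unit(e$tree$nodes[k, ] - e$tree$nodes[last, ]))
      }, numeric(1))
      kids[which.min(abs(rel - delta))]
    }
    e$route <- c(e$route, nxt)
    e$route_arc <- c(e$route_arc,
                     e$route_arc[length(e$route_arc)] +
                       vnorm(e$tree$nodes[nxt, ] - e$tree$nodes[last, ]))
  }
}

# drop committed branch choices the tip has retracted below
truncate_route <- function(e, s) {
  if (length(e$route) < 3L) return(invisible())
  is_junction <- vapply(e$route, function(n) length(e$children[[n]]) > 1L,
                        logical(1))
  j <- which(is_junction & e$route_arc > s + 1e-9)
  if (length(j) && j[1L] < length(e$route)) {
    keep <- seq_len(j[1L])
    e$route <- e$route[keep]
    e$route_arc <- e$route_arc[keep]
  }
  invisible()
}

#' Tracked points along a device
#'
#' Returns `n_tracked_points` points on the device body, the first at the
#' tip and the rest spaced `tracked_point_spacing` mm behind it in arc
#' length; a device shorter than the span is padded with the insertion
#' point.
#'
#' @param env A reset `nav_env`.
#' @param device `"guidewire"` or `"catheter"`.
#' @return A `n_tracked_points` x 2 matrix (mm), tip first.
#' @export
track_points <- function(env, device = c("guidewire", "catheter")) {
  device <- match.arg(device)
  len <- if (device == "guidewire") env$gw_len else env$cath_len
  s <- len - (seq_len(env$cfg$n_tracked_points) - 1L) *
    env$cfg$tracked_point_spacing
  t(vapply(pmax(s, 0), function(si) route_point(env, si)$pos, numeric(2)))
}

#' Guidewire tip contact-force proxy
#'
#' The unconstrained tip — the tip advanced `tip_lookahead` mm along the
#' deflected tip direction — is tested against the lumen: penetration depth
#' beyond the local radius, times `wall_stiffness`, directed along the
#' inward wall normal. Zero when the unconstrained tip stays inside the
#' lumen.
#'
#' @param env A reset `nav_env`.
#' @return Length-2 force vector (N); magnitude `sqrt(sum(P^2))`.
#' @export
compute_tip_force <- function(env) {
  tp <- route_point(env, env$gw_len)
  dir <- rotate2(tp$tangent, tip_deflection(env, env$gw_rot))
  p_la <- tp$pos + dir * env$cfg$tip_lookahead
  nn <- nearest_node(env$tree, p_la)
  near <- env$tree$nodes[nn, ]
  if (length(env$children[[nn]]) == 0L) {
    # leaf: the vasculature continues distally, so treat the lumen as
    # extending along the terminal tangent rather than as an end wall
    tang <- unit(near - env$tree$nodes[env$tree$parent[nn], ])
    along <- sum((p_la - near) * tang)
    if (along > 0) near <- near + along * tang
  }
  d <- vnorm(p_la - near)
  pen <- max(0, d - env$tree$radius[nn])
  if (pen == 0) return(c(0, 0))
  env$cfg$wall_stiffness * pen * unit(near - p_la)
}

build_observation <- function(e) {
  gw <- track_points(e, "guidewire")
  ca <- track_points(e, "catheter")
  structure(list(gw_now = gw, cath_now = ca,
                 gw_prev = e$prev_gw, cath_prev = e$prev_cath,
                 target = e$target$position,
                 prev_action = e$prev_action),
            class = "nav_observation")
}

#' Flatten an observation to the agent-facing numeric vector
#'
#' Layout: current guidewire points (x1,y1,...,x3,y3), current catheter
#' points, previous guidewire points, previous catheter points, target
#' (x,y), previous action (4). Length 30 with the default configuration.
#'
#' @param obs A `nav_observation`.
#' @return Numeric vector.
#' @export
obs_vector <- function(obs) {
  c(t(obs$gw_now), t(obs$cath_now), t(obs$gw_prev), t(obs$cath_prev),
    obs$target, obs$prev_action)
}

#' Reset the environment
#'
#' Devices are initialized at the trunk root (the stable guide-catheter
#' platform), the step counter is zeroed, and the first observation
#' duplicates current positions as "previous".
#'
#' @param env A `nav_env`.
#' @param seed Integer seed (the surrogate dynamics are deterministic; the
#'   seed is stored for contract compatibility and future stochastic terms).
#' @return The initial `nav_observation`.
#' @export
env_reset <- function(env, seed = 1L) {
  env$seed <- as.integer(seed)
  env$gw_len <- env$cfg$initial_insertion
  env$cath_len <- max(env$cfg$initial_insertion - 2, 0.5)
  env$gw_rot <- 90    # tip curve out of plane: no in-plane deflection
  env$cath_rot <- 90
  env$route <- env$root
  kid <- env$children[[env$root]]
  env$route <- c(env$root, kid[1L])
  env$route_arc <- c(0, vnorm(env$tree$nodes[kid[1L], ] -
                                env$tree$nodes[env$root, ]))
  env$gw_len <- extend_route(env, env$gw_len)
  env$step_index <- 0L
  env$done <- FALSE
  env$prev_action <- rep(0, 4)
  env$prev_gw <- track_points(env, "guidewire")
  env$prev_cath <- track_points(env, "catheter")
  env$pathlength <- route_point(env, env$gw_len)$dist
  if (env$cfg$pathlength_metric == "euclidean") {
    env$pathlength <- vnorm(route_point(env, env$gw_len)$pos -
                              env$target$position)
  }
  build_observation(env)
}

#' Advance the environment by one action
#'
#' The 4-vector action (guidewire rotation, guidewire translation, catheter
#' rotation, catheter translation), each in `[-1, 1]`, maps linearly to the
#' configured speed limits and is integrated over `dt`. The episode
#' terminates with `reached` when the Euclidean tip-to-target distance drops
#' to `success_threshold` or below, and truncates at `timeout_steps`.
#'
#' @param env A reset `nav_env`.
#' @param action Numeric length-4 vector; non-finite values are rejected.
#' @return A `step_result`: `observation`, `tip_force` (vector),
#'   `force_magnitude`, `reached`, `truncated`, `step_index`, and `info`
#'   with `pathlength`, `delta_pathlength` and the applied speeds.
#' @export
env_step <- function(env, action) {
  if (isTRUE(env$done)) {
    stop("env_step() called on a terminated episode; call env_reset()",
         call. = FALSE)
  }
  if (length(action) != 4L || any(!is.finite(action))) {
    stop("action must be a finite numeric 4-vector", call. = FALSE)
  }
  a <- clamp(action, -1, 1)
  cfg <- env$cfg
  rot_speed <- a[c(1, 3)] * cfg$max_rotation_speed     # deg/s
  trans_speed <- a[c(2, 4)] * cfg$max_translation_speed  # mm/s

  prev_gw <- track_points(env, "guidewire")
  prev_cath <- track_points(env, "catheter")
  prev_path <- env$pathlength

  env$gw_rot <- (env$gw_rot + rot_speed[1] * cfg$dt) %% 360
  env$cath_rot <- (env$cath_rot + rot_speed[2] * cfg$dt) %% 360
  new_len <- max(env$gw_len + trans_speed[1] * cfg$dt, 1)
  truncate_route(env, new_len)
  env$gw_len <- extend_route(env, new_len)
  env$cath_len <- clamp(env$cath_len + trans_speed[2] * cfg$dt,
                        0.5, env$gw_len)

  tp <- route_point(env, env$gw_len)
  env$pathlength <- if (cfg$pathlength_metric == "euclidean") {
    vnorm(tp$pos - env$target$position)
  } else tp$dist
  delta <- env$pathlength - prev_path

  force <- compute_tip_force(env)
  env$step_index <- env$step_index + 1L
  reached <- vnorm(tp$pos - env$target$position) <= cfg$success_threshold
  truncated <- !reached && env$step_index >= cfg$timeout_steps
  env$done <- reached || truncated

  env$prev_gw <- prev_gw
  env$prev_cath <- prev_cath
  env$prev_action <- a
  structure(list(observation = build_observation(env),
                 tip_force = force,
                 force_magnitude = vnorm(force),
                 reached = reached, truncated = truncated,
                 step_index = env$step_index,
                 info = list(pathlength = env$pathlength,
                             delta_pathlength = delta,
                             rotation_speed = rot_speed,
                             translation_speed = trans_speed)),
            class = "step_result")
}

#' Run one episode under a policy function
#'
#' @param env A `nav_env`.
#' @param policy Function `(observation, env) -> action` (the privileged
#'   oracle ignores neither argument; learned policies use only the
#'   observation).
#' @param seed Seed passed to [env_reset()].
#' @param reward_fn Optional function of a [reward_context()]; per-step
#'   rewards are recorded when given.
#' @param record Keep per-step actions/tracked points/forces (used by the
#'   demonstration recorder).
#' @return List with `success`, `steps`, `initial_pathlength`,
#'   `final_pathlength`, `forces`, `rewards`, and (if `record`) `trace`.
#' @export
run_episode <- function(env, policy, seed = 1L, reward_fn = NULL,
                        record = FALSE) {
  obs <- env_reset(env, seed)
  initial <- env$pathlength
  forces <- numeric(0)
  rewards <- numeric(0)
  trace <- if (record) list() else NULL
  success <- FALSE
  repeat {
    action <- policy(obs, env)
    res <- env_step(env, action)
    forces <- c(forces, res$force_magnitude)
    if (!is.null(reward_fn)) {
      ctx <- reward_context(delta_pathlength = res$info$delta_pathlength,
                            reached = res$reached,
                            force_magnitude = res$force_magnitude,
                            observation = obs_vector(res$observation),
                            target_side = env$target$branch_side)
      rewards <- c(rewards, reward_fn(ctx))
    }
    if (record) {
      trace[[length(trace) + 1L]] <- list(
        action = action,
        gw = res$observation$gw_now, cath = res$observation$cath_now,
        force = res$force_magnitude)
    }
    obs <- res$observation
    if (res$reached) { success <- TRUE; break }
    if (res$truncated) break
  }
  list(success = success, steps = env$step_index,
       initial_pathlength = initial, final_pathlength = env$pathlength,
       forces = forces, rewards = rewards, trace = trace)
}
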