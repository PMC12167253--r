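# Synthetic planar vascular trees.
#
# A tree emulates the vessel course relevant to the second stage of
# mechanical thrombectomy: an ICA-like trunk (tortuous cervical/petrous
# course) that bifurcates into an MCA-like target branch and an ACA-like
# distractor branch. Geometry is planar (mm), matching the 2-D tracking
# coordinates the controller observes; one side (left/right) per tree, with
# left cases generated as mirror images of the right-side parameterization.

RESAMPLE_STEP <- 0.5  # mm between consecutive centerline nodes

#' Default shape parameters for the synthetic vascular tree generator
#'
#' Lengths and radii are in mm, angles in degrees. Defaults approximate the
#' distal ICA trunk with its tortuous course, an M1-like target branch and an
#' A1-like distractor branch at the carotid terminus.
#'
#' @param trunk_length Arc length of the ICA-like trunk.
#' @param tortuosity_amplitude Lateral amplitude of the trunk's sinusoidal
#'   tortuosity (0 gives a straight trunk).
#' @param tortuosity_frequency Number of tortuosity cycles along the trunk.
#' @param bifurcation_angle Total opening angle between the two child
#'   branches at the carotid terminus, in (0, 180).
#' @param target_branch_length,distractor_branch_length Arc lengths of the
#'   MCA-like and ACA-like branches.
#' @param trunk_radius,target_branch_radius,distractor_branch_radius Lumen
#'   radii.
#' @param target_branch_turn,distractor_branch_turn Gentle in-branch curvature
#'   (total heading change along each branch, degrees).
#' @param side `"left"` or `"right"`; left trees mirror the right-side
#'   parameterization.
#' @param jitter Relative jitter (fraction) applied to lengths and angles by
#'   the seeded generator, emulating across-patient variability.
#' @return A named list of parameters for [generate_tree()].
#' @export
tree_params <- function(trunk_length = 60,
                        tortuosity_amplitude = 4,
                        tortuosity_frequency = 1.5,
                        bifurcation_angle = 75,
                        target_branch_length = 35,
                        distractor_branch_length = 30,
                        trunk_radius = 2.0,
                        target_branch_radius = 1.3,
                        distractor_branch_radius = 1.1,
                        target_branch_turn = 15,
                        distractor_branch_turn = -10,
                        side = "right",
                        jitter = 0.1) {
  list(trunk_length = trunk_length,
       tortuosity_amplitude = tortuosity_amplitude,
       tortuosity_frequency = tortuosity_frequency,
       bifurcation_angle = bifurcation_angle,
       target_branch_length = target_branch_length,
       distractor_branch_length = distractor_branch_length,
       trunk_radius = trunk_radius,
       target_branch_radius = target_branch_radius,
       distractor_branch_radius = distractor_branch_radius,
       target_branch_turn = target_branch_turn,
       distractor_branch_turn = distractor_branch_turn,
       side = side,
       jitter = jitter)
}

check_tree_params <- function(p) {
  for (f in c("trunk_length", "target_branch_length",
              "distractor_branch_length", "trunk_radius",
              "target_branch_radius", "distractor_branch_radius")) {
    check_positive(p[[f]], f)
  }
  if (p$tortuosity_amplitude < 0) {
    stop("parameter `tortuosity_amplitude` must be >= 0", call. = FALSE)
  }
  if (p$bifurcation_angle <= 0 || p$bifurcation_angle >= 180) {
    stop("parameter `bifurcation_angle` must lie in (0, 180) degrees",
         call. = FALSE)
  }
  if (!p$side %in% c("left", "right")) {
    stop("parameter `side` must be \"left\" or \"right\"", call. = FALSE)
  }
  invisible(p)
}

# Resample a polyline to (approximately) equal arc-length spacing `step`,
# keeping the exact endpoints.
resample_polyline <- function(pts, step = RESAMPLE_STEP) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  n_out <- max(2L, ceiling(total / step) + 1L)
  s_out <- seq(0, total, length.out = n_out)
  cbind(stats::approx(arc, pts[, 1], xout = s_out, ties = "ordered")$y,
        stats::approx(arc, pts[, 2], xout = s_out, ties = "ordered")$y)
}

# Dense polyline for one branch: start point, initial heading (unit vector),
# arc length, total in-path turn (deg), optional sinusoidal wiggle.
trace_branch <- function(start, heading, length, turn_deg,
                         wiggle_amp = 0, wiggle_freq = 0, phase = 0,
                         n_dense = 200L) {
  s <- seq(0, length, length.out = n_dense)
  ds <- s[2] - s[1]
  theta0 <- atan2(heading[2], heading[1])
  # heading angle varies linearly along the arc (constant curvature) plus a
  # sinusoidal tortuosity term
  theta <- theta0 + (turn_deg * pi / 180) * (s / length) +
    if (wiggle_amp > 0) {
      (wiggle_amp * pi / 180) * sin(2 * pi * wiggle_freq * s / length + phase)
    } else 0
  x <- start[1] + c(0, cumsum(cos(theta[-1]) * ds))
  y <- start[2] + c(0, cumsum(sin(theta[-1]) * ds))
  cbind(x, y)
}

#' Generate a synthetic vascular tree
#'
#' Deterministic in `(params, seed)`: the seed drives across-patient jitter
#' of lengths, angles and tortuosity phase.
#'
#' @param params Parameter list from [tree_params()].
#' @param seed Integer seed.
#' @param case_id Case identifier stored on the tree.
#' @return A `centerline_tree`: nodes (n x 2, mm), integer `parent`
#'   (0 for the root), per-node `radius` (mm), per-node `branch` label
#'   (`trunk`, `target_branch`, `distractor_branch`), `side`, `case_id`,
#'   `seed`, `params`.
#' @export
generate_tree <- function(params = tree_params(), seed = 1L,
                          case_id = sprintf("case_%03d", seed)) {
  p <- check_tree_params(params)
  with_seed(seed, {
    j <- function(x) x * stats::runif(1, 1 - p$jitter, 1 + p$jitter)
    trunk_len <- j(p$trunk_length)
    phase <- stats::runif(1, 0, 2 * pi)

    # Trunk: base course along +y with a sinusoidal lateral offset that
    # vanishes at both ends (stable guide-catheter platform at the root,
    # clean bifurcation at the terminus).
    s <- seq(0, trunk_len, length.out = 240L)
    lateral <- p$tortuosity_amplitude *
      sin(2 * pi * p$tortuosity_frequency * s / trunk_len + phase) *
      sin(pi * s / trunk_len)
    if (p$tortuosity_amplitude == 0) lateral <- rep(0, length(s))
    trunk_dense <- cbind(lateral, s)
    trunk <- resample_polyline(trunk_dense)

    end <- trunk[nrow(trunk), ]
    tangent <- unit(trunk[nrow(trunk), ] - trunk[nrow(trunk) - 1L, ])

    ang <- j(p$bifurcation_angle)
    # MCA-like branch heads laterally (+x side of the trunk tangent for the
    # canonical right-side tree), ACA-like branch toward the midline.
    a_target <- -0.6 * ang * pi / 180
    a_distract <- +0.4 * ang * pi / 180

    tgt_dense <- trace_branch(end, rotate2(tangent, a_target),
                              j(p$target_branch_length),
                              p$target_branch_turn,
                              wiggle_amp = 5, wiggle_freq = 1, phase = phase)
    dis_dense <- trace_branch(end, rotate2(tangent, a_distract),
                              j(p$distractor_branch_length),
                              p$distractor_branch_turn,
                              wiggle_amp = 4, wiggle_freq = 1, phase = -phase)
    tgt <- resample_polyline(tgt_dense)
    dis <- resample_polyline(dis_dense)

    n_trunk <- nrow(trunk)
    n_tgt <- nrow(tgt) - 1L   # first branch point coincides with trunk end
    n_dis <- nrow(dis) - 1L
    nodes <- rbind(trunk, tgt[-1L, , drop = FALSE], dis[-1L, , drop = FALSE])
    parent <- c(0L, seq_len(n_trunk - 1L),
                c(n_trunk, n_trunk + seq_len(n_tgt - 1L)),
                c(n_trunk, n_trunk + n_tgt + seq_len(n_dis - 1L)))
    radius <- c(seq(p$trunk_radius, 0.85 * p$trunk_radius,
                    length.out = n_trunk),
                rep(p$target_branch_radius, n_tgt),
                rep(p$distractor_branch_radius, n_dis))
    branch <- c(rep("trunk", n_trunk),
                rep("target_branch", n_tgt),
                rep("distractor_branch", n_dis))
    if (p$side == "left") nodes[, 1] <- -nodes[, 1]

    tree <- structure(
      list(nodes = unname(nodes), parent = as.integer(parent),
           radius = radius, branch = branch, side = p$side,
           case_id = case_id, seed = as.integer(seed), params = p),
      class = "centerline_tree")
    validate_tree(tree)
    tree
  })
}

#' Degenerate straight single-branch tree
#'
#' A straight trunk continuing into a collinear target branch, with no
#' distractor: the minimal navigation task (translation only, no branch
#' selection), used for scaled-down convergence runs and as a geometric
#' ground-truth case.
#'
#' @param trunk_length,branch_length Segment lengths (mm).
#' @param radius Lumen radius (mm).
#' @param side Side tag.
#' @return A `centerline_tree`.
#' @export
straight_tree <- function(trunk_length = 40, branch_length = 30,
                          radius = 2, side = "right") {
  pts <- resample_polyline(cbind(0, c(0, trunk_length + branch_length)))
  n <- nrow(pts)
  n_trunk <- sum(pts[, 2] <= trunk_length)
  tree <- structure(
    list(nodes = unname(pts), parent = c(0L, seq_len(n - 1L)),
         radius = rep(radius, n),
         branch = c(rep("trunk", n_trunk),
                    rep("target_branch", n - n_trunk)),
         side = side, case_id = "straight", seed = 0L,
         params = list(trunk_length = trunk_length,
                       branch_length = branch_length, radius = radius)),
    class = "centerline_tree")
  validate_tree(tree)
  tree
}

#' Validate the structural invariants of a centerline tree
#'
#' Checks: single root, acyclic parent indexing, positive radii, consecutive
#' nodes at most 1 mm apart, and exactly one contiguous target branch.
#'
#' @param tree A `centerline_tree`.
#' @return The tree, invisibly; errors describe the violated invariant.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "centerline_tree"))
  n <- nrow(tree$nodes)
  if (sum(tree$parent == 0L) != 1L) stop("tree must have exactly one root")
  if (any(tree$parent >= seq_len(n))) {
    stop("parent indices must precede children (acyclic ordering)")
  }
  if (any(tree$radius <= 0)) stop("all radii must be > 0")
  child <- which(tree$parent > 0L)
  seg <- sqrt(rowSums((tree$nodes[child, , drop = FALSE] -
                         tree$nodes[tree$parent[child], , drop = FALSE])^2))
  if (any(seg > 1 + 1e-9)) {
    stop("consecutive centerline points must be <= 1 mm apart")
  }
  tb <- which(tree$branch == "target_branch")
  if (length(tb) == 0L) stop("tree must contain a target_branch")
  # target branch must be one contiguous chain
  if (length(unique(tree$parent[tb[-1L]])) != length(tb) - 1L ||
      !all(tree$parent[tb[-1L]] == tb[-length(tb)])) {
    stop("target_branch must form a single chain")
  }
  invisible(tree)
}

#' @export
print.centerline_tree <- function(x, ...) {
  cat(sprintf("<centerline_tree> %s (%s side), %d nodes, seed %d\n",
              x$case_id, x$side, nrow(x$nodes), x$seed))
  cat(sprintf("  trunk %.1f mm, target branch %.1f mm, distractor %.1f mm\n",
              branch_length(x, "trunk"), branch_length(x, "target_branch"),
              branch_length(x, "distractor_branch")))
  invisible(x)
}

branch_nodes <- function(tree, label) which(tree$branch == label)

branch_length <- function(tree, label) {
  idx <- branch_nodes(tree, label)
  idx <- idx[tree$parent[idx] > 0L]
  sum(sqrt(rowSums((tree$nodes[idx, , drop = FALSE] -
                      tree$nodes[tree$parent[idx], , drop = FALSE])^2)))
}

#' Anisotropic scaling augmentation
#'
#' Scales node coordinates about the root by `(sx, sy)` and radii by
#' `mean(sx, sy)`; topology and labels are preserved. Factors are restricted
#' to the augmentation range used during training, 0.7 to 1.3 per axis.
#'
#' @param tree A `centerline_tree`.
#' @param sx,sy Width and height scale factors in `[0.7, 1.3]`.
#' @return The scaled `centerline_tree`.
#' @export
augment_scale <- function(tree, sx, sy) {
  if (sx < 0.7 || sx > 1.3 || sy < 0.7 || sy > 1.3) {
    stop("scale factors must lie in [0.7, 1.3]", call. = FALSE)
  }
  root <- tree$nodes[which(tree$parent == 0L), ]
  out <- tree
  out$nodes <- sweep(sweep(tree$nodes, 2, root), 2, c(sx, sy), `*`)
  out$nodes <- sweep(out$nodes, 2, root, `+`)
  out$radius <- tree$radius * mean(c(sx, sy))
  out
}

#' Sample a navigation target on the target branch
#'
#' One of `n_points` equally spaced candidate points along the MCA-like
#' target branch is drawn uniformly; the target side always matches the tree
#' side (a right-sided target is approached from the right ICA trunk and
#' vice versa).
#'
#' @param tree A `centerline_tree`.
#' @param n_points Number of equally spaced candidate points (default 10).
#' @param seed Integer seed for the draw.
#' @return A `target_spec`: `position` (mm), `branch_side`,
#'   `centerline_index` in `[0, n_points - 1]`, and the supporting `node`
#'   index in the tree.
#' @export
sample_target <- function(tree, n_points = 10L, seed = 1L) {
  idx <- branch_nodes(tree, "target_branch")
  if (length(idx) < n_points) {
    stop("target branch too short to host ", n_points, " candidate points",
         call. = FALSE)
  }
  cand <- target_candidates(tree, n_points)
  k <- with_seed(seed, sample.int(n_points, 1L))
  structure(list(position = tree$nodes[cand[k], ],
                 branch_side = tree$side,
                 centerline_index = k - 1L,
                 node = cand[k]),
            class = "target_spec")
}

# Node indices of the n equally spaced candidate target points along the
# target branch (arc fractions 1/n .. n/n of the branch, measured from the
# bifurcation).
target_candidates <- function(tree, n_points = 10L) {
  idx <- branch_nodes(tree, "target_branch")
  seg <- sqrt(rowSums((tree$nodes[idx, , drop = FALSE] -
                         tree$nodes[tree$parent[idx], , drop = FALSE])^2))
  arc <- cumsum(seg)
  total <- arc[length(arc)]
  sapply(seq_len(n_points) / n_points, function(f) {
    idx[which.min(abs(arc - f * total))]
  })
}

tree_children <- function(tree) {
  n <- nrow(tree$nodes)
  ch <- vector("list", n)
  for (i in which(tree$parent > 0L)) {
    ch[[tree$parent[i]]] <- c(ch[[tree$parent[i]]], i)
  }
  ch
}

# Along-centerline distance from every node to node `from`, by traversal of
# the undirected tree graph (edge weight = Euclidean node spacing).
node_distances <- function(tree, from) {
  n <- nrow(tree$nodes)
  ch <- tree_children(tree)
  d <- rep(NA_real_, n)
  d[from] <- 0
  queue <- from
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    nb <- c(if (tree$parent[i] > 0L) tree$parent[i], ch[[i]])
    for (j in nb) {
      if (is.na(d[j])) {
        d[j] <- d[i] + vnorm(tree$nodes[j, ] - tree$nodes[i, ])
        queue <- c(queue, j)
      }
    }
  }
  d
}

nearest_node <- function(tree, point) {
  which.min((tree$nodes[, 1] - point[1])^2 + (tree$nodes[, 2] - point[2])^2)
}

#' Along-centerline distance from a point to the target
#'
#' The point is projected to the nearest centerline node and the distance is
#' measured along the tree graph; this is the `pathlength` quantity of the
#' dense reward, which decreases monotonically only along a correct route
#' past the bifurcation. Set `metric = "euclidean"` for the straight-line
#' alternative.
#'
#' @param tree A `centerline_tree`.
#' @param point Numeric length-2 point (mm).
#' @param target A `target_spec` from [sample_target()].
#' @param metric `"centerline"` (default) or `"euclidean"`.
#' @return Non-negative distance in mm.
#' @export
geodesic_distance <- function(tree, point, target,
                              metric = c("centerline", "euclidean")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") return(vnorm(point - target$position))
  d <- node_distances(tree, target$node)
  d[nearest_node(tree, point)]
}
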