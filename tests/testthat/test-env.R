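test_that("reset is deterministic with previous positions duplicating current", {
  env <- default_env()
  o1 <- env_reset(env, seed = 5L)
  o2 <- env_reset(env, seed = 5L)
  expect_identical(obs_vector(o1), obs_vector(o2))
  expect_identical(o1$gw_now, o1$gw_prev)
  expect_identical(o1$cath_now, o1$cath_prev)
  expect_identical(o1$prev_action, rep(0, 4))
})

test_that("initial pathlength equals the along-centerline distance to target", {
  tree <- default_tree(2L)
  target <- sample_target(tree, seed = 3L)
  env <- nav_env(tree, target)
  env_reset(env)
  tip <- track_points(env, "guidewire")[1L, ]
  expect_equal(env$pathlength, geodesic_distance(tree, tip, target),
               tolerance = 0.5)
})

test_that("target/tree side mismatch is rejected", {
  tree <- default_tree(2L, "right")
  wrong <- sample_target(default_tree(3L, "left"), seed = 1L)
  expect_error(nav_env(tree, wrong), "side")
})

test_that("zero action leaves the state unchanged with zero force", {
  env <- default_env()
  o0 <- env_reset(env)
  res <- env_step(env, c(0, 0, 0, 0))
  expect_identical(res$observation$gw_now, o0$gw_now)
  expect_equal(res$info$delta_pathlength, 0)
  expect_equal(res$force_magnitude, 0)
})

test_that("saturating translation advances 5.4 mm per step in a straight trunk", {
  st <- straight_tree()
  tg <- sample_target(st, seed = 1L)
  env <- nav_env(st, tg)
  env_reset(env)
  l0 <- env$gw_len
  res <- env_step(env, c(0, 1, 0, 0))
  expect_equal(env$gw_len - l0, 40 * 0.135, tolerance = 1e-9)
  expect_equal(res$info$delta_pathlength, -5.4, tolerance = 1e-6)
})

test_that("tracked points sit 2 mm apart in arc length with the tip first", {
  env <- default_env()
  env_reset(env)
  set.seed(11)
  for (k in 1:30) {
    res <- env_step(env, runif(4, -1, 1))
    for (dev in c("guidewire", "catheter")) {
      pts <- track_points(env, dev)
      len <- if (dev == "guidewire") env$gw_len else env$cath_len
      if (len >= 4) {
        gaps <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                                pts[-3, , drop = FALSE])^2))
        expect_true(all(gaps <= 2 + 1e-6))
      }
    }
    # tip point is the distal endpoint of the inserted body
    expect_equal(track_points(env, "guidewire")[1L, ],
                 res$observation$gw_now[1L, ])
    if (res$reached || res$truncated) break
  }
})

test_that("short devices pad tracked points with the insertion point", {
  st <- straight_tree()
  env <- nav_env(st, sample_target(st, seed = 1L),
                 env_config(initial_insertion = 1))
  env_reset(env)
  pts <- track_points(env, "guidewire")
  expect_equal(pts[3L, ], st$nodes[1L, ])
})

test_that("every tracked point stays within the lumen under random actions", {
  set.seed(21)
  for (ep in 1:4) {
    env <- default_env(seed = ep, target_seed = ep + 10L)
    env_reset(env, seed = ep)
    repeat {
      res <- env_step(env, runif(4, -1, 1))
      for (dev in c("guidewire", "catheter")) {
        pts <- track_points(env, dev)
        for (i in 1:3) {
          nn <- which.min((env$tree$nodes[, 1] - pts[i, 1])^2 +
                            (env$tree$nodes[, 2] - pts[i, 2])^2)
          d <- sqrt(sum((pts[i, ] - env$tree$nodes[nn, ])^2))
          expect_lte(d, env$tree$radius[nn] + 1e-6)
        }
      }
      if (res$reached || res$truncated) break
    }
  }
})

test_that("pathlength is non-increasing under pure insertion in a straight trunk", {
  st <- straight_tree()
  env <- nav_env(st, sample_target(st, seed = 2L))
  env_reset(env)
  paths <- env$pathlength
  for (k in 1:20) {
    res <- env_step(env, c(0, 0.7, 0, 0))
    paths <- c(paths, res$info$pathlength)
    if (res$reached) break
  }
  expect_true(all(diff(paths) <= 1e-9))
})

test_that("episodes cap at 200 steps and success respects the 5 mm criterion", {
  env <- default_env(3L, 4L)
  env_reset(env)
  n <- 0L
  repeat {
    res <- env_step(env, c(0, 0, 0, 0))  # never reaches
    n <- n + 1L
    if (res$truncated) break
    expect_false(res$reached)
  }
  expect_identical(n, 200L)
  expect_error(env_step(env, c(0, 0, 0, 0)), "terminated")

  env2 <- default_env(3L, 4L)
  ep <- run_episode(env2, oracle_policy)
  expect_true(ep$success)
  tip <- track_points(env2, "guidewire")[1L, ]
  expect_lte(sqrt(sum((tip - env2$target$position)^2)), 5)
})

test_that("non-finite actions are rejected", {
  env <- default_env()
  env_reset(env)
  expect_error(env_step(env, c(NaN, 0, 0, 0)), "finite")
  expect_error(env_step(env, c(0, Inf, 0, 0)), "finite")
  expect_error(env_step(env, c(0, 0, 0)), "4-vector")
})

test_that("trajectories are bitwise reproducible for identical inputs", {
  run <- function() {
    env <- default_env(6L, 7L)
    env_reset(env, seed = 9L)
    set.seed(33)
    out <- list()
    for (k in 1:40) {
      res <- env_step(env, runif(4, -1, 1))
      out[[k]] <- c(obs_vector(res$observation), res$force_magnitude,
                    res$info$pathlength)
      if (res$reached || res$truncated) break
    }
    out
  }
  expect_identical(run(), run())
})

test_that("tip force is a linear penetration proxy, zero on the centerline", {
  env <- default_env()
  env_reset(env)
  expect_equal(compute_tip_force(env), c(0, 0))
  # force magnitude doubles when the wall stiffness doubles at fixed state
  envA <- default_env(8L, 9L, env_config(wall_stiffness = 0.4))
  envB <- default_env(8L, 9L, env_config(wall_stiffness = 0.8))
  env_reset(envA); env_reset(envB)
  set.seed(55)
  acts <- matrix(runif(4 * 30, -1, 1), 30)
  fa <- fb <- numeric(0)
  for (k in 1:30) {
    ra <- env_step(envA, acts[k, ]); rb <- env_step(envB, acts[k, ])
    fa <- c(fa, ra$force_magnitude); fb <- c(fb, rb$force_magnitude)
    if (ra$reached || ra$truncated) break
  }
  expect_equal(fb, fa * 2, tolerance = 1e-9)
})

test_that("environment configuration round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("dt: 0.1", "timeout_steps: 100", "wall_stiffness: 2.5"), path)
  cfg <- env_config_from_yaml(path)
  expect_equal(cfg$dt, 0.1)
  expect_identical(cfg$timeout_steps, 100L)
  expect_equal(cfg$wall_stiffness, 2.5)
  expect_equal(cfg$max_translation_speed, 40)  # untouched default
})

test_that("default episode budget spans about 27 s of simulated time", {
  cfg <- env_config()
  expect_equal(cfg$dt * cfg$timeout_steps, 27, tolerance = 0.01 * 27)
})
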