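ctx0 <- function(...) reward_context(...)

test_that("dense reward matches its printed constants", {
  expect_equal(reward_dense(ctx0(delta_pathlength = 0)), -0.005)
  expect_equal(reward_dense(ctx0(delta_pathlength = 0, reached = TRUE)),
               0.995)
  expect_equal(reward_dense(ctx0(delta_pathlength = -10)), 0.005)
  expect_error(reward_dense(ctx0(delta_pathlength = NaN)), "finite")
})

test_that("IRL reward dispatches to the ipsilateral model only", {
  calls <- new.env()
  calls$left <- 0L; calls$right <- 0L
  models <- list(
    left = irl_stub(function(obs) { calls$left <- calls$left + 1L; -3 },
                    side = "left"),
    right = irl_stub(function(obs) { calls$right <- calls$right + 1L; 7 },
                     side = "right"))
  expect_equal(reward_irl(ctx0(target_side = "right"), models), 7)
  expect_equal(calls$left, 0L)
  expect_equal(reward_irl(ctx0(target_side = "left"), models), -3)
  expect_equal(calls$right, 1L)
  # swapping the side labels swaps the outputs
  swapped <- list(left = models$right, right = models$left)
  expect_equal(reward_irl(ctx0(target_side = "left"), swapped), 7)
  expect_error(reward_irl(ctx0(target_side = "left"),
                          list(right = models$right)), "left")
})

test_that("combined reward applies the alpha scale to the IRL term", {
  models <- list(right = irl_stub(2), left = irl_stub(2))
  expect_equal(reward_combined(ctx0(delta_pathlength = 0), models = models),
               -0.003)
  zero <- list(right = irl_stub(0), left = irl_stub(0))
  for (d in c(-4, 0, 2.5)) {
    expect_identical(reward_combined(ctx0(delta_pathlength = d),
                                     models = zero),
                     reward_dense(ctx0(delta_pathlength = d)))
  }
  cfg0 <- reward_config(irl_scale = 0)
  models7 <- list(right = irl_stub(7), left = irl_stub(7))
  expect_equal(reward_combined(ctx0(), cfg0, models7),
               reward_dense(ctx0(), cfg0))
})

test_that("force penalty activates strictly above 0.85 N with slope 0.01", {
  expect_equal(force_penalty(0.5), 0)
  expect_equal(force_penalty(0.85), 0)
  expect_equal(force_penalty(1.85), -0.01)
  expect_error(force_penalty(-0.1), ">= 0")
})

test_that("force-penalized rewards reduce to their bases at zero force", {
  models <- list(right = irl_stub(1.5), left = irl_stub(1.5))
  ctx <- ctx0(delta_pathlength = 3, force_magnitude = 0,
              target_side = "right")
  expect_identical(reward_with_force("R1", ctx), reward_dense(ctx))
  expect_identical(reward_with_force("R2", ctx, models = models),
                   reward_irl(ctx, models))
  expect_identical(reward_with_force("R3", ctx, models = models),
                   reward_combined(ctx, models = models))

  hi <- ctx0(delta_pathlength = 3, force_magnitude = 1.35,
             target_side = "right")
  expect_equal(reward_with_force("R3", hi, models = models) -
                 reward_combined(hi, models = models), -0.005)

  # strictly decreasing in force above the threshold
  forces <- seq(0.86, 3, by = 0.05)
  vals <- vapply(forces, function(f) {
    reward_with_force("R1", ctx0(force_magnitude = f))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("all six rewards are exact transcriptions on randomized contexts", {
  set.seed(101)
  models <- list(right = irl_stub(function(o) sum(o) * 0.3, side = "right"),
                 left = irl_stub(function(o) -sum(o), side = "left"))
  cfg <- reward_config()
  for (i in 1:200) {
    d <- rnorm(1, 0, 20)
    f <- runif(1, 0, 2)
    reached <- runif(1) < 0.2
    side <- sample(c("left", "right"), 1)
    obs <- rnorm(5)
    ctx <- ctx0(delta_pathlength = d, reached = reached,
                force_magnitude = f, observation = obs, target_side = side)
    r1 <- -0.005 - 0.001 * d + if (reached) 1.0 else 0
    r2 <- if (side == "right") sum(obs) * 0.3 else -sum(obs)
    pen <- if (f > 0.85) -0.01 * (f - 0.85) else 0
    expect_equal(make_reward("R1")(ctx), r1, tolerance = 1e-12)
    expect_equal(make_reward("R2", models = models)(ctx), r2,
                 tolerance = 1e-12)
    expect_equal(make_reward("R3", models = models)(ctx), r1 + 0.001 * r2,
                 tolerance = 1e-12)
    expect_equal(make_reward("R4")(ctx), r1 + pen, tolerance = 1e-12)
    expect_equal(make_reward("R5", models = models)(ctx), r2 + pen,
                 tolerance = 1e-12)
    expect_equal(make_reward("R6", models = models)(ctx),
                 r1 + 0.001 * r2 + pen, tolerance = 1e-12)
    # the penalized/unpenalized difference depends only on the force
    expect_equal(make_reward("R4")(ctx) - make_reward("R1")(ctx), pen,
                 tolerance = 1e-12)
    expect_equal(make_reward("R6", models = models)(ctx) -
                   make_reward("R3", models = models)(ctx), pen,
                 tolerance = 1e-12)
  }
})

test_that("IRL-based rewards refuse to build without models", {
  expect_error(make_reward("R2"), "IRL models")
  expect_error(make_reward("R6"), "IRL models")
})
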