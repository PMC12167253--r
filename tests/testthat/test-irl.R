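# enumerate all action sequences of a small deterministic MDP
enumerate_trajs <- function(mdp, horizon) {
  out <- list()
  recurse <- function(s, traj) {
    if (length(traj) == horizon + 1L) {
      out[[length(out) + 1L]] <<- traj
      return()
    }
    for (a in seq_len(mdp$n_actions)) recurse(mdp$next_state[s, a],
                                              c(traj, mdp$next_state[s, a]))
  }
  for (s0 in mdp$start) recurse(s0, s0)
  out
}

# independent forward pass of the 4-layer reward net (re-implemented here so
# the gradient oracle does not reuse package internals)
ref_forward <- function(net, X, act = "relu") {
  h <- X
  L <- length(net$W)
  hs <- list(h)
  for (l in seq_len(L)) {
    z <- sweep(h %*% net$W[[l]], 2, net$b[[l]], `+`)
    h <- if (l < L) { if (act == "relu") pmax(z, 0) else tanh(z) } else z
    hs[[l + 1L]] <- h
  }
  list(out = h, penult = hs[[L]])
}

test_that("IRL reward models are pure, bounded, and shape-checked", {
  m <- irl_model(6L, seed = 4L)
  x <- rnorm(6)
  expect_identical(irl_reward(m, x), irl_reward(m, x))
  expect_lte(abs(irl_reward(m, x)), m$out_bound)
  # zero-weight model returns exactly zero everywhere
  z <- m
  z$net$W <- lapply(z$net$W, function(w) w * 0)
  z$net$b <- lapply(z$net$b, function(b) b * 0)
  for (i in 1:5) expect_identical(irl_reward(z, rnorm(6)), 0)
  expect_error(irl_reward(m, rnorm(5)), "dimension mismatch")
  # architecture: exactly four fully connected layers
  expect_length(m$net$W, 4L)
})

test_that("a single one-step demonstration trains to a finite loss", {
  demo <- list(matrix(c(1, 0), 1L))
  cfg <- irl_config(iterations = 20, n_background = 4L,
                    refresh_every = 5L, hidden = 8L, seed = 2L)
  sampler <- function(rf, n) lapply(seq_len(n), function(i) {
    matrix(c(runif(1), 1 - runif(1)), 1L)
  })
  m <- fit_irl(demo, cfg, sampler)
  expect_true(all(is.finite(m$history$loss)))
})

test_that("empty demonstrations are rejected", {
  expect_error(fit_irl(list(), irl_config(iterations = 1),
                       sampler = function(rf, n) list()), "no demonstrations")
})

test_that("the fitted gradient matches exhaustive trajectory enumeration on a chain", {
  # 3-state chain, actions left/right, fixed horizon
  nxt <- cbind(c(1L, 1L, 2L), c(2L, 3L, 3L))
  mdp <- tabular_mdp(nxt, terminal = rep(FALSE, 3L), start = 1L,
                     horizon = 3L)
  feat <- diag(3)
  alpha <- 0.1
  pen <- 0.01
  # expert demos: run to the right end and stay
  demos <- list(feat[c(1, 2, 3, 3), ], feat[c(1, 2, 3, 3), ])
  all_trajs <- enumerate_trajs(mdp, 3L)
  eta <- 1e-3
  model0 <- irl_model(3L, hidden = 8L, out_bound = 50, seed = 6L)
  sampler <- function(rf, n) lapply(all_trajs, function(tr) feat[tr, ])
  cfg <- irl_config(iterations = 1L, learning_rate = eta,
                    n_background = length(all_trajs), refresh_every = 1L,
                    entropy_reg = alpha, length_penalty = pen, l2 = 0,
                    background_weighting = "softmax", seed = 1L)
  fitted <- fit_irl(demos, cfg, sampler, model = model0)

  # oracle: exact maximum-entropy gradient over the enumerated trajectory
  # set, pushed through an independently computed last-layer Jacobian
  r0 <- vapply(1:3, function(s) irl_reward(model0, feat[s, ]), numeric(1))
  scores <- vapply(all_trajs, function(tr) sum(r0[tr]) - pen * length(tr),
                   numeric(1))
  w <- exp(scores / alpha - max(scores / alpha))
  w <- w / sum(w)
  # per-state occupancion: demos minus the soft trajectory distribution
  occ_d <- rowSums(vapply(demos, function(d) colSums(d), numeric(3))) /
    length(demos)
  occ_b <- Reduce(`+`, Map(function(tr, wi) wi * colSums(feat[tr, ]),
                           all_trajs, as.list(w)))
  g_state <- -(occ_d - occ_b) / alpha      # d(loss)/d r(s)
  rf <- ref_forward(model0$net, feat * model0$feature_scale)
  sq <- 1 - tanh(rf$out / model0$out_bound)^2
  # gradient of the final-layer bias: sum over states of per-state gradient
  g_b4 <- sum(g_state * drop(sq))
  g_W4 <- crossprod(rf$penult, g_state * drop(sq))
  expect_equal((model0$net$b[[4]] - fitted$net$b[[4]]) / eta, g_b4,
               tolerance = 1e-6)
  expect_equal((model0$net$W[[4]] - fitted$net$W[[4]]) / eta, g_W4,
               tolerance = 1e-6)
})

test_that("sampled visitation converges to the exact soft visitation", {
  nxt <- cbind(c(1L, 1L, 2L), c(2L, 3L, 3L))
  mdp <- tabular_mdp(nxt, terminal = rep(FALSE, 3L), start = 1L,
                     horizon = 4L)
  r <- c(0, 0.2, 1)
  sv <- soft_value_iteration(mdp, r, alpha = 0.5)
  # exact state-visitation by dynamic programming (independent of sampling)
  d <- c(1, 0, 0)
  occ <- d
  for (t in 1:4) {
    d2 <- rep(0, 3)
    for (s in 1:3) for (a in 1:2) {
      d2[nxt[s, a]] <- d2[nxt[s, a]] + d[s] * sv$policy[s, a]
    }
    d <- d2
    occ <- occ + d
  }
  set.seed(11)
  err <- vapply(c(50L, 500L, 5000L), function(n) {
    mean(replicate(8, {
      trajs <- sample_mdp_trajectories(mdp, sv$policy, n)
      emp <- rowSums(vapply(trajs, function(tr) tabulate(tr, 3L),
                            numeric(3))) / n
      max(abs(emp - occ))
    }))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("expert-visited states earn higher reward than never-visited states", {
  # 4x4 gridworld, no terminal state: the expert patrols the top row
  # (moving east, staying at the wall) and never enters the lower rows
  set.seed(6)
  S <- 16L; A <- 4L; H <- 10L
  idx <- function(r, c) (r - 1L) * 4L + c
  nxt <- matrix(0L, S, A)
  for (r in 1:4) for (c in 1:4) {
    s <- idx(r, c)
    nxt[s, 1] <- if (r > 1) idx(r - 1, c) else s
    nxt[s, 2] <- if (r < 4) idx(r + 1, c) else s
    nxt[s, 3] <- if (c < 4) idx(r, c + 1) else s
    nxt[s, 4] <- if (c > 1) idx(r, c - 1) else s
  }
  mdp <- tabular_mdp(nxt, terminal = rep(FALSE, S), start = 1:S,
                     horizon = H)
  feat <- diag(S)
  visited <- vapply(1:4, idx, integer(1), r = 1L)
  demos <- lapply(visited, function(s0) {
    s <- s0; traj <- s
    for (t in 1:H) { s <- nxt[s, 3L]; traj <- c(traj, s) }  # move east
    feat[traj, , drop = FALSE]
  })
  sampler <- function(reward_fn, n) {
    r <- reward_fn(feat)
    sv <- soft_value_iteration(mdp, r, alpha = 0.1)
    trajs <- sample_mdp_trajectories(mdp, sv$policy, n)
    lapply(trajs, function(tr) feat[tr, , drop = FALSE])
  }
  cfg <- irl_config(iterations = 800, learning_rate = 1e-3,
                    n_background = 48L, refresh_every = 10L,
                    hidden = 16L, seed = 2L)
  model <- irl_model(S, hidden = 16L, out_bound = 10, seed = 2L)
  model <- fit_irl(demos, cfg, sampler, model = model)
  r <- irl_reward(model, feat)
  expect_gt(mean(r[visited]), mean(r[-visited]))
})

test_that("per-side training isolates data and registers with the reward dispatch", {
  trees <- generate_case_set(2L, seed = 13L)
  demos <- record_demos(trees, targets_per_branch = 1L,
                        navigations_per_case = 2L, seed = 14L)
  cfg <- irl_config(iterations = 15L, n_background = 6L, refresh_every = 5L,
                    hidden = 8L, seed = 3L)
  models <- train_side_models(demos, cfg)
  expect_identical(models$left$side, "left")
  expect_identical(models$right$side, "right")
  obs <- demo_features(demos[[1L]])[1L, ]
  rl <- reward_irl(reward_context(observation = obs, target_side = "left"),
                   models)
  rr <- reward_irl(reward_context(observation = obs, target_side = "right"),
                   models)
  expect_true(is.finite(rl) && is.finite(rr))
  # independently initialized and trained: the side models differ
  expect_false(isTRUE(all.equal(rl, rr)))
  expect_error(train_side_models(demos[vapply(demos, function(d) d$side,
                                              character(1)) == "right"],
                                 cfg), "both sides")
})

test_that("IRL model checkpoints round-trip through JSON", {
  m <- irl_model(5L, side = "left", hidden = 6L, feature_scale = 0.01,
                 seed = 8L)
  f <- withr::local_tempfile(fileext = ".json")
  save_irl_model(m, f)
  back <- load_irl_model(f)
  x <- rnorm(5)
  expect_equal(irl_reward(back, x), irl_reward(m, x), tolerance = 1e-12)
  expect_identical(back$side, "left")
})
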