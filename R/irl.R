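# Maximum-entropy inverse reinforcement learning. The reward model is a
# feedforward network of four fully connected layers mapping observation
# features to a scalar reward. Training follows the sample-based
# maximum-entropy formulation: trajectories are distributed proportionally
# to exp(score / alpha) with score = sum of per-state rewards minus a
# per-step length penalty; the demonstration log-likelihood is ascended,
# with the partition term estimated over background trajectories drawn from
# a caller-supplied sampler (soft-optimal rollouts on enumerable problems,
# environment rollouts on the navigation task).

#' IRL training configuration
#'
#' Defaults are the published training setting: 1e6 iterations at learning
#' rate 1e-2 with entropy regularization alpha = 0.1 and a 0.01 per-step
#' length penalty. Desk-scale runs lower `iterations`.
#'
#' @param iterations Gradient iterations.
#' @param learning_rate Adam learning rate.
#' @param entropy_reg Entropy weight `alpha` of the maximum-entropy
#'   trajectory distribution (distinct from the combined-reward scale).
#' @param length_penalty Per-step penalty subtracted from trajectory scores.
#' @param n_background Background trajectories per refresh.
#' @param refresh_every Iterations between background refreshes.
#' @param hidden Hidden width of the 4-layer reward network.
#' @param optimizer `"sgd"` (default) or `"adam"`. Plain gradient steps pair
#'   well with the bounded reward head: as the likelihood objective pushes
#'   rewards toward the bound the gradient vanishes and the weights settle,
#'   whereas scale-normalized updates keep drifting.
#' @param l2 L2 weight-decay coefficient on the reward-network weights
#'   (tames the scale drift the likelihood objective leaves unconstrained).
#' @param background_weighting `"uniform"` treats backgrounds as samples
#'   from the current maximum-entropy trajectory distribution (the sampler
#'   receives the current reward so it can track it); `"softmax"`
#'   importance-weights trajectories by exponentiated score, for samplers
#'   that draw from an unrelated proposal.
#' @param seed Integer seed.
#' @return An `irl_config` list.
#' @export
irl_config <- function(iterations = 1e6, learning_rate = 1e-2,
                       entropy_reg = 0.1, length_penalty = 0.01,
                       n_background = 64L, refresh_every = 25L,
                       hidden = 32L, optimizer = c("sgd", "adam"),
                       l2 = 1e-4,
                       background_weighting = c("uniform", "softmax"),
                       seed = 1L) {
  for (f in c("iterations", "learning_rate", "entropy_reg",
              "length_penalty")) check_positive(get(f), f)
  structure(list(iterations = iterations, learning_rate = learning_rate,
                 entropy_reg = entropy_reg, length_penalty = length_penalty,
                 n_background = as.integer(n_background),
                 refresh_every = as.integer(refresh_every),
                 hidden = as.integer(hidden),
                 optimizer = match.arg(optimizer), l2 = l2,
                 background_weighting = match.arg(background_weighting),
                 seed = as.integer(seed)),
            class = "irl_config")
}

#' Create an (untrained) IRL reward model
#'
#' A feedforward network of exactly four fully connected layers
#' (input -> hidden -> hidden -> hidden -> 1).
#'
#' @param input_dim Feature dimension.
#' @param side `"left"` or `"right"` branch tag.
#' @param hidden Hidden width.
#' @param feature_scale Multiplier applied to raw features before the
#'   network (0.01 conditions mm-scale observations; 1 for one-hot
#'   features).
#' @param act Hidden activation of the reward network.
#' @param out_bound Reward outputs are squashed to `[-out_bound, out_bound]`
#'   by a scaled tanh; the likelihood objective fixes rewards only up to
#'   monotone rescaling, and the bound keeps trajectory scores finite.
#' @param seed Integer seed.
#' @return An `irl_reward_model`.
#' @export
irl_model <- function(input_dim, side = "right", hidden = 32L,
                      feature_scale = 1, act = "relu", out_bound = 5,
                      seed = 1L) {
  structure(list(net = mlp_init(c(input_dim, hidden, hidden, hidden, 1L),
                                act = act, seed = seed),
                 side = side, input_dim = as.integer(input_dim),
                 feature_scale = feature_scale, out_bound = out_bound),
            class = "irl_reward_model")
}

#' Constant or functional stand-in reward model
#'
#' Used to exercise the reward dispatch without training; `fn` may be a
#' constant or a function of the observation.
#'
#' @param fn Scalar constant or function.
#' @param side Branch tag.
#' @return An `irl_stub` usable wherever an IRL model is.
#' @export
irl_stub <- function(fn, side = "right") {
  if (!is.function(fn)) { val <- fn; fn <- function(obs) val }
  structure(list(fn = fn, side = side), class = "irl_stub")
}

#' Evaluate an IRL reward model on observations
#'
#' @param model An `irl_reward_model` or `irl_stub`.
#' @param observation Numeric feature vector, or a matrix of row features.
#' @return Scalar reward (or vector for matrix input).
#' @export
irl_reward <- function(model, observation) UseMethod("irl_reward")

#' @export
irl_reward.irl_reward_model <- function(model, observation) {
  X <- if (is.matrix(observation)) observation else matrix(observation, 1L)
  if (ncol(X) != model$input_dim) {
    stop("feature dimension mismatch: model expects ", model$input_dim,
         ", got ", ncol(X), call. = FALSE)
  }
  raw <- drop(mlp_forward(model$net, X * model$feature_scale)$out)
  model$out_bound * tanh(raw / model$out_bound)
}

#' @export
irl_reward.irl_stub <- function(model, observation) {
  if (is.matrix(observation)) {
    apply(observation, 1, model$fn)
  } else model$fn(observation)
}

# trajectory score under the current model: sum of per-state rewards minus
# the per-step length penalty
traj_scores <- function(out_rows, traj_id, lens, penalty) {
  drop(rowsum(out_rows, traj_id)) - penalty * lens
}

#' Fit an IRL reward model by sample-based maximum-entropy IRL
#'
#' Ascends the demonstration log-likelihood under the maximum-entropy
#' trajectory distribution `p(tau) propto exp(score(tau) / alpha)`; the
#' partition term is a softmax over background trajectories, refreshed
#' periodically from `sampler` (which receives the current reward function
#' so backgrounds can track the learner).
#'
#' @param demos List of demonstration feature matrices (rows = states), all
#'   from one branch side.
#' @param cfg An [irl_config()].
#' @param sampler Function `(reward_fn, n) -> list of feature matrices`;
#'   `reward_fn(X)` returns per-row rewards under the current model.
#' @param model Optional pre-built [irl_model()] (inferred from the demos
#'   otherwise).
#' @param side Branch tag for the inferred model.
#' @return The trained `irl_reward_model`, with a `history` data frame of
#'   the loss trace attached.
#' @export
fit_irl <- function(demos, cfg = irl_config(), sampler, model = NULL,
                    side = "right") {
  demos <- Filter(function(d) nrow(d) > 0L, demos)
  if (length(demos) == 0L) stop("no demonstrations to fit", call. = FALSE)
  if (is.null(model)) {
    model <- irl_model(ncol(demos[[1L]]), side = side, hidden = cfg$hidden,
                       seed = cfg$seed)
  }
  alpha <- cfg$entropy_reg
  Xd <- do.call(rbind, demos) * model$feature_scale
  id_d <- rep(seq_along(demos), vapply(demos, nrow, integer(1)))
  len_d <- vapply(demos, nrow, integer(1))
  nd <- length(demos)

  opt <- adam_init(list(W = model$net$W, b = model$net$b))
  loss_trace <- numeric(cfg$iterations)
  with_seed(cfg$seed, {
    Xb <- NULL
    for (it in seq_len(cfg$iterations)) {
      if (is.null(Xb) || (it - 1L) %% cfg$refresh_every == 0L) {
        rf <- function(X) irl_reward(model, X)
        bg <- sampler(rf, cfg$n_background)
        bg <- Filter(function(d) nrow(d) > 0L, bg)
        Xb <- do.call(rbind, bg) * model$feature_scale
        id_b <- rep(seq_along(bg), vapply(bg, nrow, integer(1)))
        len_b <- vapply(bg, nrow, integer(1))
        nb <- length(bg)
      }
      X <- rbind(Xd, Xb)
      fwd <- mlp_forward(model$net, X, want_cache = TRUE)
      B <- model$out_bound
      r <- B * tanh(fwd$out / B)
      dr_draw <- 1 - tanh(fwd$out / B)^2   # gradient of the bounded head
      rd <- r[seq_len(nrow(Xd)), , drop = FALSE]
      rb <- r[-seq_len(nrow(Xd)), , drop = FALSE]
      Sd <- traj_scores(rd, id_d, len_d, cfg$length_penalty)
      Sb <- traj_scores(rb, id_b, len_b, cfg$length_penalty)
      loss <- if (cfg$background_weighting == "softmax") {
        -(mean(Sd) / alpha - (logsumexp(Sb / alpha) - log(nb)))
      } else {
        -(mean(Sd) - mean(Sb)) / alpha
      }
      if (!is.finite(loss)) {
        stop("IRL training diverged at iteration ", it,
             " (non-finite loss; last mean demo score ", mean(Sd), ")",
             call. = FALSE)
      }
      loss_trace[it] <- loss
      w <- if (cfg$background_weighting == "softmax") {
        exp(Sb / alpha - logsumexp(Sb / alpha))
      } else rep(1 / nb, nb)
      dOut <- matrix(c(rep(-1 / (nd * alpha), nrow(Xd)),
                       (w / alpha)[id_b]), ncol = 1L) * dr_draw
      grads <- mlp_backward(model$net, fwd$cache, dOut)$grads
      if (cfg$l2 > 0) {
        grads$W <- Map(function(g, w) g + cfg$l2 * w, grads$W, model$net$W)
      }
      if (cfg$optimizer == "adam") {
        upd <- adam_step(list(W = model$net$W, b = model$net$b), grads, opt,
                         cfg$learning_rate)
        model$net$W <- upd$params$W
        model$net$b <- upd$params$b
        opt <- upd$state
      } else {
        model$net$W <- Map(function(w, g) w - cfg$learning_rate * g,
                           model$net$W, grads$W)
        model$net$b <- Map(function(b, g) b - cfg$learning_rate * g,
                           model$net$b, grads$b)
      }
    }
  })
  model$history <- data.frame(iteration = seq_along(loss_trace),
                              loss = loss_trace)
  model
}

#' Observation features of a recorded demonstration
#'
#' Rebuilds the agent-facing observation vector (current and previous
#' tracked points for both devices, target, previous action) for every step
#' of a demonstration trace.
#'
#' @param demo A `demonstration`.
#' @return Matrix with one observation row per step.
#' @export
demo_features <- function(demo) {
  tr <- demo$trace
  t(vapply(seq_along(tr), function(t) {
    prev <- if (t > 1L) tr[[t - 1L]] else tr[[t]]
    prev_action <- if (t > 1L) tr[[t - 1L]]$action else rep(0, 4)
    c(t(tr[[t]]$gw), t(tr[[t]]$cath), t(prev$gw), t(prev$cath),
      demo$target$position, prev_action)
  }, numeric(22L + 8L)))
}

#' Background sampler drawing random-action environment rollouts
#'
#' @param env_factory Function `(i) -> nav_env`.
#' @param max_steps Rollout length cap.
#' @return A sampler usable by [fit_irl()].
#' @export
make_rollout_sampler <- function(env_factory, max_steps = 60L) {
  force(env_factory)
  counter <- 0L
  function(reward_fn, n) {
    lapply(seq_len(n), function(i) {
      counter <<- counter + 1L
      env <- env_factory(counter)
      obs <- env_reset(env, seed = counter)
      rows <- list()
      for (s in seq_len(max_steps)) {
        res <- env_step(env, stats::runif(4, -1, 1))
        rows[[s]] <- obs_vector(res$observation)
        if (res$reached || res$truncated) break
      }
      do.call(rbind, rows)
    })
  }
}

#' Train per-branch IRL reward models
#'
#' Splits demonstrations by target side, drops timed-out navigations, and
#' fits one reward model per side; each model only ever sees its own side's
#' data.
#'
#' @param demos List of `demonstration` objects covering both sides.
#' @param cfg An [irl_config()].
#' @param trees Optional list of `centerline_tree` objects; when given,
#'   background trajectories are random-action rollouts on the matching
#'   side's trees, otherwise backgrounds are resampled demonstration
#'   fragments.
#' @return Named list with trained `left` and `right` models.
#' @export
train_side_models <- function(demos, cfg = irl_config(), trees = NULL) {
  by_side <- split_by_side(demos)
  if (length(by_side$left) == 0L || length(by_side$right) == 0L) {
    stop("demonstrations required for both sides", call. = FALSE)
  }
  fit_one <- function(side_demos, side) {
    ok <- Filter(function(d) identical(d$outcome, "success"), side_demos)
    if (length(ok) == 0L) {
      stop("no successful demonstrations for side ", side, call. = FALSE)
    }
    feats <- lapply(ok, demo_features)
    sampler <- if (!is.null(trees)) {
      side_trees <- Filter(function(t) identical(t$side, side), trees)
      make_rollout_sampler(function(i) {
        tree <- side_trees[[(i - 1L) %% length(side_trees) + 1L]]
        nav_env(tree, sample_target(tree, seed = i))
      })
    } else {
      # demo-fragment background: random contiguous fragments of the
      # demonstrations themselves
      function(reward_fn, n) {
        lapply(seq_len(n), function(i) {
          f <- feats[[sample.int(length(feats), 1L)]]
          a <- sample.int(nrow(f), 1L)
          b <- min(nrow(f), a + sample.int(20L, 1L))
          f[a:b, , drop = FALSE]
        })
      }
    }
    m <- irl_model(ncol(feats[[1L]]), side = side, hidden = cfg$hidden,
                   feature_scale = 0.01, seed = cfg$seed)
    fit_irl(feats, cfg, sampler, model = m, side = side)
  }
  list(left = fit_one(by_side$left, "left"),
       right = fit_one(by_side$right, "right"))
}

#' Save / load IRL model checkpoints
#'
#' Weights are stored as JSON (plain text) together with side and
#' feature-scale metadata.
#'
#' @param model An `irl_reward_model`.
#' @param path Output path.
#' @return `path` invisibly; `load_irl_model()` returns the model.
#' @export
save_irl_model <- function(model, path) {
  obj <- list(side = model$side, input_dim = model$input_dim,
              feature_scale = model$feature_scale,
              out_bound = model$out_bound,
              sizes = model$net$sizes, act = model$net$act,
              W = lapply(model$net$W, identity),
              b = model$net$b)
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_irl_model
#' @export
load_irl_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  net <- structure(list(W = lapply(obj$W, as.matrix),
                        b = lapply(obj$b, as.numeric),
                        act = obj$act, sizes = obj$sizes), class = "mlp")
  structure(list(net = net, side = obj$side,
                 input_dim = as.integer(obj$input_dim),
                 feature_scale = obj$feature_scale,
                 out_bound = obj$out_bound),
            class = "irl_reward_model")
}
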