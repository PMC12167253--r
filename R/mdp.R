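# Small tabular-MDP tools used to validate the learners on enumerable
# problems: entropy-regularized (soft) value iteration and trajectory
# sampling under a tabular policy. Deterministic transitions, finite
# horizon.

#' Define a small deterministic tabular MDP
#'
#' @param next_state S x A integer matrix: successor of (state, action).
#' @param terminal Logical length-S vector; terminal states absorb.
#' @param start Integer vector of admissible start states.
#' @param horizon Episode horizon.
#' @return A `tabular_mdp` list.
#' @export
tabular_mdp <- function(next_state, terminal, start, horizon) {
  stopifnot(is.matrix(next_state), length(terminal) == nrow(next_state))
  structure(list(next_state = next_state, terminal = terminal,
                 start = start, horizon = as.integer(horizon),
                 n_states = nrow(next_state), n_actions = ncol(next_state)),
            class = "tabular_mdp")
}

#' Finite-horizon soft (maximum-entropy) value iteration
#'
#' Backward recursion `Q_t(s, a) = r(s) + V_{t+1}(s')`,
#' `V_t(s) = alpha * logsumexp(Q_t(s, .) / alpha)` (terminal states get
#' `V = r`), giving the soft-optimal policy
#' `pi(a | s) propto exp(Q_1(s, a) / alpha)` used both as the
#' maximum-entropy trajectory distribution and as a sampling policy.
#'
#' @param mdp A [tabular_mdp()].
#' @param reward Length-S per-state reward vector.
#' @param alpha Entropy regularization weight (> 0).
#' @param gamma Discount (1 for the finite-horizon maximum-entropy case).
#' @return List with `Q` (S x A), `V` (length S), and `policy` (S x A row
#'   stochastic).
#' @export
soft_value_iteration <- function(mdp, reward, alpha = 0.1, gamma = 1) {
  S <- mdp$n_states; A <- mdp$n_actions
  V <- reward
  V[!mdp$terminal] <- reward[!mdp$terminal]  # horizon-0 value
  Q <- matrix(0, S, A)
  for (t in seq_len(mdp$horizon)) {
    for (a in seq_len(A)) Q[, a] <- reward + gamma * V[mdp$next_state[, a]]
    Vn <- alpha * apply(Q / alpha, 1, logsumexp)
    Vn[mdp$terminal] <- reward[mdp$terminal]
    V <- Vn
  }
  logits <- Q / alpha
  policy <- exp(logits - apply(logits, 1, max))
  policy <- policy / rowSums(policy)
  list(Q = Q, V = V, policy = policy)
}

#' Sample trajectories from a tabular policy
#'
#' @param mdp A [tabular_mdp()].
#' @param policy S x A row-stochastic matrix.
#' @param n Number of trajectories.
#' @param start Optional fixed start states (recycled); default samples
#'   uniformly from `mdp$start`.
#' @return List of integer state-index vectors (each includes the start
#'   state; stops at a terminal state or at the horizon).
#' @export
sample_mdp_trajectories <- function(mdp, policy, n, start = NULL) {
  lapply(seq_len(n), function(i) {
    s <- if (is.null(start)) {
      mdp$start[sample.int(length(mdp$start), 1L)]
    } else start[(i - 1L) %% length(start) + 1L]
    traj <- s
    for (t in seq_len(mdp$horizon)) {
      if (mdp$terminal[s]) break
      a <- sample.int(mdp$n_actions, 1L, prob = policy[s, ])
      s <- mdp$next_state[s, a]
      traj <- c(traj, s)
    }
    traj
  })
}
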