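# Minimal neural-network machinery: dense multilayer perceptrons, an LSTM
# cell with backpropagation through time, and Adam. Pure matrix-op R, sized
# for the small networks this package trains. Parameters and gradients are
# nested lists of numeric arrays with matching shapes.

sigmoid <- function(x) 1 / (1 + exp(-x))

nn_seeded_matrix <- function(nr, nc, scale) {
  matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)
}

#' Initialize a dense multilayer perceptron
#'
#' @param sizes Integer vector of layer widths, input first, output last;
#'   `length(sizes) - 1` fully connected layers.
#' @param act Hidden activation, `"relu"` or `"tanh"`; output is linear.
#' @param seed Integer seed for the (Xavier-scaled) initialization.
#' @return An `mlp` parameter list.
#' @export
mlp_init <- function(sizes, act = "relu", seed = 1L) {
  with_seed(seed, {
    W <- lapply(seq_len(length(sizes) - 1L), function(l) {
      nn_seeded_matrix(sizes[l], sizes[l + 1L], sqrt(2 / sizes[l]))
    })
    b <- lapply(sizes[-1L], function(n) rep(0, n))
    structure(list(W = W, b = b, act = act, sizes = sizes), class = "mlp")
  })
}

act_fn <- function(z, act) switch(act, relu = pmax(z, 0), tanh = tanh(z))

#' Forward pass of an MLP
#'
#' @param net An [mlp_init()] network.
#' @param X Input matrix (rows = samples).
#' @param want_cache Keep intermediate activations for [mlp_backward()].
#' @return List with `out` (matrix) and, if requested, `cache`.
#' @export
mlp_forward <- function(net, X, want_cache = FALSE) {
  L <- length(net$W)
  hs <- vector("list", L + 1L)
  zs <- vector("list", L)
  hs[[1L]] <- X
  for (l in seq_len(L)) {
    z <- hs[[l]] %*% net$W[[l]]
    z <- sweep(z, 2, net$b[[l]], `+`)
    zs[[l]] <- z
    hs[[l + 1L]] <- if (l < L) act_fn(z, net$act) else z
  }
  list(out = hs[[L + 1L]],
       cache = if (want_cache) list(hs = hs, zs = zs) else NULL)
}

#' Backward pass of an MLP
#'
#' @param net The network.
#' @param cache Cache from [mlp_forward()] with `want_cache = TRUE`.
#' @param dOut Gradient of the loss with respect to the output matrix.
#' @return List with `grads` (same shape as the `W`/`b` lists) and `dX`.
#' @export
mlp_backward <- function(net, cache, dOut) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  dH <- dOut
  for (l in rev(seq_len(L))) {
    dZ <- if (l < L) {
      if (net$act == "relu") dH * (cache$zs[[l]] > 0)
      else dH * (1 - tanh(cache$zs[[l]])^2)
    } else dH
    gW[[l]] <- crossprod(cache$hs[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    dH <- tcrossprod(dZ, net$W[[l]])
  }
  list(grads = list(W = gW, b = gb), dX = dH)
}

# ---- LSTM cell ----

#' Initialize an LSTM cell
#'
#' Gate order in the concatenated weights: input, forget, cell, output;
#' forget-gate bias starts at 1.
#'
#' @param input_dim,hidden Input and hidden sizes.
#' @param seed Integer seed.
#' @return An `lstm` parameter list.
#' @export
lstm_init <- function(input_dim, hidden, seed = 1L) {
  with_seed(seed, {
    b <- rep(0, 4L * hidden)
    b[hidden + seq_len(hidden)] <- 1
    structure(list(
      Wx = nn_seeded_matrix(input_dim, 4L * hidden, sqrt(1 / input_dim)),
      Wh = nn_seeded_matrix(hidden, 4L * hidden, sqrt(1 / hidden)),
      b = b, hidden = hidden), class = "lstm")
  })
}

lstm_zero_state <- function(cell, n) {
  list(h = matrix(0, n, cell$hidden), c = matrix(0, n, cell$hidden))
}

# One LSTM step. `state` is list(h, c) with n x H matrices.
lstm_step <- function(cell, X, state, want_cache = FALSE) {
  H <- cell$hidden
  A <- X %*% cell$Wx + state$h %*% cell$Wh
  A <- sweep(A, 2, cell$b, `+`)
  i <- sigmoid(A[, seq_len(H), drop = FALSE])
  f <- sigmoid(A[, H + seq_len(H), drop = FALSE])
  g <- tanh(A[, 2L * H + seq_len(H), drop = FALSE])
  o <- sigmoid(A[, 3L * H + seq_len(H), drop = FALSE])
  c_new <- f * state$c + i * g
  tc <- tanh(c_new)
  h_new <- o * tc
  list(state = list(h = h_new, c = c_new),
       cache = if (want_cache) {
         list(X = X, h_prev = state$h, c_prev = state$c,
              i = i, f = f, g = g, o = o, tc = tc)
       } else NULL)
}

#' Forward pass of an LSTM over a sequence
#'
#' @param cell An [lstm_init()] cell.
#' @param X_seq List over time of input matrices (n x input_dim).
#' @param state Initial state (`NULL` for zeros).
#' @param want_cache Keep per-step caches for [lstm_backward()].
#' @return List with `H` (list over time of hidden matrices), final `state`,
#'   and `cache`.
#' @export
lstm_forward <- function(cell, X_seq, state = NULL, want_cache = FALSE) {
  n <- nrow(X_seq[[1L]])
  if (is.null(state)) state <- lstm_zero_state(cell, n)
  Tn <- length(X_seq)
  Hs <- vector("list", Tn)
  caches <- if (want_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    st <- lstm_step(cell, X_seq[[t]], state, want_cache)
    state <- st$state
    Hs[[t]] <- state$h
    if (want_cache) caches[[t]] <- st$cache
  }
  list(H = Hs, state = state, cache = caches)
}

#' Backpropagation through time for the LSTM
#'
#' @param cell The cell.
#' @param cache Per-step caches from [lstm_forward()].
#' @param dH_seq List over time of gradients w.r.t. the hidden outputs.
#' @return List with `grads` (`Wx`, `Wh`, `b`).
#' @export
lstm_backward <- function(cell, cache, dH_seq) {
  H <- cell$hidden
  Tn <- length(cache)
  gWx <- matrix(0, nrow(cell$Wx), ncol(cell$Wx))
  gWh <- matrix(0, H, 4L * H)
  gb <- rep(0, 4L * H)
  n <- nrow(dH_seq[[Tn]])
  dh_next <- matrix(0, n, H)
  dc_next <- matrix(0, n, H)
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    dh <- dH_seq[[t]] + dh_next
    do_ <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dc_next <- dc * cc$f
    dA <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    gWx <- gWx + crossprod(cc$X, dA)
    gWh <- gWh + crossprod(cc$h_prev, dA)
    gb <- gb + colSums(dA)
    dh_next <- tcrossprod(dA, cell$Wh)
  }
  list(grads = list(Wx = gWx, Wh = gWh, b = gb))
}

# ---- Adam over nested parameter lists ----

nn_zeros_like <- function(p) {
  if (is.list(p)) lapply(p, nn_zeros_like)
  else if (is.numeric(p)) p * 0
  else p
}

#' Initialize Adam optimizer state for a nested parameter list
#' @param params Nested list of numeric arrays.
#' @return Optimizer state.
#' @export
adam_init <- function(params) {
  list(m = nn_zeros_like(params), v = nn_zeros_like(params), t = 0L)
}

# walk params/grads in parallel; when both are named lists only the leaves
# named in the gradients are updated (metadata fields pass through)
adam_walk <- function(p, g, m, v, f) {
  if (is.list(p)) {
    if (!is.null(names(p)) && !is.null(names(g))) {
      for (nm in names(g)) {
        out <- adam_walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]], f)
        p[[nm]] <- out$p
        m[[nm]] <- out$m
        v[[nm]] <- out$v
      }
      list(p = p, m = m, v = v)
    } else {
      out <- Map(adam_walk, p, g, m, v, MoreArgs = list(f = f))
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    }
  } else if (is.numeric(p) && !is.null(g)) f(p, g, m, v)
  else list(p = p, m = m, v = v)
}

#' One Adam step
#'
#' @param params,grads,state Nested parameter/gradient lists and the state
#'   from [adam_init()].
#' @param lr Learning rate; `beta1`, `beta2`, `eps` as usual.
#' @return List with updated `params` and `state`.
#' @export
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  f <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    list(p = p - lr * (m / bc1) / (sqrt(v / bc2) + eps), m = m, v = v)
  }
  # `grads` must be congruent with `params`: pass pure parameter structures
  # (numeric leaves only), e.g. list(W = net$W, b = net$b) for an MLP
  out <- adam_walk(params, grads, state$m, state$v, f)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}
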