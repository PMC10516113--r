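# Minimal dense-network toolkit backing the sequential autoencoder: seeded
# fan-in initialization, MLP and GRU forward/backward wrappers around the
# compiled kernels, an Adam optimizer over nested parameter lists, and leaf
# accessors used by the finite-difference gradient checks.

ACT_CODES <- c(relu = 0L, tanh = 1L)

#' Derive a component seed from a global seed
#'
#' Deterministic 31-bit mixing of a base seed and an integer salt so that
#' independent stochastic components (data generation, weight initialization,
#' minibatching, probe regressors) draw from distinct but reproducible
#' streams.
#'
#' @param seed integer base seed.
#' @param salt integer component tag.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, salt = 0L) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  for (k in seq_len(abs(as.integer(salt)) %% 64 + 2)) {
    s <- (s * 48271 + as.numeric(salt) + k) %% 2147483647
  }
  as.integer(s %% 2147483645) + 1L
}

init_linear <- function(d_in, d_out, zero = FALSE) {
  if (zero) {
    list(W = matrix(0, d_in, d_out), b = rep(0, d_out))
  } else {
    bound <- 1 / sqrt(d_in)
    list(W = matrix(stats::runif(d_in * d_out, -bound, bound), d_in, d_out),
         b = stats::runif(d_out, -bound, bound))
  }
}

# dims: c(d_in, hidden..., d_out); hidden activation shared, output linear.
# The activation and layer sizes ride along as attributes so that the list
# itself contains only trainable arrays (the optimizer walks every numeric
# leaf of the parameter tree).
init_mlp <- function(dims, act = "relu", zero_last = FALSE) {
  L <- length(dims) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    lin <- init_linear(dims[l], dims[l + 1L], zero = zero_last && l == L)
    W[[l]] <- lin$W
    b[[l]] <- lin$b
  }
  structure(list(W = W, b = b), act = act, dims = dims, class = "mlp_params")
}

mlp_act <- function(mlp) attr(mlp, "act")

mlp_forward <- function(mlp, X, with_cache = FALSE) {
  out <- cpp_mlp_forward(X, mlp$W, mlp$b, ACT_CODES[[mlp_act(mlp)]])
  if (with_cache) list(out = out$out, cache = list(X = X, hidden = out$hidden))
  else out$out
}

# Returns list(dX, dW, db); dX only when need_dx.
mlp_backward <- function(mlp, cache, grad_out, need_dx = TRUE) {
  cpp_mlp_backward(cache$X, cache$hidden, mlp$W, grad_out,
                   ACT_CODES[[mlp_act(mlp)]], need_dx)
}

# Exact Jacobian of the MLP at a single input point, by chaining layer
# Jacobians; returned in standard orientation J[i, j] = d out_i / d in_j.
# Differentiable up to the usual ReLU measure-zero caveat.
mlp_jacobian <- function(mlp, x) {
  x <- matrix(x, nrow = 1)
  L <- length(mlp$W)
  J <- diag(length(x))
  h <- x
  for (l in seq_len(L)) {
    a <- h %*% mlp$W[[l]] + matrix(mlp$b[[l]], 1)
    J <- J %*% mlp$W[[l]]
    if (l < L) {
      if (mlp_act(mlp) == "relu") {
        h <- pmax(a, 0)
        J <- J * rep(as.numeric(a > 0), each = nrow(J))
      } else {
        h <- tanh(a)
        J <- J * rep(1 - as.numeric(h)^2, each = nrow(J))
      }
    }
  }
  t(J)
}

init_gru <- function(d_in, hidden) {
  bound <- 1 / sqrt(hidden)
  r <- function(n) stats::runif(n, -bound, bound)
  list(W = matrix(r(d_in * 3 * hidden), d_in, 3 * hidden),
       U = matrix(r(hidden * 3 * hidden), hidden, 3 * hidden),
       bi = r(3 * hidden), bh = r(3 * hidden))
}

# X_cube: batch x inputs x time
gru_forward <- function(gru, X_cube, with_cache = FALSE) {
  out <- cpp_gru_forward(X_cube, gru$W, gru$U, gru$bi, gru$bh)
  if (with_cache) out else out$hT
}

gru_backward <- function(gru, X_cube, cache, dhT) {
  cpp_gru_backward(X_cube, cache$r, cache$z, cache$n, cache$ghn, cache$hprev,
                   gru$W, gru$U, dhT)
}

## ---- nested parameter-list utilities -------------------------------------

is_param_leaf <- function(x) is.numeric(x)

# Apply f(leaf_a, leaf_b) over two parallel nested lists.
param_map2 <- function(a, b, f) {
  if (is_param_leaf(a)) return(f(a, b))
  out <- a
  for (nm in seq_along(a)) {
    if (is.null(a[[nm]])) next
    out[[nm]] <- param_map2(a[[nm]], b[[nm]], f)
  }
  out
}

param_zeros_like <- function(p) {
  if (is_param_leaf(p)) return(p * 0)
  out <- p
  for (i in seq_along(p)) if (!is.null(p[[i]])) out[[i]] <- param_zeros_like(p[[i]])
  out
}

param_sumsq <- function(p) {
  if (is_param_leaf(p)) return(sum(p^2))
  s <- 0
  for (i in seq_along(p)) if (!is.null(p[[i]])) s <- s + param_sumsq(p[[i]])
  s
}

# Enumerate leaf paths as lists of indices, for the gradient checker.
param_leaf_paths <- function(p, prefix = list()) {
  if (is_param_leaf(p)) return(list(prefix))
  out <- list()
  for (i in seq_along(p)) {
    if (is.null(p[[i]])) next
    out <- c(out, param_leaf_paths(p[[i]], c(prefix, list(i))))
  }
  out
}

param_get <- function(p, path) {
  for (i in path) p <- p[[i]]
  p
}

param_set <- function(p, path, value) {
  if (length(path) == 1L) {
    p[[path[[1L]]]] <- value
    return(p)
  }
  p[[path[[1L]]]] <- param_set(p[[path[[1L]]]], path[-1L], value)
  p
}

## ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = param_zeros_like(params), v = param_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip_norm = Inf) {
  if (is.finite(clip_norm)) {
    gnorm <- sqrt(param_sumsq(grads))
    if (gnorm > clip_norm) {
      scale <- clip_norm / gnorm
      grads <- param_map2(grads, grads, function(g, ...) g * scale)
    }
  }
  state$t <- state$t + 1L
  state$m <- param_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  mhat_scale <- 1 / (1 - beta1^state$t)
  vhat_scale <- 1 / (1 - beta2^state$t)
  upd <- param_map2(state$m, state$v, function(m, v) {
    lr * (m * mhat_scale) / (sqrt(v * vhat_scale) + eps)
  })
  # gradient leaves may arrive as 1 x n row matrices for vector parameters;
  # preserve each parameter's original shape
  params <- param_map2(params, upd, function(p, u) {
    r <- p - u
    if (is.null(dim(p))) as.numeric(r) else r
  })
  list(params = params, state = state)
}
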