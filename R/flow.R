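# The Flow readout: an approximately injective residual map from latent
# space to log-firing-rate space.  Forward, the latent state is zero-padded
# to the neural dimensionality and refined by K small additive MLP steps,
#
#   s_0 = [z | 0],   s_{k+1} = s_k + beta * MLP(s_k),   log_rates = s_K.
#
# The (approximate) inverse serially subtracts the same MLP evaluated at the
# current state and trims back to the leading latent coordinates.  The map
# is injective whenever beta * Lip(MLP) < 1; with small beta and moderate K
# it remains approximately injective, which is the property the model relies
# on to keep latent activity visible in the likelihood.

#' Initialize Flow readout parameters
#'
#' @param D_hat latent (input) dimensionality; must not exceed `N`.
#' @param N neural (output) dimensionality.
#' @param hidden integer vector of hidden-layer widths of the shared MLP.
#' @param K number of additive refinement steps (default 20).
#' @param beta step-size scale on the MLP output (default 0.1).
#' @return An object of class `flow_params` (an [init_mlp()] parameter list
#'   with flow metadata attributes).
#' @export
flow_params <- function(D_hat, N, hidden = c(150, 150), K = 20L, beta = 0.1) {
  if (D_hat > N) stop("flow readout requires D_hat <= N (zero-padding)")
  if (K < 1) stop("K must be >= 1")
  if (beta <= 0 || beta > 1) stop("beta must be in (0, 1]")
  mlp <- init_mlp(c(N, hidden, N), act = "relu")
  structure(mlp, D_hat = as.integer(D_hat), N = as.integer(N),
            K = as.integer(K), beta = beta,
            class = c("flow_params", class(mlp)))
}

flow_pad <- function(z, N) {
  if (ncol(z) == N) return(z)
  cbind(z, matrix(0, nrow(z), N - ncol(z)))
}

#' Flow forward pass: latent states to log-rates
#'
#' @param fp [flow_params()].
#' @param z matrix `points x D_hat` of latent states.
#' @param with_cache keep per-step caches for backpropagation.
#' @return Matrix `points x N` of log-rates (exponentiation is the caller's
#'   responsibility), or a list with `out` and `cache` when `with_cache`.
#' @export
flow_forward <- function(fp, z, with_cache = FALSE) {
  N <- attr(fp, "N"); K <- attr(fp, "K"); beta <- attr(fp, "beta")
  if (ncol(z) != attr(fp, "D_hat")) stop("latent dimension mismatch")
  s <- flow_pad(z, N)
  caches <- if (with_cache) vector("list", K)
  for (k in seq_len(K)) {
    step <- mlp_forward(fp, s, with_cache = with_cache)
    if (with_cache) {
      caches[[k]] <- step$cache
      s <- s + beta * step$out
    } else {
      s <- s + beta * step
    }
  }
  if (with_cache) list(out = s, cache = caches) else s
}

# Backward through the forward flow.  grad_out: points x N.  Returns
# list(dz, dW, db) with dz restricted to the leading D_hat coordinates.
flow_forward_backward <- function(fp, cache, grad_out) {
  K <- attr(fp, "K"); beta <- attr(fp, "beta"); D_hat <- attr(fp, "D_hat")
  dW <- lapply(fp$W, function(w) w * 0)
  db <- lapply(fp$b, function(b) b * 0)
  g <- grad_out
  for (k in rev(seq_len(K))) {
    bk <- mlp_backward(fp, cache[[k]], beta * g, need_dx = TRUE)
    for (l in seq_along(dW)) {
      dW[[l]] <- dW[[l]] + bk$dW[[l]]
      db[[l]] <- db[[l]] + bk$db[[l]]
    }
    g <- g + bk$dX
  }
  list(dz = g[, seq_len(D_hat), drop = FALSE], dW = dW, db = db)
}

#' Flow reverse pass: log-rates to latent states
#'
#' Serially subtracts the shared MLP evaluated at the current state,
#' `u_{k-1} = u_k - beta * MLP(u_k)`, `K` times, then trims to the leading
#' `D_hat` coordinates.  Because the subtraction is evaluated at the current
#' rather than the pre-update state, the composition with the forward pass
#' is the identity only approximately, with residual shrinking as
#' `O(beta^2)`.
#'
#' @param fp [flow_params()].
#' @param log_rates matrix `points x N`.
#' @param with_cache keep per-step caches for backpropagation.
#' @return Matrix `points x D_hat`, or a list with `out` and `cache`.
#' @export
flow_reverse <- function(fp, log_rates, with_cache = FALSE) {
  N <- attr(fp, "N"); K <- attr(fp, "K"); beta <- attr(fp, "beta")
  D_hat <- attr(fp, "D_hat")
  if (ncol(log_rates) != N) stop("neural dimension mismatch")
  u <- log_rates
  caches <- if (with_cache) vector("list", K)
  for (k in seq_len(K)) {
    step <- mlp_forward(fp, u, with_cache = with_cache)
    if (with_cache) {
      caches[[k]] <- step$cache
      u <- u - beta * step$out
    } else {
      u <- u - beta * step
    }
  }
  z <- u[, seq_len(D_hat), drop = FALSE]
  if (with_cache) list(out = z, cache = caches) else z
}

# Backward through the reverse flow.  grad_z: points x D_hat.  Returns
# list(dlog_rates, dW, db).
flow_reverse_backward <- function(fp, cache, grad_z) {
  N <- attr(fp, "N"); K <- attr(fp, "K"); beta <- attr(fp, "beta")
  dW <- lapply(fp$W, function(w) w * 0)
  db <- lapply(fp$b, function(b) b * 0)
  g <- flow_pad(grad_z, N)
  for (k in rev(seq_len(K))) {
    bk <- mlp_backward(fp, cache[[k]], -beta * g, need_dx = TRUE)
    for (l in seq_along(dW)) {
      dW[[l]] <- dW[[l]] + bk$dW[[l]]
      db[[l]] <- db[[l]] + bk$db[[l]]
    }
    g <- g + bk$dX
  }
  list(dlog_rates = g, dW = dW, db = db)
}

#' Empirical Lipschitz bounds for the Flow update
#'
#' Lower-bounds the Lipschitz constant of the scaled update `beta * MLP` by
#' the largest pairwise difference quotient over probe points, and
#' upper-bounds it by `beta` times the product of per-layer spectral norms
#' (ReLU being 1-Lipschitz).  An upper bound below 1 certifies injectivity
#' of the Flow.
#'
#' @param fp [flow_params()].
#' @param probe_points matrix `points x N` (at least 2 rows).
#' @param max_pairs cap on the number of random probe pairs examined.
#' @return A list with `lower` and `upper` bounds on `Lip(beta * MLP)`.
#' @export
lipschitz_estimate <- function(fp, probe_points, max_pairs = 2000L) {
  if (nrow(probe_points) < 2) stop("need at least 2 probe points")
  beta <- attr(fp, "beta")
  out <- beta * mlp_forward(fp, probe_points)
  n <- nrow(probe_points)
  pairs <- utils::combn(min(n, 64L), 2L)
  if (n > 64L) {
    extra <- cbind(sample.int(n, max_pairs, replace = TRUE),
                   sample.int(n, max_pairs, replace = TRUE))
    extra <- t(extra[extra[, 1] != extra[, 2], , drop = FALSE])
    pairs <- cbind(pairs, extra)
  }
  num <- sqrt(rowSums((out[pairs[1, ], , drop = FALSE] -
                       out[pairs[2, ], , drop = FALSE])^2))
  den <- sqrt(rowSums((probe_points[pairs[1, ], , drop = FALSE] -
                       probe_points[pairs[2, ], , drop = FALSE])^2))
  lower <- if (all(den == 0)) 0 else max(num[den > 0] / den[den > 0])
  upper <- beta * prod(vapply(fp$W, function(w) svd(w, nu = 0, nv = 0)$d[1],
                              numeric(1)))
  list(lower = lower, upper = upper)
}
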