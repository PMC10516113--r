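# Small fixtures shared across test files; everything is generated in code.

tiny_benchmark <- function(n_trials = 12, T = 15, N = 6, seed = 7,
                           activation = "scaled_sigmoid") {
  generate_benchmark(n_trials = n_trials, T = T, N = N,
                     activation = activation, seed = seed)
}

tiny_config <- function(readout = "flow", D_hat = 3, epochs = 2, seed = 5,
                        ...) {
  model_config(D_hat = D_hat, readout = readout, encoder_hidden = 8,
               node_hidden = c(10), readout_hidden = c(12), flow_K = 4,
               epochs = epochs, batch_size = 8, seed = seed, ...)
}

# A flow whose MLP is identically zero (all weights and biases zero).
zero_flow <- function(D_hat, N, K = 4, beta = 0.1, hidden = c(5)) {
  fp <- flow_params(D_hat, N, hidden = hidden, K = K, beta = beta)
  fp$W <- lapply(fp$W, function(w) w * 0)
  fp$b <- lapply(fp$b, function(b) b * 0)
  fp
}

# A flow whose update MLP realizes the linear map x -> x %*% A (no bias),
# built from a one-hidden-layer ReLU net via the identity
# x = relu(x) - relu(-x).
linear_flow <- function(A, K, beta) {
  N <- nrow(A)
  fp <- flow_params(N, N, hidden = 2 * N, K = K, beta = beta)
  fp$W[[1]] <- cbind(diag(N), -diag(N))
  fp$b[[1]] <- rep(0, 2 * N)
  fp$W[[2]] <- rbind(A, -A)
  fp$b[[2]] <- rep(0, N)
  fp
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
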