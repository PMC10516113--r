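# Synthetic spiking benchmark: latent trajectories are projected onto random
# encoding vectors, the per-neuron activations are standardized to zero mean
# and unit variance over the whole dataset, a per-neuron activation function
# turns activations into firing rates (spikes/bin), and spike counts are
# Poisson samples of those rates.

#' Create a latent-to-neural embedding specification
#'
#' Encoding vectors (columns of a `D x N` matrix) are sampled elementwise
#' from U\[-0.5, 0.5\].  For the `scaled_sigmoid` activation each neuron gets
#' its own sigmoid steepness, evenly spaced on a logarithmic scale between
#' `10^0.2` and `10`, producing activation functions ranging from
#' quasi-linear to nearly step-like.  `lin_exp` and `linear` both use an
#' exponentiated affine activation (log-rate affine in the activation), the
#' classical linear-exponential embedding; `linear` is the variant name used
#' when pairing it with linear readouts in the effective-rank experiment.
#'
#' @param D latent dimensionality of the generating system.
#' @param N number of synthetic neurons.
#' @param activation one of `"scaled_sigmoid"`, `"lin_exp"`, `"linear"`.
#' @param rate_scale peak firing rate in spikes/bin: the sigmoid ceiling for
#'   `scaled_sigmoid`, and twice the geometric-mean rate for the exponential
#'   variants.
#' @param seed integer seed for the encoding matrix.
#' @return An object of class `embedding_spec`.
#' @export
make_embedding <- function(D, N, activation = c("scaled_sigmoid", "lin_exp",
                                                "linear"),
                           rate_scale = 1.0, seed = 0L) {
  activation <- match.arg(activation)
  if (D < 1 || N < 1) stop("D and N must be >= 1")
  if (rate_scale <= 0) stop("rate_scale must be positive")
  set.seed(derive_seed(seed, 23L))
  enc <- matrix(stats::runif(D * N, -0.5, 0.5), D, N)
  scales <- if (N == 1) 10^0.2 else 10^seq(0.2, 1, length.out = N)
  structure(list(encoding_matrix = enc, activation = activation,
                 sigmoid_scales = scales, rate_scale = rate_scale,
                 standardization_mean = NULL, standardization_sd = NULL),
            class = "embedding_spec")
}

#' @export
print.embedding_spec <- function(x, ...) {
  cat(sprintf("<embedding_spec> %dD -> %d neurons, activation=%s, rate_scale=%g\n",
              nrow(x$encoding_matrix), ncol(x$encoding_matrix), x$activation,
              x$rate_scale))
  invisible(x)
}

# Evaluate a neuron's activation function on (already standardized)
# activations; exposed so the metric suite can reconstruct the ground-truth
# curve for a given neuron.
activation_function <- function(emb, neuron, a) {
  switch(emb$activation,
    scaled_sigmoid = emb$rate_scale *
      stats::plogis(emb$sigmoid_scales[neuron] * a),
    lin_exp = exp(a + log(emb$rate_scale / 2)),
    linear = exp(a + log(emb$rate_scale / 2)))
}

#' Embed latent trajectories into firing rates
#'
#' Projects latents through the encoding matrix, standardizes each neuron's
#' activation trace to zero mean and unit variance over all trials and bins
#' (the statistics are stored on the returned embedding for later
#' reconstruction of the true activation functions), and applies the
#' per-neuron activation function.
#'
#' @param Z latent array `trials x T x D`.
#' @param emb an [make_embedding()] specification.
#' @return A list with `activations` and `rates` (arrays `trials x T x N`)
#'   and the updated `embedding` carrying the standardization statistics.
#' @export
embed_latents <- function(Z, emb) {
  stopifnot(inherits(emb, "embedding_spec"))
  d <- dim(Z)
  if (d[3] != nrow(emb$encoding_matrix)) {
    stop("latent dimensionality does not match the encoding matrix")
  }
  N <- ncol(emb$encoding_matrix)
  Zf <- flatten_trials(Z)
  A <- Zf %*% emb$encoding_matrix
  if (!all(is.finite(A))) stop("non-finite activations")
  mu <- colMeans(A)
  sdev <- apply(A, 2, stats::sd)
  sdev[sdev == 0] <- 1
  A <- sweep(sweep(A, 2, mu), 2, sdev, "/")
  Y <- vapply(seq_len(N), function(i) activation_function(emb, i, A[, i]),
              numeric(nrow(A)))
  emb$standardization_mean <- mu
  emb$standardization_sd <- sdev
  list(activations = unflatten_trials(A, d[1], d[2]),
       rates = unflatten_trials(Y, d[1], d[2]),
       embedding = emb)
}

#' Sample Poisson spike counts from firing rates
#'
#' @param Y nonnegative rate array (spikes/bin).
#' @param seed integer seed.
#' @return Integer array of counts with the same dimensions as `Y`.
#' @export
sample_spikes <- function(Y, seed = 0L) {
  if (any(Y < 0)) stop("negative rates")
  set.seed(derive_seed(seed, 37L))
  X <- array(stats::rpois(length(Y), as.numeric(Y)), dim = dim(Y))
  storage.mode(X) <- "integer"
  X
}

#' Split trials into training and validation sets
#'
#' Seeded random split at the trial level; indices are disjoint and
#' exhaustive, with `round(train_frac * trials)` training trials.
#'
#' @param X integer spike-count array `trials x T x N`.
#' @param train_frac fraction of trials assigned to training (default 0.8).
#' @param bin_width bin width in seconds (metadata).
#' @param seed integer seed.
#' @param ground_truth optional generating [generate_benchmark()] object kept
#'   alongside for ground-truth-aware metrics.
#' @return An object of class `spike_dataset` with fields `X`, `train_idx`,
#'   `valid_idx`, `bin_width`, `ground_truth`.
#' @export
split_dataset <- function(X, train_frac = 0.8, bin_width = 0.02, seed = 0L,
                          ground_truth = NULL) {
  n <- dim(X)[1]
  if (n < 2) stop("need at least 2 trials to split")
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  set.seed(derive_seed(seed, 53L))
  n_train <- max(1L, min(n - 1L, round(train_frac * n)))
  train_idx <- sort(sample.int(n, n_train))
  valid_idx <- setdiff(seq_len(n), train_idx)
  structure(list(X = X, train_idx = train_idx, valid_idx = valid_idx,
                 bin_width = bin_width, seed = seed,
                 ground_truth = ground_truth),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("<spike_dataset> %d trials x %d bins x %d neurons (%d train / %d valid)\n",
              d[1], d[2], d[3], length(x$train_idx), length(x$valid_idx)))
  if (!is.null(x$ground_truth)) cat("  with linked ground truth\n")
  invisible(x)
}

#' Generate the full synthetic spiking benchmark
#'
#' Integrates latent trajectories of the ground-truth system, embeds them
#' into per-neuron firing rates, samples Poisson spikes, and splits trials
#' into train/validation sets.  The `(system, embedding, seed)` triple fully
#' determines the output.
#'
#' @param n_trials number of 70-bin segments (default 1175).
#' @param T bins per segment (default 70).
#' @param N number of synthetic neurons (default 12).
#' @param system a [chaotic_system()]; default Arneodo.
#' @param activation activation family passed to [make_embedding()].
#' @param rate_scale peak rate in spikes/bin (default 1).
#' @param train_frac training fraction of the trial split (default 0.8).
#' @param bin_width bin width in seconds (default 0.02).
#' @param seed integer seed controlling initial conditions, the encoding
#'   matrix, and the Poisson draws.
#' @return An object of class `ground_truth_system` with latents `Z`,
#'   `activations`, rates `Y`, counts `X`, the `system` and `embedding`
#'   specifications, and a [split_dataset()] in `$dataset`.
#' @export
generate_benchmark <- function(n_trials = 1175L, T = 70L, N = 12L,
                               system = chaotic_system(),
                               activation = "scaled_sigmoid",
                               rate_scale = 1.0, train_frac = 0.8,
                               bin_width = 0.02, seed = 0L) {
  Z <- integrate_system(system, n_trials, T, seed = seed)
  emb <- make_embedding(system$D, N, activation = activation,
                        rate_scale = rate_scale, seed = seed)
  em <- embed_latents(Z, emb)
  X <- sample_spikes(em$rates, seed = seed)
  gts <- structure(list(Z = Z, activations = em$activations, Y = em$rates,
                        X = X, system = system, embedding = em$embedding,
                        seed = seed),
                   class = "ground_truth_system")
  gts$dataset <- split_dataset(X, train_frac = train_frac,
                               bin_width = bin_width, seed = seed,
                               ground_truth = gts)
  gts
}

#' @export
print.ground_truth_system <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("<ground_truth_system> %s, %d trials x %d bins x %d neurons\n",
              x$system$name, d[1], d[2], d[3]))
  cat(sprintf("  activation=%s, mean count=%.3f spikes/bin\n",
              x$embedding$activation, mean(x$X)))
  invisible(x)
}

## ---- array helpers -------------------------------------------------------

# trials x T x d  ->  (trials*T) x d, time fastest within trial blocks
flatten_trials <- function(A) {
  d <- dim(A)
  matrix(aperm(A, c(2, 1, 3)), d[1] * d[2], d[3])
}

unflatten_trials <- function(M, n_trials, T) {
  aperm(array(M, dim = c(T, n_trials, ncol(M))), c(2, 1, 3))
}
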