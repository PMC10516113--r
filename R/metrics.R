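# Evaluation suite: reconstruction (spike NLL, Rate R2), latent accuracy
# (State R2 and the affine alignment map it yields), readout injectivity
# (effective rank of linear readouts, cycle consistency through a probe
# regressor), embedding accuracy (per-neuron activation-function recovery),
# and co-smoothing bits per spike.

#' Poisson spike negative log-likelihood
#'
#' Mean over all bins and neurons of `lambda - x log lambda + log(x!)`,
#' i.e. the training objective plus the data-dependent constant.
#'
#' @param X observed counts.
#' @param rates inferred rates (spikes/bin), strictly positive, same shape.
#' @return Mean NLL per bin-neuron.
#' @export
spike_nll <- function(X, rates) {
  if (!identical(dim(X), dim(rates)) &&
      !(is.null(dim(X)) && length(X) == length(rates))) {
    stop("shape mismatch between counts and rates")
  }
  if (any(rates <= 0)) stop("rates must be strictly positive")
  mean(rates - X * log(rates) + lgamma(X + 1))
}

#' Per-neuron rate recovery R-squared
#'
#' Coefficient of determination between inferred and true rates per neuron
#' over all flattened bins, averaged with equal weight across neurons.
#' Neurons whose true rate has zero variance are excluded with a warning.
#'
#' @param Y_true,Y_inferred rate arrays `trials x T x N`.
#' @return Mean per-neuron R-squared.
#' @export
rate_r2 <- function(Y_true, Y_inferred) {
  stopifnot(identical(dim(Y_true), dim(Y_inferred)))
  yt <- flatten_trials(Y_true)
  yh <- flatten_trials(Y_inferred)
  sst <- colSums(sweep(yt, 2, colMeans(yt))^2)
  keep <- sst > 0
  if (!all(keep)) warning(sum(!keep), " zero-variance neuron(s) excluded")
  sse <- colSums((yt - yh)^2)
  mean(1 - sse[keep] / sst[keep])
}

#' Latent state recovery R-squared and alignment map
#'
#' Fits a single multioutput affine regression from true latent trajectories
#' to inferred ones over all flattened timepoints and reports the
#' variance-weighted R-squared `1 - sum(SSE_j) / sum(SST_j)` over inferred
#' dimensions.  The fitted map (used again for projecting ground-truth
#' fixed points and encoding vectors into model latent space) is returned.
#' A high value means the inferred latents contain no structure beyond an
#' affine image of the truth; note it can be attained trivially by
#' low-dimensional projections of the truth, so it is read together with
#' reconstruction metrics.
#'
#' @param Z_true array `trials x T x D`.
#' @param Z_hat array `trials x T x D_hat`.
#' @return A list of class `state_r2` with `r2` and `map` (list with
#'   `linear` `D x D_hat`, `offset` length `D_hat`, and `r2`).
#' @export
state_r2 <- function(Z_true, Z_hat) {
  dt <- dim(Z_true); dh <- dim(Z_hat)
  stopifnot(dt[1] == dh[1], dt[2] == dh[2])
  Xf <- flatten_trials(Z_true)
  Yf <- flatten_trials(Z_hat)
  if (nrow(Xf) < ncol(Xf) + 1) stop("fewer points than D + 1")
  Xd <- cbind(1, Xf)
  beta <- qr.coef(qr(Xd), Yf)
  beta[is.na(beta)] <- 0
  resid <- Yf - Xd %*% beta
  sst <- sum(sweep(Yf, 2, colMeans(Yf))^2)
  r2 <- 1 - sum(resid^2) / sst
  map <- list(linear = beta[-1, , drop = FALSE], offset = beta[1, ], r2 = r2)
  structure(list(r2 = r2, map = map), class = "state_r2")
}

#' Effective rank of a matrix
#'
#' Exponentiated Shannon entropy of the nuclear-norm-normalized singular
#' value distribution: `erank = exp(-sum p_i log p_i)` with
#' `p_i = sigma_i / sum_j sigma_j`.  A continuous proxy for rank, between 1
#' and `min(dim(M))`.
#'
#' @param M a nonzero numeric matrix (e.g. a linear readout weight matrix).
#' @return The effective rank (numeric scalar).
#' @export
effective_rank <- function(M) {
  M <- as.matrix(M)
  s <- svd(M, nu = 0, nv = 0)$d
  if (sum(s) == 0) stop("effective rank undefined for the zero matrix")
  p <- s / sum(s)
  p <- p[p > 0]
  exp(-sum(p * log(p)))
}

#' Cycle consistency of a readout
#'
#' Measures how well inferred latents can be recovered from predicted
#' log-rates: for each noise level sigma, corrupts the log-rates with
#' Gaussian noise, fits a fresh MLP probe on a training split and reports
#' the held-out variance-weighted R-squared of latent prediction.  An
#' empirical surrogate for readout injectivity; a non-injective readout
#' collapses latent directions that the probe then cannot recover,
#' especially under noise.
#'
#' @param log_rates array `trials x T x N` of predicted log-rates.
#' @param Z_hat array `trials x T x D_hat` of inferred latents.
#' @param noise_levels nonnegative noise standard deviations (default
#'   `c(0, 0.1, 0.25, 0.5, 1)`).
#' @param seed integer seed for noise, probe init and the probe split.
#' @param hidden probe MLP hidden widths (default `c(64, 64)`).
#' @param epochs probe training epochs (default 150).
#' @param max_points random subsample cap on flattened timepoints.
#' @return Numeric vector of held-out R-squared, one per noise level.
#' @export
cycle_consistency <- function(log_rates, Z_hat, noise_levels = c(0, 0.1, 0.25,
                                                                 0.5, 1),
                              seed = 0L, hidden = c(64L, 64L), epochs = 150L,
                              max_points = 6000L) {
  stopifnot(all(noise_levels >= 0))
  L <- flatten_trials(log_rates)
  Z <- flatten_trials(Z_hat)
  if (all(apply(Z, 2, stats::sd) < 1e-12)) stop("degenerate constant latents")
  set.seed(derive_seed(seed, 131L))
  if (nrow(L) > max_points) {
    keep <- sample.int(nrow(L), max_points)
    L <- L[keep, , drop = FALSE]
    Z <- Z[keep, , drop = FALSE]
  }
  n <- nrow(L)
  tr <- sort(sample.int(n, round(0.8 * n)))
  te <- setdiff(seq_len(n), tr)
  vapply(noise_levels, function(sig) {
    Ln <- L + matrix(stats::rnorm(length(L), sd = sig), nrow(L), ncol(L))
    fit_probe_r2(Ln[tr, , drop = FALSE], Z[tr, , drop = FALSE],
                 Ln[te, , drop = FALSE], Z[te, , drop = FALSE],
                 hidden = hidden, epochs = epochs)
  }, numeric(1))
}

# Small seeded MLP regressor (squared error, Adam, minibatches) used as the
# cycle-consistency probe; returns held-out variance-weighted R2.
fit_probe_r2 <- function(X_tr, Y_tr, X_te, Y_te, hidden = c(64L, 64L),
                         epochs = 150L, lr = 2e-3, batch = 512L) {
  mu <- colMeans(X_tr); sdv <- apply(X_tr, 2, stats::sd); sdv[sdv == 0] <- 1
  X_tr <- sweep(sweep(X_tr, 2, mu), 2, sdv, "/")
  X_te <- sweep(sweep(X_te, 2, mu), 2, sdv, "/")
  mlp <- init_mlp(c(ncol(X_tr), hidden, ncol(Y_tr)), act = "relu")
  opt <- adam_init(mlp)
  n <- nrow(X_tr)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (s in seq(1L, n, by = batch)) {
      idx <- ord[s:min(s + batch - 1L, n)]
      fw <- mlp_forward(mlp, X_tr[idx, , drop = FALSE], with_cache = TRUE)
      g <- 2 * (fw$out - Y_tr[idx, , drop = FALSE]) / length(idx)
      bk <- mlp_backward(mlp, fw$cache, g, need_dx = FALSE)
      upd <- adam_step(mlp, list(W = bk$dW, b = bk$db), opt, lr = lr)
      mlp <- upd$params
      opt <- upd$state
    }
  }
  pred <- mlp_forward(mlp, X_te)
  sst <- sum(sweep(Y_te, 2, colMeans(Y_te))^2)
  1 - sum((pred - Y_te)^2) / sst
}

#' Per-neuron activation-function recovery
#'
#' For each synthetic neuron: (1) carry its ground-truth encoding vector
#' into model latent space through the State-R2 alignment map -- encoding
#' vectors transform as covectors, so the linear part enters through its
#' pseudo-inverse; (2) project the inferred latents onto the transformed
#' vector to obtain the neuron's predicted activations; (3) align the
#' predicted activation axis to the true standardized activation axis by
#' least squares; (4) regress the ground-truth activation curve
#' (reconstructed from the stored standardization statistics and the
#' neuron's activation function) evaluated at the aligned activations on
#' the predicted rates.  The R-squared of that affine fit measures how well
#' the model recovered the neuron's activation nonlinearity.
#'
#' @param gts a [generate_benchmark()] object.
#' @param Z_hat inferred latents for a set of trials, `trials x T x D_hat`.
#' @param rates_inferred inferred rates for the same trials.
#' @param map the `map` element of a [state_r2()] fit from the same model.
#' @param trial_idx indices of the trials within the ground truth.
#' @return Numeric vector of per-neuron R-squared values.
#' @export
activation_recovery <- function(gts, Z_hat, rates_inferred, map,
                                trial_idx = seq_len(dim(Z_hat)[1])) {
  if (is.null(gts$embedding$standardization_mean)) {
    stop("ground truth lacks standardization statistics")
  }
  emb <- gts$embedding
  N <- ncol(emb$encoding_matrix)
  Zh <- flatten_trials(Z_hat)
  Yh <- flatten_trials(rates_inferred)
  A_true <- flatten_trials(gts$activations[trial_idx, , , drop = FALSE])
  G <- pinv(map$linear)
  vapply(seq_len(N), function(i) {
    v <- as.numeric(G %*% emb$encoding_matrix[, i])
    a_pred <- as.numeric(Zh %*% v)
    if (stats::sd(a_pred) == 0) return(0)
    # align the predicted activation axis with the true standardized axis
    fit <- stats::lm.fit(cbind(1, a_pred), A_true[, i])
    a_aligned <- cbind(1, a_pred) %*% fit$coefficients
    curve_true <- activation_function(emb, i, as.numeric(a_aligned))
    af <- stats::lm(curve_true ~ Yh[, i])
    summary_r2(af, curve_true)
  }, numeric(1))
}

summary_r2 <- function(fit, y) {
  1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}

# Moore-Penrose pseudo-inverse via SVD.
pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d, 0)
  if (!any(pos)) stop("cannot invert a zero map")
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Co-smoothing bits per spike
#'
#' Likelihood improvement of model rates over a per-neuron mean-rate null
#' on held-out spikes, normalized by the total spike count:
#' `(NLL_null - NLL_model) / (n_spikes * log 2)` with NLLs summed over all
#' bins.
#'
#' @param X_heldout observed counts.
#' @param rates_heldout model-inferred rates, same shape.
#' @param null_rates per-neuron mean-rate null, broadcastable to `X_heldout`
#'   (vector of length N or full array).
#' @return Bits per spike (numeric scalar).
#' @export
co_bps <- function(X_heldout, rates_heldout, null_rates) {
  stopifnot(identical(dim(X_heldout), dim(rates_heldout)))
  total_spikes <- sum(X_heldout)
  if (total_spikes == 0) stop("no spikes in held-out data")
  if (is.null(dim(null_rates))) {
    d <- dim(X_heldout)
    null_rates <- aperm(array(null_rates, dim = c(d[3], d[1], d[2])),
                        c(2, 3, 1))
  }
  nll <- function(lam) sum(lam - X_heldout * log(lam) + lgamma(X_heldout + 1))
  (nll(null_rates) - nll(rates_heldout)) / (total_spikes * log(2))
}
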