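# Sequential autoencoder variants for Poisson spiking data.
#
# A bidirectional GRU consumes the spike-count window x_{1:T}; the
# concatenated final hidden states are mapped to an initial condition z0 by
# phi (an affine map for linear/MLP readouts; for Flow readouts an affine
# map to neural space followed by the Flow's reverse pass and trimming).
# A neural-ODE generator unrolls z0 with Euler steps of one bin,
# z_{t+1} = z_t + alpha * MLP(z_t), and the readout maps each latent state
# to log-rates; rates are exp(log-rates).  Training minimizes the Poisson
# negative log-likelihood of the observed counts by plain backpropagation
# through the whole unrolled computation.

#' Configuration of a sequential autoencoder
#'
#' @param D_hat model state dimensionality.
#' @param readout `"flow"` (ODIN), `"mlp"` (MLP-NODE) or `"linear"`
#'   (Linear-NODE).
#' @param encoder_hidden hidden units per GRU direction (default 100).
#' @param node_hidden hidden widths of the generator MLP (default
#'   `c(128, 128)`, tanh; smooth activations keep the learned vector field
#'   amenable to fixed-point analysis).
#' @param alpha scale on the generator MLP output (default 0.1), stabilizing
#'   early training.
#' @param readout_hidden hidden widths of the MLP/Flow readout network
#'   (default `c(150, 150)`, ReLU).
#' @param flow_K number of Flow refinement steps (default 20).
#' @param beta scale on the Flow MLP output (default 0.1).
#' @param epochs training epochs (default 1500).
#' @param learning_rate Adam step size (default 5e-3).
#' @param batch_size trials per minibatch (default 64).
#' @param clip_norm global gradient-norm clip (default 200).
#' @param weight_decay L2 coefficient added to the gradient (default 0, no
#'   regularization).  A small value (e.g. 1e-5) lets parameters that
#'   receive no likelihood gradient decay to zero instead of persisting at
#'   their random initialization, which matters when inspecting readout
#'   weight matrices (effective rank).
#' @param seed integer seed for initialization and batching.
#' @return An object of class `model_config`.
#' @export
model_config <- function(D_hat = 3L, readout = c("flow", "mlp", "linear"),
                         encoder_hidden = 100L, node_hidden = c(128L, 128L),
                         alpha = 0.1, readout_hidden = c(150L, 150L),
                         flow_K = 20L, beta = 0.1, epochs = 1500L,
                         learning_rate = 5e-3, batch_size = 64L,
                         clip_norm = 200, weight_decay = 0, seed = 0L) {
  readout <- match.arg(readout)
  if (D_hat < 1) stop("D_hat must be >= 1")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (beta <= 0 || beta > 1) stop("beta must be in (0, 1]")
  if (flow_K < 1) stop("flow_K must be >= 1")
  structure(list(D_hat = as.integer(D_hat), readout = readout,
                 encoder_hidden = as.integer(encoder_hidden),
                 node_hidden = as.integer(node_hidden), alpha = alpha,
                 readout_hidden = as.integer(readout_hidden),
                 flow_K = as.integer(flow_K), beta = beta,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), clip_norm = clip_norm,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "model_config")
}

#' Initialize an untrained sequential autoencoder
#'
#' @param config a [model_config()].
#' @param N number of observed neurons.
#' @return An object of class `odin_model` holding the parameter tree
#'   (`enc_f`, `enc_b`, `phi`, `node`, `readout`), the config, and an empty
#'   training log.
#' @export
init_model <- function(config, N) {
  stopifnot(inherits(config, "model_config"))
  if (config$readout == "flow" && config$D_hat > N) {
    stop("flow readout requires D_hat <= N")
  }
  set.seed(derive_seed(config$seed, 71L))
  H <- config$encoder_hidden
  phi_out <- if (config$readout == "flow") N else config$D_hat
  readout <- switch(config$readout,
    linear = init_mlp(c(config$D_hat, N), act = "relu"),
    mlp = init_mlp(c(config$D_hat, config$readout_hidden, N), act = "relu"),
    flow = flow_params(config$D_hat, N, hidden = config$readout_hidden,
                       K = config$flow_K, beta = config$beta))
  params <- list(
    enc_f = init_gru(N, H),
    enc_b = init_gru(N, H),
    phi = init_linear(2L * H, phi_out),
    node = init_mlp(c(config$D_hat, config$node_hidden, config$D_hat),
                    act = "tanh", zero_last = TRUE),
    readout = readout)
  structure(list(params = params, config = config, N = as.integer(N),
                 log = data.frame()),
            class = "odin_model")
}

#' @export
print.odin_model <- function(x, ...) {
  kind <- switch(x$config$readout, flow = "ODIN", mlp = "MLP-NODE",
                 linear = "Linear-NODE")
  cat(sprintf("<odin_model> %s: D_hat=%d, N=%d, %s\n", kind, x$config$D_hat,
              x$N, if (nrow(x$log)) sprintf("trained %d epochs", max(x$log$epoch))
                   else "untrained"))
  if (nrow(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  final train NLL %.4f / valid NLL %.4f\n",
                last$train_nll, last$valid_nll))
  }
  invisible(x)
}

# trials x T x N  ->  GRU cube (trials x N x T)
spikes_to_cube <- function(X) aperm(X, c(1, 3, 2))

#' Encode a spike window into the final bidirectional hidden state
#'
#' @param model an [init_model()] object.
#' @param X spike-count array `trials x T x N`.
#' @param with_cache keep caches for backpropagation.
#' @return Matrix `trials x 2*encoder_hidden` (forward | backward final
#'   states), or a list with caches when `with_cache`.
#' @export
encode <- function(model, X, with_cache = FALSE) {
  if (length(dim(X)) != 3 || dim(X)[2] < 1) stop("X must be trials x T x N with T >= 1")
  cube_f <- spikes_to_cube(X)
  cube_b <- cube_f[, , rev(seq_len(dim(cube_f)[3])), drop = FALSE]
  f <- gru_forward(model$params$enc_f, cube_f, with_cache = with_cache)
  b <- gru_forward(model$params$enc_b, cube_b, with_cache = with_cache)
  if (with_cache) {
    list(hT = cbind(f$hT, b$hT), cache = list(f = f, b = b,
                                              cube_f = cube_f, cube_b = cube_b))
  } else {
    cbind(f, b)
  }
}

#' Map the encoder state to the initial condition
#'
#' For linear/MLP readouts phi is an affine map to the model state space.
#' For Flow readouts phi is an affine map to neural space followed by the
#' Flow's reverse pass, so the initial condition lives in the same latent
#' chart as the readout's preimage.
#'
#' @param model an `odin_model`.
#' @param hT encoder output `trials x 2*encoder_hidden`.
#' @param with_cache keep caches for backpropagation.
#' @return Matrix `trials x D_hat`, or a list with caches.
#' @export
init_condition <- function(model, hT, with_cache = FALSE) {
  a <- hT %*% model$params$phi$W + matrix(model$params$phi$b, nrow(hT),
                                          length(model$params$phi$b),
                                          byrow = TRUE)
  if (model$config$readout == "flow") {
    rev_out <- flow_reverse(model$params$readout, a, with_cache = with_cache)
    if (with_cache) {
      list(z0 = rev_out$out, cache = list(hT = hT, affine = a,
                                          flow_rev = rev_out$cache))
    } else {
      rev_out
    }
  } else {
    if (with_cache) list(z0 = a, cache = list(hT = hT)) else a
  }
}

#' Unroll the generator from initial conditions
#'
#' Euler steps of one bin: `z_{t+1} = z_t + alpha * MLP(z_t)`.  The returned
#' trajectory contains states t = 1..T, with z_1 one step from z0 so the
#' output length matches the observation window.
#'
#' @param model an `odin_model`.
#' @param z0 matrix `trials x D_hat`.
#' @param T number of states to generate.
#' @param with_cache keep per-step caches for backpropagation.
#' @return Array `trials x T x D_hat`, or a list with caches.
#' @export
unroll_dynamics <- function(model, z0, T, with_cache = FALSE) {
  if (T < 1) stop("T must be >= 1")
  alpha <- model$config$alpha
  node <- model$params$node
  B <- nrow(z0)
  Z <- array(0, dim = c(B, T, ncol(z0)))
  caches <- if (with_cache) vector("list", T)
  z <- z0
  for (t in seq_len(T)) {
    step <- mlp_forward(node, z, with_cache = with_cache)
    if (with_cache) {
      caches[[t]] <- step$cache
      z <- z + alpha * step$out
    } else {
      z <- z + alpha * step
    }
    if (!all(is.finite(z))) stop("non-finite latent state at unroll step ", t)
    Z[, t, ] <- z
  }
  if (with_cache) list(Z = Z, cache = caches) else Z
}

#' Map latent trajectories to firing rates
#'
#' Dispatches to the configured readout and exponentiates to rates.
#'
#' @param model an `odin_model`.
#' @param Z_hat latent array `trials x T x D_hat`.
#' @param with_cache keep caches for backpropagation.
#' @return A list with `log_rates` and `rates` (arrays `trials x T x N`),
#'   plus caches when requested.
#' @export
readout_rates <- function(model, Z_hat, with_cache = FALSE) {
  d <- dim(Z_hat)
  Zf <- flatten_trials(Z_hat)
  if (model$config$readout == "flow") {
    out <- flow_forward(model$params$readout, Zf, with_cache = with_cache)
  } else {
    out <- mlp_forward(model$params$readout, Zf, with_cache = with_cache)
  }
  lr_flat <- if (with_cache) out$out else out
  log_rates <- unflatten_trials(lr_flat, d[1], d[2])
  res <- list(log_rates = log_rates, rates = exp(log_rates))
  if (with_cache) res$cache <- out$cache
  res
}

# Full forward pass with caches; X: trials x T x N.
forward_pass <- function(model, X, with_cache = FALSE) {
  enc <- encode(model, X, with_cache = with_cache)
  hT <- if (with_cache) enc$hT else enc
  ic <- init_condition(model, hT, with_cache = with_cache)
  z0 <- if (with_cache) ic$z0 else ic
  un <- unroll_dynamics(model, z0, dim(X)[2], with_cache = with_cache)
  Z_hat <- if (with_cache) un$Z else un
  ro <- readout_rates(model, Z_hat, with_cache = with_cache)
  list(hT = hT, z0 = z0, Z_hat = Z_hat, log_rates = ro$log_rates,
       rates = ro$rates,
       cache = if (with_cache) list(enc = enc$cache, ic = ic$cache,
                                    un = un$cache, ro = ro$cache))
}

# Training objective: mean over bins/neurons of (rate - x * log rate); the
# constant log(x!) term is dropped here and restored by spike_nll() for
# reporting.
poisson_objective <- function(X, log_rates) {
  mean(exp(log_rates) - X * log_rates)
}

# Start the readout at the per-neuron mean log-rate so early epochs fit
# deviations rather than the overall scale (linear/MLP readouts only; the
# flow readout's output level is implicit in its residual structure).  Part
# of the deterministic initialization performed by train_model().
init_output_bias <- function(model, X_train) {
  if (model$config$readout %in% c("linear", "mlp")) {
    mean_rates <- pmax(apply(X_train, 3, mean), 1e-3)
    L <- length(model$params$readout$b)
    model$params$readout$b[[L]] <- log(mean_rates)
  }
  model
}

# Full backward pass; returns gradient tree parallel to model$params.
backward_pass <- function(model, X, fwd) {
  cfg <- model$config
  d <- dim(X)
  n_el <- prod(d)
  # d objective / d log_rates
  g_lr <- (exp(fwd$log_rates) - X) / n_el
  g_lr_flat <- flatten_trials(g_lr)

  grads <- list()
  if (cfg$readout == "flow") {
    fb <- flow_forward_backward(model$params$readout, fwd$cache$ro, g_lr_flat)
    grads$readout <- list(W = fb$dW, b = fb$db)
    dZf <- fb$dz
  } else {
    mb <- mlp_backward(model$params$readout, fwd$cache$ro, g_lr_flat,
                       need_dx = TRUE)
    grads$readout <- list(W = mb$dW, b = mb$db)
    dZf <- mb$dX
  }
  dZ <- unflatten_trials(dZf, d[1], d[2])

  # back through the Euler unroll
  node <- model$params$node
  dW_node <- lapply(node$W, function(w) w * 0)
  db_node <- lapply(node$b, function(b) b * 0)
  carry <- matrix(0, d[1], cfg$D_hat)
  for (t in rev(seq_len(d[2]))) {
    g <- dZ[, t, , drop = TRUE]
    if (is.null(dim(g))) g <- matrix(g, d[1], cfg$D_hat)
    g <- g + carry
    nb <- mlp_backward(node, fwd$cache$un[[t]], cfg$alpha * g, need_dx = TRUE)
    for (l in seq_along(dW_node)) {
      dW_node[[l]] <- dW_node[[l]] + nb$dW[[l]]
      db_node[[l]] <- db_node[[l]] + nb$db[[l]]
    }
    carry <- g + nb$dX
  }
  grads$node <- list(W = dW_node, b = db_node)
  dz0 <- carry

  # back through phi (and the flow reverse pass for flow readouts)
  if (cfg$readout == "flow") {
    rb <- flow_reverse_backward(model$params$readout, fwd$cache$ic$flow_rev, dz0)
    for (l in seq_along(grads$readout$W)) {
      grads$readout$W[[l]] <- grads$readout$W[[l]] + rb$dW[[l]]
      grads$readout$b[[l]] <- grads$readout$b[[l]] + rb$db[[l]]
    }
    da <- rb$dlog_rates
  } else {
    da <- dz0
  }
  hT <- fwd$cache$ic$hT
  grads$phi <- list(W = t(hT) %*% da, b = colSums(da))
  dhT <- da %*% t(model$params$phi$W)

  # back through the bidirectional encoder
  H <- cfg$encoder_hidden
  gf <- gru_backward(model$params$enc_f, fwd$cache$enc$cube_f,
                     fwd$cache$enc$f, dhT[, seq_len(H), drop = FALSE])
  gb <- gru_backward(model$params$enc_b, fwd$cache$enc$cube_b,
                     fwd$cache$enc$b, dhT[, H + seq_len(H), drop = FALSE])
  grads$enc_f <- gf[c("dW", "dU", "dbi", "dbh")]
  names(grads$enc_f) <- c("W", "U", "bi", "bh")
  grads$enc_b <- gb[c("dW", "dU", "dbi", "dbh")]
  names(grads$enc_b) <- c("W", "U", "bi", "bh")

  grads[names(model$params)]
}

# Objective (and gradients) for one batch; used by training and by the
# finite-difference gradient checks.
batch_loss <- function(model, X, with_grads = FALSE) {
  fwd <- forward_pass(model, X, with_cache = with_grads)
  loss <- poisson_objective(X, fwd$log_rates)
  if (!with_grads) return(loss)
  list(loss = loss, grads = backward_pass(model, X, fwd))
}

#' Train a sequential autoencoder
#'
#' Minimizes the Poisson negative log-likelihood of the training trials with
#' Adam over minibatches of whole trials.  The per-epoch log reports the
#' full spike NLL (including the `log(x!)` constant) on the training and
#' validation splits.  Deterministic given the config seed up to
#' floating-point reassociation in the BLAS.
#'
#' @param dataset a [split_dataset()] object.
#' @param config a [model_config()].
#' @param eval_every epochs between validation evaluations (default 10).
#' @param verbose print progress every `eval_every` epochs.
#' @param keep_best return the parameters with the lowest validation NLL
#'   seen at evaluation points rather than the final ones (default TRUE;
#'   long runs can overfit the Poisson likelihood).
#' @param hook optional monitoring callback `function(model, epoch)` called
#'   at every evaluation point.
#' @return A trained `odin_model` with the training log in `$log`.
#' @export
train_model <- function(dataset, config, eval_every = 10L, verbose = FALSE,
                        keep_best = TRUE, hook = NULL) {
  stopifnot(inherits(dataset, "spike_dataset"))
  model <- init_model(config, dim(dataset$X)[3])
  X_train <- dataset$X[dataset$train_idx, , , drop = FALSE]
  X_valid <- dataset$X[dataset$valid_idx, , , drop = FALSE]
  const_train <- mean(lgamma(X_train + 1))
  const_valid <- if (length(dataset$valid_idx)) mean(lgamma(X_valid + 1)) else NA
  n_train <- dim(X_train)[1]
  model <- init_output_bias(model, X_train)
  opt <- adam_init(model$params)
  set.seed(derive_seed(config$seed, 97L))
  log_rows <- list()
  best_nll <- Inf
  best_params <- NULL
  for (epoch in seq_len(config$epochs)) {
    # step-decayed Adam: drop the step size for the final quarter of
    # training to settle oscillations near the optimum
    lr_epoch <- config$learning_rate *
      (if (epoch > 0.75 * config$epochs) 0.3 else 1)
    ord <- sample.int(n_train)
    starts <- seq(1L, n_train, by = config$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n_train)]
      lb <- batch_loss(model, X_train[idx, , , drop = FALSE], with_grads = TRUE)
      if (!is.finite(lb$loss)) {
        stop(sprintf("NaN/Inf loss at epoch %d, batch starting %d", epoch, s))
      }
      if (config$weight_decay > 0) {
        lb$grads <- param_map2(lb$grads, model$params, function(g, p) {
          g + config$weight_decay * as.numeric(p)
        })
      }
      upd <- adam_step(model$params, lb$grads, opt, lr = lr_epoch,
                       clip_norm = config$clip_norm)
      model$params <- upd$params
      opt <- upd$state
      epoch_loss <- epoch_loss + lb$loss * length(idx)
    }
    if (epoch %% eval_every == 0L || epoch == config$epochs) {
      valid_nll <- if (length(dataset$valid_idx)) {
        batch_loss(model, X_valid) + const_valid
      } else NA
      row <- data.frame(epoch = epoch,
                        train_nll = epoch_loss / n_train + const_train,
                        valid_nll = valid_nll)
      log_rows[[length(log_rows) + 1L]] <- row
      if (keep_best && is.finite(valid_nll) && valid_nll < best_nll) {
        best_nll <- valid_nll
        best_params <- model$params
      }
      if (!is.null(hook)) hook(model, epoch)
      if (verbose) {
        message(sprintf("epoch %4d  train NLL %.4f  valid NLL %.4f",
                        epoch, row$train_nll, row$valid_nll))
      }
    }
  }
  model$log <- do.call(rbind, log_rows)
  if (keep_best && !is.null(best_params)) {
    model$params <- best_params
    model$best_valid_nll <- best_nll
  }
  model
}

#' Run the trained model on a dataset split
#'
#' Pure forward pass (no parameter mutation): encoder, initial-condition
#' map, generator unroll, readout.
#'
#' @param model a trained `odin_model`.
#' @param dataset a [split_dataset()] object with the same neuron count the
#'   model was trained on.
#' @param split `"valid"`, `"train"` or `"all"`.
#' @return An object of class `latent_inference` with `z0_hat`
#'   (`trials x D_hat`), `Z_hat` (`trials x T x D_hat`), `log_rates` and
#'   `rates` (`trials x T x N`), and the trial indices used.
#' @export
infer <- function(model, dataset, split = c("valid", "train", "all")) {
  split <- match.arg(split)
  stopifnot(inherits(dataset, "spike_dataset"))
  if (dim(dataset$X)[3] != model$N) {
    stop(sprintf("dataset has %d neurons but model was built for %d",
                 dim(dataset$X)[3], model$N))
  }
  idx <- switch(split, valid = dataset$valid_idx, train = dataset$train_idx,
                all = seq_len(dim(dataset$X)[1]))
  X <- dataset$X[idx, , , drop = FALSE]
  fwd <- forward_pass(model, X, with_cache = FALSE)
  structure(list(z0_hat = fwd$z0, Z_hat = fwd$Z_hat,
                 log_rates = fwd$log_rates, rates = fwd$rates,
                 trial_idx = idx, split = split),
            class = "latent_inference")
}

#' @export
print.latent_inference <- function(x, ...) {
  d <- dim(x$Z_hat)
  cat(sprintf("<latent_inference> %s split: %d trials x %d bins, D_hat=%d\n",
              x$split, d[1], d[2], d[3]))
  invisible(x)
}
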