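# odinflow

Sequential autoencoders for recovering low-dimensional latent dynamical
systems from Poisson spiking observations, for computational neuroscientists
who want *interpretable* latent dynamics rather than only good
reconstruction.

Binned spike counts `x_{1:T}` are modeled as

    z_{t+1} = z_t + f(z_t)        latent dynamics
    y_t     = exp g(z_t)          firing rates (spikes/bin)
    x_t     ~ Poisson(y_t)        observed counts

A bidirectional GRU encoder maps a spike window to an initial condition
`ẑ₀`; a neural-ODE generator unrolls it with Euler steps of one bin,
`ẑ_{t+1} = ẑ_t + α·MLP(ẑ_t)` (α = 0.1); and a readout `ĝ` maps latent
states to log-rates. Three readouts are provided:

* **linear** (Linear-NODE),
* **MLP** (MLP-NODE),
* **Flow** (ODIN): zero-pad `ẑ_t` to the neural dimensionality and apply
  K = 20 small residual refinements `s_{k+1} = s_k + β·MLP(s_k)`
  (β = 0.1). The Flow is approximately *injective* — distinct latent states
  must produce distinct predicted activity — which prevents the generator
  from inventing latent structure invisible to the likelihood, and it is
  approximately invertible by serially subtracting the same MLP, which is
  how initial conditions are formed from the encoder state.

All networks and their gradients are implemented in the package (C++
kernels for the dense layers, exact backpropagation through the encoder,
unroll and Flow recursions), trained by Adam on the Poisson negative
log-likelihood.

The package ships the synthetic benchmark used to validate latent
recovery (chaotic Arneodo trajectories nonlinearly embedded into spiking
via per-neuron scaled sigmoids), a metric suite (spike NLL, Rate R²,
State R², effective rank, cycle consistency, activation-function
recovery, co-smoothing bits/spike) and fixed-point analysis of trained
generators (location, Jacobian eigenvalues against the unit circle,
stability classification).

## Worked example

```r
library(odinflow)

# 560 trials x 70 bins x 12 neurons of Poisson spikes from the Arneodo
# system, nonlinearly embedded through scaled sigmoids
gts <- generate_benchmark(n_trials = 560, seed = 42)

# desk-scale ODIN (Flow readout) at the true dimensionality
cfg <- model_config(D_hat = 3, readout = "flow", encoder_hidden = 48,
                    node_hidden = c(96, 96), readout_hidden = 64,
                    epochs = 160, batch_size = 60, seed = 101)
model <- train_model(gts$dataset, cfg)      # ~9 min on one CPU core

ev <- evaluate_model(model, gts)
round(ev$metrics, 3)
#>     spike_nll       rate_r2      state_r2 activation_r2
#>         0.789         0.920         0.909         0.901

# fixed points of the learned dynamics, compared with the analytic truth
fps <- find_fixed_points(model_dynamics(model),
                         fp_candidates(ev$inference$Z_hat, 256, seed = 1))
truth <- arneodo_fixed_points()
compare_fixed_points(fps, truth$locations, truth$eig_discrete,
                     ev$state_fit$map)$matches
```

`state_r2` close to 1 means the inferred latents are an affine image of
the true Arneodo states (no invented structure); `rate_r2` measures
recovery of the true per-neuron firing rates from spikes alone;
`activation_r2` measures recovery of each neuron's sigmoid activation
curve. The three recovered fixed points correspond to the cubic roots of
the Arneodo nullcline, with the central one carrying rotational (complex)
eigenvalues.

A command-line front end wrapping these functions is installed at
`inst/cli/odinflow.R` (`generate`, `train`, `infer`, `evaluate`,
`find-fps`, `sweep`), and `run_sweep()` drives multi-model experiment
grids into tidy CSV tables.

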