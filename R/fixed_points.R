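# Fixed-point analysis of discrete-time latent dynamics z -> z + f(z).
# Candidate locations minimize q(z) = 0.5 * ||f(z)||^2 by quasi-Newton
# descent from many seeds drawn near observed latent states; converged
# minima below tolerance are deduplicated and characterized by the
# eigenvalues of the update-map Jacobian I + df/dz, whose unit-circle
# position separates locally attractive from repulsive behavior.

# Dynamics-function interface: a list with
#   f(Z)   : matrix of displacements (rows = states)
#   jac(z) : optional analytic Jacobian of f at a single state
#   D      : state dimensionality
#' Dynamics function of a trained generator
#'
#' Wraps the model's Euler update displacement `alpha * MLP(z)` in the
#' dynamics-function interface used by [find_fixed_points()], with an exact
#' analytic Jacobian.
#'
#' @param model a trained `odin_model`.
#' @return A list with `f`, `jac` and `D`.
#' @export
model_dynamics <- function(model) {
  node <- model$params$node
  alpha <- model$config$alpha
  list(
    f = function(Z) alpha * mlp_forward(node, Z),
    jac = function(z) alpha * mlp_jacobian(node, z),
    D = model$config$D_hat
  )
}

#' Locate fixed points of a discrete dynamics function
#'
#' Runs BFGS minimization of `q(z) = 0.5 ||f(z)||^2` from each candidate
#' seed, keeps converged points with `q < tol`, and deduplicates by radius
#' (keeping the lowest-residual representative).  Deterministic given the
#' seeds.
#'
#' @param dyn a dynamics function (see [model_dynamics()],
#'   [discrete_dynamics()]).
#' @param candidates matrix of seed points (rows), e.g. sampled from
#'   inferred latents via [fp_candidates()].
#' @param tol keep minima with `q` below this (default 1e-6).
#' @param dedup_radius merge fixed points closer than this (default 1% of
#'   the candidate cloud's range).
#' @param max_iter BFGS iteration cap per seed.
#' @return An object of class `fixed_point_set`: `locations` (M x D),
#'   `residuals` (vector-field norms), `jacobians` (list of update-map
#'   Jacobians `I + df/dz`), `eigenvalues` (list of complex vectors),
#'   `labels` (stability classification).
#' @export
find_fixed_points <- function(dyn, candidates, tol = 1e-6,
                              dedup_radius = NULL, max_iter = 500L) {
  candidates <- as.matrix(candidates)
  if (nrow(candidates) < 1) stop("need at least one candidate seed")
  if (is.null(dedup_radius)) {
    rng <- max(apply(candidates, 2, function(x) diff(range(x))), 1)
    dedup_radius <- 0.01 * rng
  }
  q_fn <- function(z) 0.5 * sum(dyn$f(matrix(z, nrow = 1))^2)
  g_fn <- function(z) {
    fz <- as.numeric(dyn$f(matrix(z, nrow = 1)))
    J <- dyn_jacobian(dyn, z)
    as.numeric(crossprod(J, fz))
  }
  found <- list()
  for (i in seq_len(nrow(candidates))) {
    opt <- try(stats::optim(candidates[i, ], q_fn, g_fn, method = "BFGS",
                            control = list(maxit = max_iter,
                                           reltol = 1e-14)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (opt$value < tol) found[[length(found) + 1L]] <- opt$par
  }
  if (!length(found)) {
    warning("no candidate converged below tolerance; empty fixed-point set")
    return(empty_fp_set(dyn$D))
  }
  locs <- do.call(rbind, found)
  res <- sqrt(2 * apply(locs, 1, q_fn))
  ord <- order(res)
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) ||
        min(sqrt(rowSums((locs[keep, , drop = FALSE] -
                          matrix(locs[i, ], length(keep), ncol(locs),
                                 byrow = TRUE))^2))) > dedup_radius) {
      keep <- c(keep, i)
    }
  }
  locs <- locs[keep, , drop = FALSE]
  res <- res[keep]
  jacs <- lapply(seq_len(nrow(locs)), function(i) linearize(dyn, locs[i, ]))
  eigs <- lapply(jacs, function(J) eigen(J, only.values = TRUE)$values)
  labels <- vapply(eigs, classify_fixed_point, character(1))
  structure(list(locations = locs, residuals = res, jacobians = jacs,
                 eigenvalues = eigs, labels = labels),
            class = "fixed_point_set")
}

empty_fp_set <- function(D) {
  structure(list(locations = matrix(0, 0, D), residuals = numeric(0),
                 jacobians = list(), eigenvalues = list(),
                 labels = character(0)),
            class = "fixed_point_set")
}

#' @export
print.fixed_point_set <- function(x, ...) {
  cat(sprintf("<fixed_point_set> %d fixed point(s)\n", nrow(x$locations)))
  for (i in seq_len(nrow(x$locations))) {
    cat(sprintf("  [%d] %-11s |f|=%.2e at (%s)\n", i, x$labels[i],
                x$residuals[i],
                paste(sprintf("%.3f", x$locations[i, ]), collapse = ", ")))
  }
  invisible(x)
}

# Jacobian of the displacement f at z: analytic when provided, else central
# finite differences.
dyn_jacobian <- function(dyn, z, h = 1e-5) {
  if (!is.null(dyn$jac)) return(dyn$jac(z))
  finite_diff_jacobian(dyn$f, z, h)
}

finite_diff_jacobian <- function(f, z, h = 1e-5) {
  D <- length(z)
  J <- matrix(0, D, D)
  for (j in seq_len(D)) {
    zp <- z; zm <- z
    zp[j] <- zp[j] + h
    zm[j] <- zm[j] - h
    J[, j] <- (as.numeric(f(matrix(zp, nrow = 1))) -
               as.numeric(f(matrix(zm, nrow = 1)))) / (2 * h)
  }
  if (!all(is.finite(J))) stop("non-finite derivative in Jacobian")
  J
}

#' Linearize the update map at a point
#'
#' Returns the Jacobian of the full update `z -> z + f(z)`, i.e.
#' `I + df/dz`, using the analytic Jacobian when the dynamics provide one
#' and central finite differences otherwise.
#'
#' @param dyn a dynamics function.
#' @param z state (numeric vector).
#' @param use_finite_diff force finite differences even when an analytic
#'   Jacobian is available.
#' @return `D x D` Jacobian of the update map.
#' @export
linearize <- function(dyn, z, use_finite_diff = FALSE) {
  Jf <- if (use_finite_diff) finite_diff_jacobian(dyn$f, z) else
    dyn_jacobian(dyn, z)
  diag(length(z)) + Jf
}

#' Classify a fixed point from update-map eigenvalues
#'
#' Discrete-time stability against the unit circle: all `|lambda| < 1` is
#' attracting (a spiral when any eigenvalue is complex), all `> 1`
#' repelling (spiral-out likewise), a mixture is a saddle, and moduli
#' within `tol` of 1 are center-like.
#'
#' @param eigenvalues complex eigenvalue vector of the update-map Jacobian.
#' @param tol modulus tolerance around the unit circle (default 1e-6).
#' @return One of `"attractor"`, `"spiral-in"`, `"repeller"`,
#'   `"spiral-out"`, `"saddle"`, `"center-like"`.
#' @export
classify_fixed_point <- function(eigenvalues, tol = 1e-6) {
  if (!length(eigenvalues)) stop("empty eigenvalue list")
  mod <- Mod(eigenvalues)
  rotational <- any(abs(Im(eigenvalues)) > tol)
  if (any(abs(mod - 1) <= tol)) return("center-like")
  if (all(mod < 1)) return(if (rotational) "spiral-in" else "attractor")
  if (all(mod > 1)) return(if (rotational) "spiral-out" else "repeller")
  "saddle"
}

#' Draw fixed-point search seeds from inferred latents
#'
#' Samples points uniformly from the rows of flattened latent trajectories
#' and adds small Gaussian jitter, giving a candidate cloud covering the
#' visited region of state space.
#'
#' @param Z_hat latent array `trials x T x D_hat`.
#' @param n_seeds number of candidates (default 256).
#' @param jitter_sd jitter standard deviation as a fraction of each
#'   dimension's spread (default 0.05).
#' @param seed integer seed.
#' @return Matrix `n_seeds x D_hat`.
#' @export
fp_candidates <- function(Z_hat, n_seeds = 256L, jitter_sd = 0.05,
                          seed = 0L) {
  Zf <- flatten_trials(Z_hat)
  set.seed(derive_seed(seed, 151L))
  idx <- sample.int(nrow(Zf), n_seeds, replace = TRUE)
  spread <- apply(Zf, 2, stats::sd)
  Zf[idx, , drop = FALSE] +
    matrix(stats::rnorm(n_seeds * ncol(Zf)), n_seeds) *
      matrix(spread * jitter_sd, n_seeds, ncol(Zf), byrow = TRUE)
}

#' Compare model fixed points to ground truth
#'
#' Transforms ground-truth fixed-point locations into model latent space
#' through the State-R2 alignment map, greedily matches them to model fixed
#' points by distance, and reports per-pair location errors plus the
#' Hausdorff distance between each pair's eigenvalue sets in the complex
#' plane.  A cardinality mismatch is reported, not fatal.
#'
#' @param model_fps a `fixed_point_set` from the trained model.
#' @param truth_locations matrix of ground-truth fixed-point locations.
#' @param truth_eigenvalues list of complex eigenvalue vectors of the
#'   ground-truth one-bin update map, parallel to `truth_locations`.
#' @param map the `map` element of a [state_r2()] fit (truth -> model).
#' @return A list with `n_model`, `n_truth`, `matches` (data frame of
#'   matched indices, location errors, eigenvalue-set distances), and
#'   `transformed_truth`.
#' @export
compare_fixed_points <- function(model_fps, truth_locations,
                                 truth_eigenvalues, map) {
  if (!nrow(model_fps$locations) || !nrow(truth_locations)) {
    stop("both fixed-point sets must be nonempty")
  }
  tt <- truth_locations %*% map$linear +
    matrix(map$offset, nrow(truth_locations), length(map$offset),
           byrow = TRUE)
  n_t <- nrow(tt)
  n_m <- nrow(model_fps$locations)
  avail <- seq_len(n_m)
  rows <- list()
  for (i in seq_len(n_t)) {
    if (!length(avail)) break
    d <- sqrt(rowSums((model_fps$locations[avail, , drop = FALSE] -
                       matrix(tt[i, ], length(avail), ncol(tt),
                              byrow = TRUE))^2))
    j <- avail[which.min(d)]
    avail <- setdiff(avail, j)
    rows[[i]] <- data.frame(
      truth = i, model = j, location_error = min(d),
      eig_distance = eig_set_distance(truth_eigenvalues[[i]],
                                      model_fps$eigenvalues[[j]]))
  }
  list(n_model = n_m, n_truth = n_t, matches = do.call(rbind, rows),
       transformed_truth = tt)
}

# Hausdorff distance between two finite sets of complex numbers.
eig_set_distance <- function(e1, e2) {
  d <- outer(e1, e2, function(a, b) Mod(a - b))
  max(max(apply(d, 1, min)), max(apply(d, 2, min)))
}
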