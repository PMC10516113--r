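# Ground-truth latent dynamical systems.  The benchmark system is the
# Arneodo-Coullet attractor
#
#   dx/dt = y,   dy/dt = z,   dz/dt = -a x - b y - c z + d x^3
#
# with the conventional chaotic coefficients a = -5.5, b = 3.5, c = 1,
# d = -1.  Its three fixed points (y = z = 0, x in {0, +/-sqrt(a/d)}) and
# their continuous-time Jacobian eigenvalues are available in closed form,
# which the fixed-point recovery tests lean on.

ARNEODO_PARAMS <- c(a = -5.5, b = 3.5, c = 1, d = -1)

#' Specify a ground-truth latent dynamical system
#'
#' @param name `"arneodo"` for the chaotic benchmark system, or `"zero"` for
#'   a degenerate constant system (zero vector field) used in testing.
#' @param params named numeric coefficients of the vector field; defaults to
#'   the conventional chaotic Arneodo set `c(a = -5.5, b = 3.5, c = 1, d = -1)`.
#' @param dt integration time units per observation bin.
#' @param integrator `"rk4"` (default; used for ground truth so that the
#'   simulated system does not inherit the model's Euler discretization
#'   error) or `"euler"`.
#' @param burn_in_steps integration steps discarded before recording, letting
#'   trajectories relax onto the attractor.
#' @return An object of class `chaotic_system`.
#' @export
chaotic_system <- function(name = "arneodo", params = NULL, dt = 0.05,
                           integrator = c("rk4", "euler"),
                           burn_in_steps = 1000L) {
  integrator <- match.arg(integrator)
  if (dt <= 0) stop("dt must be positive")
  if (burn_in_steps < 0) stop("burn_in_steps must be nonnegative")
  if (name == "arneodo") {
    if (is.null(params)) params <- ARNEODO_PARAMS
    if (!all(c("a", "b", "c", "d") %in% names(params))) {
      stop("arneodo system requires parameters a, b, c, d")
    }
    D <- 3L
  } else if (name == "zero") {
    params <- c(D = if (is.null(params)) 3 else unname(params[["D"]]))
    D <- as.integer(params[["D"]])
  } else {
    stop("unknown system name: ", name)
  }
  structure(list(name = name, params = params, dt = dt,
                 integrator = integrator,
                 burn_in_steps = as.integer(burn_in_steps), D = D),
            class = "chaotic_system")
}

#' @export
print.chaotic_system <- function(x, ...) {
  cat("<chaotic_system>", x$name, sprintf("(D=%d, dt=%g, %s)\n",
      x$D, x$dt, x$integrator))
  cat("  params:", paste(names(x$params), signif(unname(x$params), 4),
      sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Vector field as a function acting on a matrix of states (rows = points).
vector_field <- function(system) {
  if (system$name == "arneodo") {
    p <- system$params
    function(S) {
      cbind(S[, 2],
            S[, 3],
            -p[["a"]] * S[, 1] - p[["b"]] * S[, 2] - p[["c"]] * S[, 3] +
              p[["d"]] * S[, 1]^3)
    }
  } else {
    function(S) S * 0
  }
}

# Analytic Jacobian of the continuous-time vector field at a single state.
continuous_jacobian <- function(system, z) {
  if (system$name == "arneodo") {
    p <- system$params
    rbind(c(0, 1, 0),
          c(0, 0, 1),
          c(-p[["a"]] + 3 * p[["d"]] * z[1]^2, -p[["b"]], -p[["c"]]))
  } else {
    matrix(0, system$D, system$D)
  }
}

# One integration step for a matrix of states.
integration_step <- function(system, S, dt = system$dt) {
  f <- vector_field(system)
  if (system$integrator == "euler") {
    S + dt * f(S)
  } else {
    k1 <- f(S)
    k2 <- f(S + dt / 2 * k1)
    k3 <- f(S + dt / 2 * k2)
    k4 <- f(S + dt * k3)
    S + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
}

#' Integrate latent trajectories of a ground-truth system
#'
#' Draws random initial conditions, discards a burn-in period so states lie
#' on the attractor, and records `T` post-burn-in states per trajectory.
#' All randomness is in the initial conditions, so the output is fully
#' determined by `seed`.
#'
#' @param system a [chaotic_system()].
#' @param n_traj number of trajectories (>= 1).
#' @param T number of recorded time bins per trajectory (>= 2).
#' @param seed integer seed.
#' @return numeric array `n_traj x T x D` of latent states.
#' @export
integrate_system <- function(system, n_traj, T, seed = 0L) {
  stopifnot(inherits(system, "chaotic_system"))
  if (n_traj < 1) stop("n_traj must be >= 1")
  if (T < 2) stop("T must be >= 2")
  set.seed(derive_seed(seed, 11L))
  S <- matrix(stats::runif(n_traj * system$D, -1, 1), n_traj, system$D)
  for (i in seq_len(system$burn_in_steps)) {
    S <- integration_step(system, S)
    if (!all(is.finite(S))) {
      stop("non-finite state during burn-in at step ", i)
    }
  }
  Z <- array(0, dim = c(n_traj, T, system$D))
  for (t in seq_len(T)) {
    S <- integration_step(system, S)
    if (!all(is.finite(S))) {
      stop("non-finite state during integration at recorded step ", t)
    }
    Z[, t, ] <- S
  }
  Z
}

# The discrete one-bin update displacement F(z) = step(z) - z, plus its
# analytic fixed points when known.  This is the "dynamics function"
# interface consumed by the fixed-point machinery: a list with
#   f(Z)  : matrix of displacements for a matrix of states
#   jac(z): optional analytic Jacobian of f at one state
#' One-bin discrete update map of a ground-truth system
#'
#' Wraps one integration step of the system as a discrete-time displacement
#' function `f(z) = step(z) - z`, the same interface used for trained
#' generators, so that ground-truth fixed points can be found and linearized
#' with the same machinery.
#'
#' @param system a [chaotic_system()].
#' @return A list with elements `f` (matrix-in, matrix-out displacement
#'   function) and `jac` (analytic Jacobian of the displacement at a single
#'   state, via the matrix exponential of the continuous Jacobian).
#' @export
discrete_dynamics <- function(system) {
  list(
    f = function(Z) integration_step(system, Z) - Z,
    jac = function(z) {
      Jc <- continuous_jacobian(system, z)
      as.matrix(Matrix::expm(Jc * system$dt)) - diag(nrow(Jc))
    },
    D = system$D
  )
}

#' Analytic fixed points of the Arneodo system
#'
#' The fixed points solve `y = z = 0`, `-a x + d x^3 = 0`, giving `x = 0`
#' and `x = +/- sqrt(a/d)` when `a/d > 0`.  Continuous-time eigenvalues are
#' those of the analytic Jacobian; the discrete-map eigenvalues over one bin
#' are their exponentials `exp(lambda * dt)`.
#'
#' @param system an Arneodo [chaotic_system()].
#' @return A list with `locations` (matrix, one fixed point per row),
#'   `eig_continuous` and `eig_discrete` (lists of complex eigenvalue
#'   vectors; discrete values are eigenvalues of the one-bin update map
#'   `z -> z + f(z)`).
#' @export
arneodo_fixed_points <- function(system = chaotic_system()) {
  if (system$name != "arneodo") stop("analytic fixed points known for arneodo only")
  p <- system$params
  ratio <- p[["a"]] / p[["d"]]
  xs <- 0
  if (ratio > 0) xs <- c(-sqrt(ratio), 0, sqrt(ratio))
  locations <- cbind(x = xs, y = 0, z = 0)
  eig_cont <- lapply(xs, function(x0) {
    eigen(continuous_jacobian(system, c(x0, 0, 0)), only.values = TRUE)$values
  })
  eig_disc <- lapply(eig_cont, function(ev) exp(ev * system$dt))
  list(locations = locations, eig_continuous = eig_cont,
       eig_discrete = eig_disc)
}
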