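## Synthetic ground truth: kinetic models, steady states, true Jacobians,
## Langevin-type SDE replicate data, and the two noise-injection protocols.

#' Construct a kinetic model
#'
#' @param rhs function mapping a length-n concentration vector to dC/dt.
#' @param n metabolite count.
#' @param names metabolite labels.
#' @param parameters named list of kinetic parameters (metadata).
#' @param jacobian optional analytic Jacobian function `C -> n x n matrix`.
#' @param rhs_matrix optional vectorized rhs mapping an n x m state matrix
#'   (one trajectory per column) to its n x m derivative; used to batch SDE
#'   trajectories.
#' @param initial_guess default starting point for the steady-state search.
#' @return object of class `kinetic_model`.
#' @export
kinetic_model <- function(rhs, n, names = paste0("M", seq_len(n)),
                          parameters = list(), jacobian = NULL,
                          rhs_matrix = NULL, initial_guess = rep(1, n)) {
  stopifnot(is.function(rhs), n >= 1, length(names) == n)
  structure(list(rhs = rhs, n = as.integer(n), names = names,
                 parameters = parameters, jacobian = jacobian,
                 rhs_matrix = rhs_matrix, initial_guess = initial_guess),
            class = "kinetic_model")
}

#' Find a steady state of a kinetic model
#'
#' Damped Newton iteration on `rhs(C) = 0` with a finite-difference
#' Jacobian. Converges to `max|rhs(C_s)| < tol`; concentrations at the
#' root must be nonnegative.
#'
#' @param model `kinetic_model`.
#' @param initial_guess starting concentrations (defaults to the model's).
#' @param tol convergence tolerance on the max-norm of the rhs.
#' @param max_iter maximum Newton iterations.
#' @return steady-state concentration vector `C_s` (named).
#' @export
find_steady_state <- function(model, initial_guess = model$initial_guess,
                              tol = 1e-10, max_iter = 200L) {
  stopifnot(inherits(model, "kinetic_model"))
  x <- as.numeric(initial_guess)
  f <- model$rhs(x)
  for (iter in seq_len(max_iter)) {
    if (max(abs(f)) < tol) break
    J <- numeric_jacobian(model$rhs, x)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step) || anyNA(step) || any(!is.finite(step))) {
      stop("steady-state search failed: singular Jacobian at iteration ",
           iter, ", residual ", format(max(abs(f))))
    }
    ## damped update: halve the step until the residual decreases
    alpha <- 1
    repeat {
      x_new <- x + alpha * step
      f_new <- model$rhs(x_new)
      if (all(is.finite(f_new)) && max(abs(f_new)) < max(abs(f))) break
      alpha <- alpha / 2
      if (alpha < 1e-10) {
        stop("steady-state search did not converge: stalled at residual ",
             format(max(abs(f))), " after ", iter, " iterations")
      }
    }
    x <- x_new
    f <- f_new
  }
  if (max(abs(f)) >= tol) {
    stop("steady-state search did not converge: final residual ",
         format(max(abs(f))), " after ", max_iter, " iterations")
  }
  if (any(x < 0)) {
    stop("steady-state search converged to a state with negative concentration(s)")
  }
  stats::setNames(x, model$names)
}

#' Finite-difference Jacobian of a vector field
#'
#' Central differences with per-coordinate step
#' `h_j = max(1e-6, 1e-6 * |x_j|)`.
#'
#' @param f function mapping length-n vector to length-n vector.
#' @param x evaluation point.
#' @return n x n matrix of partial derivatives d f_i / d x_j.
#' @export
numeric_jacobian <- function(f, x) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- max(1e-6, 1e-6 * abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' True Jacobian of a kinetic model at a steady state
#'
#' Entry (i, j) is the partial derivative of metabolite i's balance
#' equation with respect to metabolite j, evaluated at `C_s`. Uses the
#' analytic Jacobian when the model supplies one, otherwise central finite
#' differences.
#'
#' @param model `kinetic_model`.
#' @param C_s steady-state concentrations.
#' @return n x n Jacobian matrix with metabolite dimnames.
#' @export
true_jacobian <- function(model, C_s) {
  stopifnot(inherits(model, "kinetic_model"))
  J <- if (!is.null(model$jacobian)) model$jacobian(as.numeric(C_s))
       else numeric_jacobian(model$rhs, as.numeric(C_s))
  dimnames(J) <- list(model$names, model$names)
  J
}

#' Configuration for Langevin-type SDE replicate generation
#'
#' Each metabolite i is forced by white noise of intensity `sqrt(2 D_i)`,
#' so replicate fluctuations around the steady state carry the network
#' structure through the stationary covariance. Defaults are the package's
#' reference study conditions: fluctuation magnitude 0.005 for every
#' metabolite and 1000 replicates.
#'
#' @param fluctuations per-metabolite fluctuation magnitudes D_i (recycled
#'   to length n at simulation time); noise amplitudes are `sqrt(2 D_i)`.
#' @param dt Euler-Maruyama step; `NULL` picks
#'   `0.05 / max|eigenvalue(J)|` from the model Jacobian.
#' @param t_end trajectory horizon; `NULL` picks `10 / min|Re eigenvalue|`
#'   (about ten relaxation times of the slowest mode).
#' @param burn_in initial time span regarded as equilibration; must be
#'   smaller than `t_end`. Only sampled states beyond it are used.
#' @param n_replicates number of replicates.
#' @param method `"independent"` (each replicate is the endpoint of an
#'   independent trajectory started at the steady state) or `"thinned"`
#'   (states sampled along one long trajectory after burn-in).
#' @param seed RNG seed.
#' @return list of class `sde_config`.
#' @export
sde_config <- function(fluctuations = 0.005, dt = NULL, t_end = NULL,
                       burn_in = 0, n_replicates = 1000L,
                       method = c("independent", "thinned"), seed = 1L) {
  method <- match.arg(method)
  if (any(fluctuations < 0)) stop("fluctuation magnitudes must be nonnegative")
  if (!is.null(dt) && dt <= 0) stop("dt must be positive")
  if (!is.null(t_end) && !is.null(burn_in) && burn_in >= t_end) {
    stop("burn_in must be smaller than t_end")
  }
  structure(list(fluctuations = fluctuations, dt = dt, t_end = t_end,
                 burn_in = burn_in, n_replicates = as.integer(n_replicates),
                 method = method, seed = as.integer(seed)),
            class = "sde_config")
}

#' Simulate steady-state metabolome replicates by Euler-Maruyama
#'
#' Integrates the Langevin system `dC = rhs(C) dt + sqrt(2 D) dW` from the
#' steady state. With `method = "independent"` each replicate is the state
#' at `t_end` of an independent trajectory; with `"thinned"`, states are
#' sampled along one long trajectory after `burn_in`. Concentrations are
#' floored at zero; the number of floor events is recorded in the
#' `floor_events` attribute.
#'
#' @param model `kinetic_model`.
#' @param C_s steady-state concentrations.
#' @param cfg `sde_config`.
#' @return `replicate_dataset` (provenance "simulated") with attributes
#'   `floor_events` and `sde_config`.
#' @export
simulate_replicates <- function(model, C_s, cfg = sde_config()) {
  stopifnot(inherits(model, "kinetic_model"), inherits(cfg, "sde_config"))
  n <- model$n
  C_s <- as.numeric(C_s)
  D <- rep_len(cfg$fluctuations, n)
  J <- true_jacobian(model, C_s)
  ev <- eigen(J, only.values = TRUE)$values
  if (max(Re(ev)) >= 0) {
    stop("model is not locally stable at the supplied steady state")
  }
  dt <- if (is.null(cfg$dt)) 0.05 / max(abs(ev)) else cfg$dt
  t_end <- if (is.null(cfg$t_end)) 10 / min(abs(Re(ev))) else cfg$t_end
  burn_in <- cfg$burn_in
  if (burn_in >= t_end) stop("burn_in must be smaller than t_end")
  amp <- sqrt(2 * D)
  rhs_mat <- if (!is.null(model$rhs_matrix)) model$rhs_matrix
             else function(X) apply(X, 2L, model$rhs)
  set.seed(cfg$seed)
  floor_events <- 0L
  divergence_cap <- 1e6 * max(abs(C_s), 1)

  step_block <- function(X, n_steps) {
    m <- ncol(X)
    sq <- amp * sqrt(dt)
    for (s in seq_len(n_steps)) {
      X <- X + rhs_mat(X) * dt + sq * matrix(stats::rnorm(n * m), n, m)
      neg <- X < 0
      if (any(neg)) {
        floor_events <<- floor_events + sum(neg)
        X[neg] <- 0
      }
      if (s %% 50L == 0L && any(abs(X) > divergence_cap)) {
        stop("SDE trajectory diverged (|C| > 1e6 * max steady state); ",
             "try a smaller dt")
      }
    }
    X
  }

  if (cfg$method == "independent") {
    n_steps <- max(1L, ceiling(t_end / dt))
    X <- matrix(C_s, n, cfg$n_replicates)
    X <- step_block(X, n_steps)
    reps <- t(X)
  } else {
    ## one long trajectory, thinned after burn-in
    burn_steps <- max(0L, ceiling(burn_in / dt))
    spacing <- max(1L, ceiling((t_end - burn_in) / dt / cfg$n_replicates))
    X <- matrix(C_s, n, 1L)
    X <- step_block(X, burn_steps)
    reps <- matrix(0, cfg$n_replicates, n)
    for (r in seq_len(cfg$n_replicates)) {
      X <- step_block(X, spacing)
      reps[r, ] <- X[, 1L]
    }
  }
  colnames(reps) <- model$names
  out <- replicate_dataset(reps, model$names, "simulated")
  attr(out, "floor_events") <- floor_events
  attr(out, "sde_config") <- cfg
  out
}

#' Multiplicative noise on an exact covariance matrix
#'
#' Each upper-triangle entry (and its mirror image, sharing the same
#' factor) is multiplied by an independent draw from N(1, `noise_sd`), so
#' the output stays exactly symmetric.
#'
#' @param C_exact symmetric covariance matrix.
#' @param noise_sd standard deviation of the multiplicative factors.
#' @param seed optional RNG seed.
#' @return noisy symmetric covariance matrix.
#' @export
noisy_covariance <- function(C_exact, noise_sd = 0.005, seed = NULL) {
  C_exact <- as_covariance(C_exact)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(C_exact)
  F <- matrix(1, n, n)
  upper <- upper.tri(F, diag = TRUE)
  F[upper] <- stats::rnorm(sum(upper), mean = 1, sd = noise_sd)
  F[lower.tri(F)] <- t(F)[lower.tri(F)]
  C_exact * F
}

#' Additive measurement noise on replicate data
#'
#' Adds independent zero-mean Gaussian noise per metabolite. In the default
#' `"variance"` mode the noise standard deviation for metabolite i is
#' `scale * Var_i` (its sample variance across replicates); the
#' `"sd"` mode uses `scale * sd_i` instead.
#'
#' @param data `replicate_dataset`.
#' @param scale noise scale (default 0.10).
#' @param seed optional RNG seed.
#' @param mode `"variance"` or `"sd"`.
#' @return noisy `replicate_dataset`.
#' @export
add_measurement_noise <- function(data, scale = 0.10, seed = NULL,
                                  mode = c("variance", "sd")) {
  stopifnot(inherits(data, "replicate_dataset"))
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  X <- data$matrix
  m <- nrow(X)
  base <- if (mode == "variance") apply(X, 2L, stats::var)
          else apply(X, 2L, stats::sd)
  noise <- vapply(scale * base,
                  function(s) stats::rnorm(m, 0, s), numeric(m))
  replicate_dataset(X + noise, data$metabolite_names, data$provenance)
}

#' Random sparse stable linear kinetic model
#'
#' Generates a toy network with known ground truth: a sparse Hurwitz-stable
#' Jacobian `J` (every diagonal entry negative, off-diagonal entries present
#' with probability `density`) and linear kinetics
#' `dC/dt = J (C - C_s)` around a random positive steady state. Jacobian
#' sparsity is required to be at least 0.55, matching the empirical sparsity
#' of small metabolic networks.
#'
#' @param n metabolite count (3-8 intended).
#' @param density off-diagonal edge probability; must be consistent with
#'   sparsity above 0.55.
#' @param seed RNG seed.
#' @return `kinetic_model` whose `parameters` hold `J` (true Jacobian),
#'   `C_s` (steady state) and `sparsity`.
#' @export
make_toy_network <- function(n = 5L, density = 0.2, seed = 1L) {
  if (density > 0.45) {
    stop("density ", density, " is inconsistent with the minimum Jacobian ",
         "sparsity of 0.55 for toy networks")
  }
  set.seed(seed)
  for (attempt in seq_len(100L)) {
    edges <- matrix(stats::runif(n * n) < density, n, n)
    diag(edges) <- FALSE
    vals <- matrix(stats::runif(n * n, 0.2, 1) *
                     sign(stats::runif(n * n) - 0.5), n, n)
    J <- vals * edges
    ## diagonal dominance guarantees Hurwitz stability (Gershgorin)
    diag(J) <- -(rowSums(abs(J)) + stats::runif(n, 0.5, 1.5))
    sparsity <- mean(J == 0)
    ev <- eigen(J, only.values = TRUE)$values
    if (sparsity >= 0.55 && max(Re(ev)) < 0) {
      C_s <- stats::runif(n, 0.5, 2)
      names <- paste0("M", seq_len(n))
      dimnames(J) <- list(names, names)
      rhs <- function(C) as.vector(J %*% (C - C_s))
      return(kinetic_model(
        rhs = rhs, n = n, names = names,
        parameters = list(J = J, C_s = stats::setNames(C_s, names),
                          sparsity = sparsity),
        jacobian = function(C) J,
        rhs_matrix = function(X) J %*% (X - C_s),
        initial_guess = C_s))
    }
  }
  stop("failed to generate a stable sparse network in 100 attempts")
}

#' Synthetic 13-metabolite glycolysis-like kinetic model
#'
#' A hand-built mass-action model of a glycolysis-like pathway (glucose
#' uptake through hexose phosphates, triose phosphates, pyruvate and
#' ethanol, with ATP and NAD coupling) used as the package's benchmark
#' fixture at realistic network size. It is a synthetic stand-in
#' constructed for this package, not a published kinetic model: rate
#' constants are chosen so that a fixed positive concentration vector is
#' the steady state, the Jacobian there is Hurwitz-stable and well damped
#' (slowest mode about -0.18; weak damping would make the stationary
#' covariance far exceed the fluctuation scale), and the Jacobian sparsity
#' (about 0.78) is in the empirically observed range (> 0.55).
#'
#' @return `kinetic_model` with 13 metabolites.
#' @export
glycolysis_synthetic_model <- function() {
  names <- c("GLC", "G6P", "F6P", "FBP", "DHAP", "GAP", "BPG",
             "PEP", "PYR", "ACA", "ETOH", "ATP", "NAD")
  p <- list(k0 = 1, k1 = 1, k2f = 2, k2r = 1, k3 = 1, k4 = 1,
            k5f = 2, k5r = 1, k6 = 2, k7 = 2, k8 = 4, k9 = 4,
            k10 = 4, k11 = 4, k12 = 6.5, k13 = 4.5, k14 = 3, k15 = 3)
  rhs_rows <- function(GLC, G6P, F6P, FBP, DHAP, GAP, BPG, PEP, PYR,
                       ACA, ETOH, ATP, NAD) {
    with(p, rbind(
      k0 - k1 * GLC * ATP,                                      # GLC
      k1 * GLC * ATP - k2f * G6P + k2r * F6P,                   # G6P
      k2f * G6P - k2r * F6P - k3 * F6P * ATP,                   # F6P
      k3 * F6P * ATP - k4 * FBP,                                # FBP
      k4 * FBP - k5f * DHAP + k5r * GAP,                        # DHAP
      k4 * FBP + k5f * DHAP - k5r * GAP - k6 * GAP * NAD,       # GAP
      k6 * GAP * NAD - k7 * BPG,                                # BPG
      k7 * BPG - k8 * PEP,                                      # PEP
      k8 * PEP - k9 * PYR,                                      # PYR
      k9 * PYR - k10 * ACA,                                     # ACA
      k10 * ACA - k11 * ETOH,                                   # ETOH
      k7 * BPG + k8 * PEP - k1 * GLC * ATP - k3 * F6P * ATP -
        k12 * ATP + k13,                                        # ATP
      k14 + k10 * ACA - k6 * GAP * NAD - k15 * NAD))            # NAD
  }
  rhs_matrix <- function(X) {
    out <- rhs_rows(X[1, ], X[2, ], X[3, ], X[4, ], X[5, ], X[6, ], X[7, ],
                    X[8, ], X[9, ], X[10, ], X[11, ], X[12, ], X[13, ])
    dim(out) <- dim(X)
    out
  }
  rhs <- function(C) as.vector(rhs_matrix(matrix(C, ncol = 1)))
  ss <- c(rep(1, 7), rep(0.5, 4), 1, 1)
  kinetic_model(rhs = rhs, n = 13L, names = names, parameters = p,
                rhs_matrix = rhs_matrix, initial_guess = ss)
}
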