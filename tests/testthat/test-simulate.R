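test_that("steady-state search solves linear and mass-action models", {
  # linear relaxation dC/dt = -K (C - b) has steady state b
  K <- diag(c(1, 2, 0.5)); b <- c(1.5, 0.7, 2.2)
  model <- kinetic_model(function(C) as.vector(-K %*% (C - b)), 3,
                         initial_guess = c(1, 1, 1))
  C_s <- find_steady_state(model)
  expect_equal(unname(C_s), b, tolerance = 1e-8)

  # mass-action chain: influx -> M1 -> M2 -> out, verified by substitution
  chain <- kinetic_model(function(C) c(1 - 2 * C[1], 2 * C[1] - 0.5 * C[2]), 2,
                         initial_guess = c(0.1, 0.1))
  C_s2 <- find_steady_state(chain)
  expect_lt(max(abs(chain$rhs(C_s2))), 1e-10)
  expect_equal(unname(C_s2), c(0.5, 2), tolerance = 1e-8)

  # a hopeless starting point reports non-convergence, not a wrong root
  bad <- kinetic_model(function(C) c(1 + C[1]^2), 1, initial_guess = 0)
  expect_error(find_steady_state(bad), "converge|singular")
})

test_that("finite-difference Jacobian matches analytic derivatives", {
  K <- diag(c(1, 3)); b <- c(1, 1)
  lin <- kinetic_model(function(C) as.vector(-K %*% (C - b)), 2)
  expect_equal(true_jacobian(lin, c(1, 1)), -K,
               tolerance = 1e-6, ignore_attr = TRUE)

  # quadratic rhs: d/dC of (-C1^2 + C2, C1 C2 - 2 C2) known in closed form
  quad <- kinetic_model(function(C) c(-C[1]^2 + C[2], C[1] * C[2] - 2 * C[2]), 2)
  x <- c(1.3, 0.8)
  J_expect <- matrix(c(-2 * x[1], x[2], 1, x[1] - 2), 2, 2)
  expect_equal(true_jacobian(quad, x), J_expect,
               tolerance = 1e-6, ignore_attr = TRUE)

  # analytic Jacobian takes precedence and agrees with finite differences
  lin2 <- kinetic_model(function(C) as.vector(-K %*% (C - b)), 2,
                        jacobian = function(C) -K)
  expect_equal(unname(true_jacobian(lin2, c(2, 2))),
               lyapnet::numeric_jacobian(lin2$rhs, c(2, 2)), tolerance = 1e-5)
})

test_that("zero noise amplitudes keep every replicate at the steady state", {
  model <- make_toy_network(4, density = 0.2, seed = 12)
  C_s <- model$parameters$C_s
  cfg <- sde_config(fluctuations = 0, t_end = 2, n_replicates = 5, seed = 1)
  data <- simulate_replicates(model, C_s, cfg)
  expect_equal(unname(data$matrix),
               matrix(C_s, 5, 4, byrow = TRUE), tolerance = 1e-12)
  expect_identical(data$provenance, "simulated")
})

test_that("OU process variance converges to sigma^2 / (2a)", {
  # dX = -a X dt + sigma dW around 10: Var(X) -> sigma^2 / (2a).
  # In fluctuation terms sigma = sqrt(2 D), so Var -> D / a.
  a <- 2; D <- 0.02
  model <- kinetic_model(function(C) -a * (C - 10), 1, names = "X",
                         jacobian = function(C) matrix(-a, 1, 1),
                         rhs_matrix = function(X) -a * (X - 10))
  cfg <- sde_config(fluctuations = D, dt = 0.005, t_end = 6,
                    n_replicates = 10000, seed = 7)
  data <- simulate_replicates(model, 10, cfg)
  v <- stats::var(data$matrix[, 1])
  v_theory <- D / a
  se <- v_theory * sqrt(2 / (10000 - 1))  # SE of a variance estimate
  expect_lt(abs(v - v_theory), 3 * se + 0.05 * v_theory)
})

test_that("replicate covariance of a linear system approaches the Lyapunov solution", {
  model <- make_toy_network(4, density = 0.2, seed = 15)
  J <- model$parameters$J
  D <- rep(0.01, 4)
  C_theory <- forward_solve_covariance(J, D)
  cfg <- sde_config(fluctuations = D, t_end = 40, n_replicates = 10000, seed = 8)
  data <- simulate_replicates(model, model$parameters$C_s, cfg)
  C_emp <- compute_covariance(data)
  rel_err <- norm(C_emp - C_theory, "F") / norm(C_theory, "F")
  expect_lt(rel_err, 0.15)
})

test_that("multiplicative covariance noise is symmetric with the right spread", {
  C <- forward_solve_covariance(random_stable_jacobian(4, 0.4, 2), rep(0.1, 4))
  expect_identical(noisy_covariance(C, noise_sd = 0), C)

  set.seed(9)
  devs <- unlist(lapply(1:200, function(k) {
    Cn <- noisy_covariance(C, noise_sd = 0.005, seed = k)
    expect_identical(Cn, t(Cn))
    (Cn / C - 1)[upper.tri(C, diag = TRUE)]
  }))
  expect_lt(abs(stats::sd(devs) - 0.005), 0.0005)
})

test_that("additive measurement noise has the configured per-metabolite scale", {
  set.seed(10)
  X <- cbind(A = stats::rnorm(4000, 10, 2), B = stats::rnorm(4000, 5, 0.5))
  data <- replicate_dataset(X, c("A", "B"), "simulated")
  expect_identical(add_measurement_noise(data, scale = 0)$matrix, data$matrix)

  noisy <- add_measurement_noise(data, scale = 0.10, seed = 11)
  added <- noisy$matrix - data$matrix
  target <- 0.10 * apply(X, 2, stats::var)
  for (j in 1:2) {
    expect_lt(abs(stats::sd(added[, j]) / target[j] - 1), 0.1)
  }
  # independence across metabolites
  expect_lt(abs(stats::cor(added[, 1], added[, 2])), 0.05)

  # alternative reading: sd proportional to the standard deviation
  noisy_sd <- add_measurement_noise(data, scale = 0.10, seed = 12, mode = "sd")
  added_sd <- noisy_sd$matrix - data$matrix
  expect_lt(abs(stats::sd(added_sd[, 1]) / (0.10 * stats::sd(X[, 1])) - 1), 0.1)
})

test_that("toy networks are reproducible, stable and sparse", {
  m1 <- make_toy_network(5, density = 0.2, seed = 77)
  m2 <- make_toy_network(5, density = 0.2, seed = 77)
  expect_identical(m1$parameters, m2$parameters)

  for (seed in 1:100) {
    m <- make_toy_network(5, density = 0.2, seed = seed)
    ev <- eigen(m$parameters$J, only.values = TRUE)$values
    expect_lt(max(Re(ev)), 0)
    expect_gte(m$parameters$sparsity, 0.55)
  }
  expect_error(make_toy_network(5, density = 0.6), "sparsity")
})

test_that("the synthetic glycolysis fixture is a stable 13-metabolite model", {
  model <- glycolysis_synthetic_model()
  expect_identical(model$n, 13L)
  C_s <- find_steady_state(model)
  expect_lt(max(abs(model$rhs(C_s))), 1e-10)
  J <- true_jacobian(model, C_s)
  ev <- eigen(J, only.values = TRUE)$values
  expect_lt(max(Re(ev)), 0)  # Hurwitz at the steady state
  expect_gt(sparsity_of((abs(J) > 1e-10) * 1), 0.55)
  # vectorized rhs agrees with the scalar rhs
  X <- matrix(stats::runif(26, 0.5, 1.5), 13, 2)
  expect_equal(model$rhs_matrix(X), cbind(model$rhs(X[, 1]), model$rhs(X[, 2])))
})

test_that("SDE divergence is detected and reported", {
  unstable_after <- kinetic_model(function(C) C^2, 1, initial_guess = 1,
                                  jacobian = function(C) matrix(-1, 1, 1),
                                  rhs_matrix = function(X) X^2)
  cfg <- sde_config(fluctuations = 0.5, dt = 0.5, t_end = 400,
                    n_replicates = 3, seed = 2)
  expect_error(simulate_replicates(unstable_after, 1, cfg), "diverged")
})
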