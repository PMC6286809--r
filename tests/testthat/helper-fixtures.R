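# Fixtures built in code: random stable Jacobians and an independent
# brute-force assembly of the vectorized Lyapunov operator.

# Random Hurwitz-stable sparse Jacobian (diagonal dominance).
random_stable_jacobian <- function(n, density = 0.3, seed = 1) {
  set.seed(seed)
  J <- matrix(stats::runif(n * n, -1, 1) * (stats::runif(n * n) < density), n, n)
  diag(J) <- -(rowSums(abs(J)) + stats::runif(n, 0.5, 1.5))
  J
}

# Independent oracle for the vectorized operator: writes each of the n^2
# scalar balance equations of J C + C J' entry by entry. Row for entry
# (i, j): coefficient of J[i, k] is C[k, j]; coefficient of J[j, k] is
# C[i, k]. Column-major position of (i, j) is (j - 1) * n + i.
brute_force_A <- function(C) {
  n <- nrow(C)
  A <- matrix(0, n * n, n * n)
  pos <- function(i, j) (j - 1L) * n + i
  for (i in seq_len(n)) for (j in seq_len(n)) {
    row <- pos(i, j)
    for (k in seq_len(n)) {
      A[row, pos(i, k)] <- A[row, pos(i, k)] + C[k, j]
      A[row, pos(j, k)] <- A[row, pos(j, k)] + C[i, k]
    }
  }
  A
}

# Hand-built candidate for ensemble tests.
make_candidate <- function(structure, residual, floor = 0) {
  structure(list(structure = as.integer(structure),
                 zero_count = sum(structure == 0),
                 j_values = numeric(sum(structure != 0)),
                 support = which(structure != 0),
                 residual = residual, residual_floor = floor,
                 fitness = NA_real_),
            class = "candidate_solution")
}

# Small exact-covariance system with known ground truth.
toy_exact_system <- function(n = 5, density = 0.2, seed = 3, fluct = 0.005) {
  model <- make_toy_network(n, density = density, seed = seed)
  J <- model$parameters$J
  D <- rep(fluct, n)
  C <- forward_solve_covariance(J, D)
  list(model = model, J = J, D = D, C = C,
       sys = vectorize_lyapunov(C, D),
       truth = as.integer(as.vector(J) != 0))
}
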