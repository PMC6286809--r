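test_that("generated individuals always satisfy minimum sparsity", {
  cfg <- ga_config(min_sparsity = 0.5)
  set.seed(1)
  n <- 4
  for (i in 1:500) {
    bits <- create_individual(n, cfg)
    expect_lte(sum(bits), 8)  # at most half of 16 positions
    expect_gte(sum(bits), 1)
  }
})

test_that("min_sparsity = 0 admits any bitstring including all ones", {
  cfg <- ga_config(min_sparsity = 0)
  set.seed(2)
  ones <- replicate(2000, sum(create_individual(3, cfg)))
  expect_true(any(ones == 9))  # all-ones reachable
  expect_true(all(ones >= 1))
})

test_that("prior mask positions are forced in created individuals", {
  n <- 4
  cfg <- ga_config(min_sparsity = 0.5)
  mask <- prior_mask(known_zero = cbind(2, 3), known_nonzero = cbind(1, 1), n = n)
  pos_zero <- (3 - 1) * n + 2
  pos_one <- 1
  set.seed(3)
  for (i in 1:1000) {
    bits <- create_individual(n, cfg, mask)
    expect_identical(bits[pos_zero], 0L)
    expect_identical(bits[pos_one], 1L)
  }
})

test_that("infeasible masks are rejected", {
  # forcing 9 of 9 positions nonzero cannot meet 50% sparsity
  mask <- prior_mask(known_nonzero = cbind(rep(1:3, 3), rep(1:3, each = 3)), n = 3)
  expect_error(create_individual(3, ga_config(min_sparsity = 0.5), mask),
               "infeasible")
  expect_error(prior_mask(known_zero = cbind(1, 1), known_nonzero = cbind(1, 1), n = 2),
               "contradictory")
})

test_that("crossover of identical parents returns the parents", {
  cfg <- ga_config()
  set.seed(4)
  p <- create_individual(4, cfg)
  kids <- crossover(p, p, cfg)
  expect_identical(kids[[1]], p)
  expect_identical(kids[[2]], p)
})

test_that("crossover children are always repaired onto the constraint set", {
  n <- 4
  cfg <- ga_config(min_sparsity = 0.5)
  mask <- prior_mask(known_zero = cbind(4, 4), n = n)
  pos_zero <- (4 - 1) * n + 4
  set.seed(5)
  violations <- 0
  for (i in 1:1000) {
    pa <- create_individual(n, cfg, mask)
    pb <- create_individual(n, cfg, mask)
    kids <- crossover(pa, pb, cfg, mask)
    for (kid in kids) {
      if (sum(kid) > 8 || kid[pos_zero] != 0L) violations <- violations + 1
      # each bit agrees with at least one parent except where repair applied:
      # a disagreeing 1 can only come from the empty-structure repair, which
      # sets a single bit
      disagreeing <- which(kid != pa & kid != pb)
      if (length(disagreeing) > 0 && any(kid[disagreeing] == 1L) &&
          sum(kid) != 1L) {
        violations <- violations + 1
      }
    }
  }
  expect_identical(violations, 0)
})

test_that("zero mutation rate is the identity", {
  cfg <- ga_config(mutation_rate = 0)
  set.seed(6)
  p <- create_individual(5, cfg)
  expect_identical(mutate(p, cfg), p)
})

test_that("mutation flips free bits at the configured rate and respects constraints", {
  n <- 4
  cfg <- ga_config(mutation_rate = 0.05, min_sparsity = 0)
  base <- rep(c(1L, 0L), 8)  # half-dense, 16 bits
  set.seed(7)
  flips <- numeric(10000)
  for (i in 1:10000) {
    mutant <- mutate(base, cfg)
    flips[i] <- mean(mutant != base)
  }
  expect_gt(mean(flips), 0.045)
  expect_lt(mean(flips), 0.055)

  cfg_s <- ga_config(mutation_rate = 0.3, min_sparsity = 0.5)
  set.seed(8)
  p <- create_individual(n, cfg_s)
  for (i in 1:10000) {
    p <- mutate(p, cfg_s)
    if (sum(p) > 8 || sum(p) < 1) fail("sparsity constraint violated by mutation")
  }
  succeed()
})

test_that("fitness combines the zero count and log residual as specified", {
  # an exactly solvable 2x2 diagonal system lets us hand-check the terms
  sys <- vectorize_lyapunov(diag(c(2, 3)), c(1, 2))
  cand <- evaluate_fitness(c(1L, 0L, 0L, 1L), sys, lam = 0.05)
  expect_identical(cand$zero_count, 2L)
  # residual at the floor: fitness = 2 * 0.05 - log10(floor)
  expect_equal(cand$fitness, 2 * 0.05 - log10(max(cand$residual, cand$residual_floor)))
  # fitted values solve 2*c_ii*j_ii = -2*d_i exactly
  expect_equal(cand$j_values, c(-1 / 2, -2 / 3), tolerance = 1e-10)

  # worked arithmetic: 100 zeros, lambda 0.05, residual 1e-6 gives f = 11
  cand$zero_count <- 100L
  f <- 100 * 0.05 - log10(1e-6)
  expect_equal(f, 11)

  # all-zero structure gets worst fitness, not an error
  worst <- evaluate_fitness(integer(4), sys, 0.05)
  expect_identical(worst$fitness, -Inf)

  # lambda = 0 ranks by residual only
  a <- evaluate_fitness(c(1L, 1L, 1L, 1L), sys, 0)
  expect_equal(a$fitness, -log10(max(a$residual, a$residual_floor)))
})

test_that("GA is deterministic given a seed and degenerates gracefully", {
  fx <- toy_exact_system(n = 4, density = 0.25, seed = 11)
  cfg <- ga_config(max_generations = 30, population_size = 20)
  b1 <- run_ga(fx$sys, 0.05, cfg, seed = 99)
  b2 <- run_ga(fx$sys, 0.05, cfg, seed = 99)
  expect_identical(b1$structure, b2$structure)
  expect_identical(b1$fitness, b2$fitness)

  # population of 1 with no mutation returns the initial individual
  cfg1 <- ga_config(max_generations = 10, population_size = 1, mutation_rate = 0.05)
  set.seed(123)
  b <- run_ga(fx$sys, 0.05, cfg1, seed = 123)
  set.seed(123)
  init <- create_individual(4, cfg1)
  expect_identical(b$structure, init)
})

test_that("best fitness trace is non-decreasing (elitism)", {
  fx <- toy_exact_system(n = 5, seed = 3)
  b <- run_ga(fx$sys, 0.05, ga_config(max_generations = 60, population_size = 30),
              seed = 5)
  h <- attr(b, "history")
  expect_true(all(diff(h) >= 0))
})

test_that("every structure evaluated by the GA satisfies sparsity and mask", {
  # instrument the fitness function by running the GA and re-checking the
  # final population implicitly through a masked, tightly constrained run
  n <- 4
  mask <- prior_mask(known_zero = cbind(c(1, 2), c(2, 1)), n = n)
  fx <- toy_exact_system(n = n, density = 0.25, seed = 11)
  cfg <- ga_config(max_generations = 40, population_size = 25, min_sparsity = 0.5)
  seen <- new.env(); seen$bad <- 0
  trace_eval <- evaluate_fitness
  testthat::with_mocked_bindings(
    evaluate_fitness = function(structure, sys, lam) {
      s <- as.integer(structure != 0)
      if (sum(s) > 8 || any(s[c(5, 2)] != 0)) seen$bad <- seen$bad + 1
      trace_eval(structure, sys, lam)
    },
    run_ga(fx$sys, 0.03, cfg, mask, seed = 17),
    .package = "lyapnet"
  )
  expect_identical(seen$bad, 0)
})

test_that("lambda scan produces the configured candidate count in stable order", {
  fx <- toy_exact_system(n = 3, density = 0.2, seed = 21)
  cfg <- ga_config(max_generations = 2, population_size = 4,
                   lambda_grid = c(0.02, 0.05), repeats_per_lambda = 3,
                   rng_seed = 1)
  cands <- lambda_scan(fx$sys, cfg)
  expect_length(cands, 6)
  expect_equal(vapply(cands, attr, numeric(1), "lambda"),
               rep(c(0.02, 0.05), each = 3))
  expect_equal(vapply(cands, attr, numeric(1), "repeat_index"), rep(1:3, 2))

  # a grid of one lambda and one repeat equals a single seeded run
  cfg1 <- ga_config(max_generations = 2, population_size = 4,
                    lambda_grid = 0.05, repeats_per_lambda = 1, rng_seed = 1)
  single <- lambda_scan(fx$sys, cfg1)
  direct <- run_ga(fx$sys, 0.05, cfg1, seed = cfg1$rng_seed + 1000L + 1L)
  expect_identical(single[[1]]$structure, direct$structure)
})

test_that("mean zero count of best-found candidates is non-decreasing in lambda", {
  fx <- toy_exact_system(n = 4, density = 0.25, seed = 11)
  cfg <- ga_config(max_generations = 40, population_size = 25,
                   lambda_grid = c(0.005, 0.05, 0.3), repeats_per_lambda = 4,
                   rng_seed = 2)
  cands <- lambda_scan(fx$sys, cfg)
  lam <- vapply(cands, attr, numeric(1), "lambda")
  zc <- vapply(cands, `[[`, numeric(1), "zero_count")
  means <- tapply(zc, lam, mean)
  expect_true(all(diff(means) >= 0))
})
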