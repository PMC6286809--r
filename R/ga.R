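## Sparsity-constrained genetic algorithm over Jacobian structures.
##
## Individuals are 0/1 bitstrings of length n^2 (column-major positions of
## the Jacobian). The minimum-sparsity constraint and any prior-knowledge
## mask are intrinsic: creation, crossover and mutation only ever emit
## admissible bitstrings (repair, never rejection sampling).

#' Genetic algorithm configuration
#'
#' Defaults follow the reference protocol for small metabolic networks:
#' 800 generations, 5\% mutation, a minimum Jacobian sparsity of 50\%
#' (metabolic networks empirically exceed 0.55), and a scan of the sparsity
#' scaling factor lambda over 0.01-0.10 in steps of 0.005 with 10 repeated
#' runs per lambda (about 200 best-found candidates per inference).
#'
#' Population size, selection and elitism are not part of that protocol and
#' are this package's choices: population 200, tournament selection of size
#' 2, 5\% elitism.
#'
#' @param max_generations generations per GA run.
#' @param mutation_rate per-bit flip probability for free (unmasked) bits.
#' @param min_sparsity minimum fraction of zero entries in any candidate
#'   Jacobian, in `[0, 1)`.
#' @param population_size individuals per generation.
#' @param lambda_grid strictly positive scaling factors to scan.
#' @param repeats_per_lambda independent GA runs per lambda value.
#' @param rng_seed master seed; run-level seeds are derived as
#'   `rng_seed + 1000 * lambda_index + repeat_index`.
#' @param tournament_size competitors per tournament draw.
#' @param elitism_frac fraction of the population copied unchanged.
#' @param crossover_fraction fraction of non-elite children produced by
#'   crossover; the remainder are mutation-only children.
#' @param stall_generations optional early stop after this many generations
#'   without improvement of the best fitness; `NULL` (default) disables it.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(max_generations = 800L,
                      mutation_rate = 0.05,
                      min_sparsity = 0.5,
                      population_size = 200L,
                      lambda_grid = seq(0.01, 0.10, by = 0.005),
                      repeats_per_lambda = 10L,
                      rng_seed = 1L,
                      tournament_size = 2L,
                      elitism_frac = 0.05,
                      crossover_fraction = 0.8,
                      stall_generations = NULL) {
  stopifnot(max_generations >= 1, population_size >= 1,
            repeats_per_lambda >= 1, tournament_size >= 1)
  if (min_sparsity < 0 || min_sparsity >= 1) stop("min_sparsity must be in [0, 1)")
  if (mutation_rate < 0 || mutation_rate >= 1) stop("mutation_rate must be in [0, 1)")
  if (any(lambda_grid <= 0)) stop("lambda_grid must be strictly positive")
  structure(list(max_generations = as.integer(max_generations),
                 mutation_rate = mutation_rate,
                 min_sparsity = min_sparsity,
                 population_size = as.integer(population_size),
                 lambda_grid = as.numeric(lambda_grid),
                 repeats_per_lambda = as.integer(repeats_per_lambda),
                 rng_seed = as.integer(rng_seed),
                 tournament_size = as.integer(tournament_size),
                 elitism_frac = elitism_frac,
                 crossover_fraction = crossover_fraction,
                 stall_generations = stall_generations),
            class = "ga_config")
}

#' Prior-knowledge mask over Jacobian positions
#'
#' Positions known a priori to be absent (`known_zero`, true negatives) or
#' present (`known_nonzero`) in the Jacobian. Positions are `(i, j)` pairs:
#' row i is the affected metabolite, column j the influencing one.
#'
#' @param known_zero,known_nonzero two-column integer matrices of `(i, j)`
#'   pairs (or `NULL`).
#' @param n network dimension.
#' @return list of class `prior_mask` with linear (column-major) position
#'   sets `zero` and `nonzero`.
#' @export
prior_mask <- function(known_zero = NULL, known_nonzero = NULL, n) {
  to_pos <- function(ij) {
    if (is.null(ij) || NROW(ij) == 0L) return(integer(0))
    ij <- matrix(as.integer(ij), ncol = 2)
    if (any(ij < 1L) || any(ij > n)) stop("mask position out of range 1..", n)
    sort(unique((ij[, 2] - 1L) * n + ij[, 1]))
  }
  zero <- to_pos(known_zero)
  nonzero <- to_pos(known_nonzero)
  if (length(intersect(zero, nonzero)) > 0L) {
    stop("contradictory prior mask: positions listed as both zero and nonzero")
  }
  structure(list(zero = zero, nonzero = nonzero, n = as.integer(n)),
            class = "prior_mask")
}

empty_mask <- function(n) prior_mask(NULL, NULL, n)

## Feasible range for the number of ones under the sparsity constraint and
## mask. Errors if infeasible.
.ones_range <- function(n, cfg, mask) {
  L <- n * n
  max_ones <- floor(L * (1 - cfg$min_sparsity))
  forced <- length(mask$nonzero)
  free <- L - length(mask$zero) - forced
  lo <- max(1L, forced)
  hi <- min(max_ones, forced + free)
  if (hi < lo) {
    stop("infeasible prior mask: ", forced, " forced-present positions ",
         "exceed the maximum of ", max_ones,
         " ones allowed at min_sparsity = ", cfg$min_sparsity)
  }
  list(lo = lo, hi = hi, max_ones = max_ones,
       free_pos = setdiff(seq_len(L), c(mask$zero, mask$nonzero)))
}

#' Create an admissible random Jacobian structure
#'
#' The number of ones is drawn uniformly from the feasible range (so the
#' sparsity constraint holds by construction, never by rejection sampling)
#' and placed uniformly at random over positions not fixed by the mask;
#' masked positions are set accordingly.
#'
#' @param n network dimension.
#' @param cfg `ga_config`.
#' @param mask `prior_mask` (or `NULL`).
#' @return integer 0/1 vector of length `n^2`.
#' @export
create_individual <- function(n, cfg, mask = NULL) {
  if (is.null(mask)) mask <- empty_mask(n)
  rng <- .ones_range(n, cfg, mask)
  k <- if (rng$hi > rng$lo) rng$lo + sample.int(rng$hi - rng$lo + 1L, 1L) - 1L else rng$lo
  bits <- integer(n * n)
  bits[mask$nonzero] <- 1L
  extra <- k - length(mask$nonzero)
  if (extra > 0L && length(rng$free_pos) > 0L) {
    bits[rng$free_pos[sample.int(length(rng$free_pos), min(extra, length(rng$free_pos)))]] <- 1L
  }
  bits
}

## Repair a bitstring so that the mask and sparsity constraint hold and at
## least one bit is set: masked positions are forced, then randomly chosen
## free 1-bits are flipped to 0 until the allowed count is met.
.repair <- function(bits, cfg, mask, max_ones) {
  bits[mask$zero] <- 0L
  bits[mask$nonzero] <- 1L
  excess <- sum(bits) - max_ones
  if (excess > 0L) {
    removable <- setdiff(which(bits == 1L), mask$nonzero)
    drop <- if (length(removable) > 1L) {
      removable[sample.int(length(removable), excess)]
    } else removable
    bits[drop] <- 0L
  }
  if (sum(bits) == 0L) {
    free <- setdiff(seq_along(bits), mask$zero)
    bits[free[sample.int(length(free), 1L)]] <- 1L
  }
  bits
}

#' Uniform crossover of two Jacobian structures
#'
#' Each bit of the first child is taken from either parent with equal
#' probability; the second child takes the complementary choices. Children
#' are repaired back onto the constraint set.
#'
#' @param parent_a,parent_b admissible 0/1 vectors.
#' @inheritParams create_individual
#' @return list of two children.
#' @export
crossover <- function(parent_a, parent_b, cfg, mask = NULL) {
  n <- as.integer(sqrt(length(parent_a)))
  if (is.null(mask)) mask <- empty_mask(n)
  max_ones <- .ones_range(n, cfg, mask)$max_ones
  pick <- stats::runif(length(parent_a)) < 0.5
  child_a <- ifelse(pick, parent_a, parent_b)
  child_b <- ifelse(pick, parent_b, parent_a)
  list(.repair(as.integer(child_a), cfg, mask, max_ones),
       .repair(as.integer(child_b), cfg, mask, max_ones))
}

#' Bit-flip mutation of a Jacobian structure
#'
#' Each free (unmasked) bit flips independently with probability
#' `cfg$mutation_rate`; the result is repaired back onto the constraint set.
#'
#' @param individual admissible 0/1 vector.
#' @inheritParams create_individual
#' @return mutated admissible 0/1 vector.
#' @export
mutate <- function(individual, cfg, mask = NULL) {
  n <- as.integer(sqrt(length(individual)))
  if (is.null(mask)) mask <- empty_mask(n)
  rng <- .ones_range(n, cfg, mask)
  if (cfg$mutation_rate > 0 && length(rng$free_pos) > 0L) {
    flip <- rng$free_pos[stats::runif(length(rng$free_pos)) < cfg$mutation_rate]
    individual[flip] <- 1L - individual[flip]
  }
  .repair(as.integer(individual), cfg, mask, rng$max_ones)
}

#' Evaluate the dual objective for a candidate structure
#'
#' Fitness is `f = zero_count * lambda - log10(||A_r j_r + 2 d||)`: sparsity
#' is rewarded, the Lyapunov residual of the least-squares fit on the
#' candidate support is penalized. Before taking log10, residuals are
#' clamped below at the roundoff floor of the fit,
#' `100 * eps * ||2 d||` (and absolutely at 1e-300): residuals below the
#' floor are numerically indistinguishable from an exact fit, and without
#' the clamp their meaningless log10 differences would swamp the sparsity
#' term whenever several supports fit exactly (as with noise-free
#' covariances). An all-zero structure is assigned `-Inf` fitness rather
#' than erroring, for robustness inside the search.
#'
#' @param structure 0/1 vector of length `n^2`.
#' @param sys `vectorized_system`.
#' @param lam scaling factor lambda (> 0, or 0 to rank by residual alone).
#' @return list of class `candidate_solution`: `structure`, `zero_count`,
#'   `j_values` (fitted values on the support), `support`, `residual`,
#'   `fitness`.
#' @export
evaluate_fitness <- function(structure, sys, lam) {
  structure <- as.integer(structure != 0)
  L <- length(sys$d)
  zero_count <- L - sum(structure)
  floor_ <- max(1e-300,
                100 * .Machine$double.eps * sqrt(sum((2 * sys$d)^2)))
  if (zero_count == L) {
    return(base::structure(list(structure = structure, zero_count = zero_count,
                                j_values = numeric(0), support = integer(0),
                                residual = Inf, residual_floor = floor_,
                                fitness = -Inf),
                           class = "candidate_solution"))
  }
  support <- which(structure == 1L)
  fit <- .fast_lstsq(sys$A[, support, drop = FALSE], -2 * sys$d)
  res <- max(fit$residual, floor_)
  base::structure(list(structure = structure, zero_count = zero_count,
                       j_values = fit$j_r, support = support,
                       residual = fit$residual, residual_floor = floor_,
                       fitness = zero_count * lam - log10(res)),
                  class = "candidate_solution")
}

#' @export
print.candidate_solution <- function(x, ...) {
  cat("candidate Jacobian structure: ", length(x$support), " edges, ",
      x$zero_count, " zeros (sparsity ",
      format(x$zero_count / length(x$structure), digits = 3), ")\n",
      "residual ", format(x$residual, digits = 4),
      ", fitness ", format(x$fitness, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Run one genetic-algorithm search for a fixed lambda
#'
#' Standard generational GA with elitism: the top `elitism_frac` fraction is
#' copied unchanged, the remainder produced by tournament selection, uniform
#' crossover and bit-flip mutation. Returns the best individual ever
#' evaluated; the best fitness trace is non-decreasing. Fully deterministic
#' given `seed`.
#'
#' @param sys `vectorized_system`.
#' @param lam scaling factor lambda.
#' @param cfg `ga_config`.
#' @param mask `prior_mask` or `NULL`.
#' @param seed run seed (defaults to `cfg$rng_seed`).
#' @return best `candidate_solution`, with attributes `history` (best
#'   fitness per generation) and `seed`.
#' @export
run_ga <- function(sys, lam, cfg, mask = NULL, seed = cfg$rng_seed) {
  stopifnot(inherits(sys, "vectorized_system"))
  n <- sys$n
  if (is.null(mask)) mask <- empty_mask(n)
  set.seed(seed)
  pop_size <- cfg$population_size
  pop <- matrix(0L, pop_size, n * n)
  for (i in seq_len(pop_size)) pop[i, ] <- create_individual(n, cfg, mask)

  eval_row <- function(bits) evaluate_fitness(bits, sys, lam)
  cands <- apply(pop, 1L, eval_row)
  fitness <- vapply(cands, `[[`, numeric(1), "fitness")
  best <- cands[[which.max(fitness)]]
  history <- numeric(cfg$max_generations)
  n_elite <- max(1L, round(cfg$elitism_frac * pop_size))
  stall <- 0L

  for (gen in seq_len(cfg$max_generations)) {
    if (pop_size > 1L) {
      elite_idx <- order(fitness, decreasing = TRUE)[seq_len(n_elite)]
      n_child <- pop_size - n_elite
      ## tournament selection of parents
      pick_parent <- function() {
        comp <- sample.int(pop_size, cfg$tournament_size, replace = TRUE)
        comp[which.max(fitness[comp])]
      }
      ## crossover-only children exploit recombination; mutation-only
      ## children explore (MATLAB-ga-style split, not crossover+mutation)
      n_cross <- round((cfg$crossover_fraction %||% 0.8) * n_child)
      children <- vector("list", n_child)
      ci <- 1L
      while (ci <= n_cross) {
        pa <- pop[pick_parent(), ]
        pb <- pop[pick_parent(), ]
        kids <- crossover(pa, pb, cfg, mask)
        children[[ci]] <- kids[[1L]]
        ci <- ci + 1L
        if (ci <= n_cross) {
          children[[ci]] <- kids[[2L]]
          ci <- ci + 1L
        }
      }
      while (ci <= n_child) {
        children[[ci]] <- mutate(pop[pick_parent(), ], cfg, mask)
        ci <- ci + 1L
      }
      child_cands <- lapply(children, eval_row)
      child_fit <- vapply(child_cands, `[[`, numeric(1), "fitness")
      new_pop <- rbind(pop[elite_idx, , drop = FALSE],
                       do.call(rbind, children))
      fitness <- c(fitness[elite_idx], child_fit)
      pop <- new_pop
      gen_best_i <- which.max(child_fit)
      if (length(child_fit) && child_fit[gen_best_i] > best$fitness) {
        best <- child_cands[[gen_best_i]]
        stall <- 0L
      } else stall <- stall + 1L
    } else {
      ## degenerate single-individual population: elitism keeps it unchanged
      stall <- stall + 1L
    }
    history[gen] <- best$fitness
    if (!is.null(cfg$stall_generations) && stall >= cfg$stall_generations) {
      history <- history[seq_len(gen)]
      break
    }
  }
  attr(best, "history") <- history
  attr(best, "seed") <- seed
  best
}

#' Scan the sparsity scaling factor
#'
#' Runs `repeats_per_lambda` independent seeded GA searches for every lambda
#' in `cfg$lambda_grid` (default grid: 19 values x 10 repeats = 190
#' best-found candidates). Run-level seeds are derived from the master seed
#' as `rng_seed + 1000 * lambda_index + repeat_index`, so results are
#' identical whether runs execute serially or concurrently.
#'
#' @param sys `vectorized_system`.
#' @param cfg `ga_config`.
#' @param mask `prior_mask` or `NULL`.
#' @param progress print one line per completed run.
#' @return list of `candidate_solution`s ordered by lambda then repeat
#'   index; each carries attributes `lambda`, `repeat_index`, `run_index`.
#' @export
lambda_scan <- function(sys, cfg, mask = NULL, progress = FALSE) {
  out <- vector("list", length(cfg$lambda_grid) * cfg$repeats_per_lambda)
  k <- 0L
  for (li in seq_along(cfg$lambda_grid)) {
    lam <- cfg$lambda_grid[li]
    for (ri in seq_len(cfg$repeats_per_lambda)) {
      seed <- cfg$rng_seed + 1000L * li + ri
      cand <- run_ga(sys, lam, cfg, mask, seed = seed)
      k <- k + 1L
      attr(cand, "lambda") <- lam
      attr(cand, "repeat_index") <- ri
      attr(cand, "run_index") <- k
      out[[k]] <- cand
      if (progress) {
        message(sprintf("lambda %.3f repeat %d: fitness %.4f, %d zeros, residual %.3e",
                        lam, ri, cand$fitness, cand$zero_count, cand$residual))
      }
    }
  }
  out
}
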