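## Scripted benchmark experiments: exact-covariance recovery, noisy
## covariances, replicate-count sweeps, normalization and prior knowledge.
## These drive the full method end to end on models with known ground
## truth and report TPR/FPR/g-score tables.

## Exact covariance of a kinetic model under diagonal fluctuations: the
## forward Lyapunov solve at the model's true Jacobian.
model_ground_truth <- function(model, fluctuations = 0.005) {
  C_s <- find_steady_state(model)
  J <- true_jacobian(model, C_s)
  D <- fluctuation_spec(rep_len(fluctuations, model$n), names = model$names,
                        strict = TRUE)
  list(C_s = C_s, J = J, D = D,
       structure = (abs(J) > 1e-10) * 1L,
       C_exact = forward_solve_covariance(J, D))
}

#' Repeated exact-covariance recovery runs
#'
#' Runs the full inference pipeline `n_runs` times (master seeds
#' `seed, seed + 1, ...`) on the exact covariance of `model` under
#' diagonal fluctuations, and reports per-run TPR/FPR plus the fraction of
#' runs recovering the true structure perfectly.
#'
#' @param model `kinetic_model` with a stable steady state.
#' @param n_runs number of independent pipeline runs.
#' @param cfg `ga_config` (its `rng_seed` is overridden per run).
#' @param bounds `community_bounds`.
#' @param fluctuations diagonal fluctuation magnitude(s), default 0.005.
#' @param seed first master seed.
#' @return data.frame (run, tpr, fpr, g_score, perfect) with attribute
#'   `recovery_rate`.
#' @export
benchmark_exact_recovery <- function(model, n_runs = 20L, cfg = ga_config(),
                                     bounds = community_bounds(),
                                     fluctuations = 0.005, seed = 1L) {
  gt <- model_ground_truth(model, fluctuations)
  rows <- lapply(seq_len(n_runs), function(r) {
    cfg_r <- cfg
    cfg_r$rng_seed <- as.integer(seed + r - 1L)
    res <- infer_network(C = gt$C_exact, D = gt$D, cfg = cfg_r, bounds = bounds)
    ev <- tpr_fpr(res$structure, gt$structure)
    data.frame(run = r, tpr = ev$tpr, fpr = ev$fpr, g_score = ev$g_score,
               perfect = ev$tpr == 1 && ev$fpr == 0)
  })
  out <- do.call(rbind, rows)
  attr(out, "recovery_rate") <- mean(out$perfect)
  out
}

#' Noisy-covariance experiment
#'
#' Applies N(1, `noise_sd`) symmetric multiplicative noise to the exact
#' covariance of `model`, `n_noisy` times, infers a network from each noisy
#' covariance, and evaluates the consensus at binarization thresholds 0.5
#' and 0.4.
#'
#' @inheritParams benchmark_exact_recovery
#' @param n_noisy number of noisy covariance draws.
#' @param noise_sd standard deviation of the multiplicative factors.
#' @return data.frame (draw, threshold, tpr, fpr, g_score).
#' @export
benchmark_noisy_covariance <- function(model, n_noisy = 10L,
                                       cfg = ga_config(),
                                       bounds = community_bounds(),
                                       noise_sd = 0.005,
                                       fluctuations = 0.005, seed = 1L) {
  gt <- model_ground_truth(model, fluctuations)
  rows <- list()
  for (k in seq_len(n_noisy)) {
    Ck <- noisy_covariance(gt$C_exact, noise_sd = noise_sd, seed = seed + k)
    cfg_k <- cfg
    cfg_k$rng_seed <- as.integer(seed + 100L * k)
    res <- infer_network(C = Ck, D = gt$D, cfg = cfg_k, bounds = bounds)
    for (thr in c(0.5, 0.4)) {
      final <- (res$support >= thr) * 1L
      ev <- tpr_fpr(final, gt$structure)
      rows[[length(rows) + 1L]] <-
        data.frame(draw = k, threshold = thr, tpr = ev$tpr, fpr = ev$fpr,
                   g_score = ev$g_score)
    }
  }
  do.call(rbind, rows)
}

#' Replicate-count sweep on simulated SDE data
#'
#' Generates a pool of SDE replicates from `model`, then for each
#' `m` in `m_values` and each of `n_draws` random subsamples runs both the
#' Lyapunov/GA pipeline and the GGM baseline, reporting g-scores. GGM is
#' evaluated off-diagonal (it infers no self-loops) against the
#' symmetrized true structure (it is undirected); the pipeline is evaluated
#' over all positions against the directed truth.
#'
#' @inheritParams benchmark_exact_recovery
#' @param m_values replicate counts to test.
#' @param n_draws random subsamples per replicate count.
#' @param sde `sde_config` for the replicate pool (its `n_replicates` must
#'   cover `max(m_values)`).
#' @param ggm_cutoff p-value cutoff for the GGM baseline.
#' @return data.frame (method, m, draw, tpr, fpr, g_score).
#' @export
benchmark_replicate_count <- function(model, m_values = c(100L, 1000L),
                                      n_draws = 10L, cfg = ga_config(),
                                      bounds = community_bounds(),
                                      sde = sde_config(), ggm_cutoff = 0.01,
                                      seed = 1L) {
  gt <- model_ground_truth(model, sde$fluctuations)
  sde$n_replicates <- max(m_values, sde$n_replicates)
  sde$seed <- as.integer(seed)
  pool <- simulate_replicates(model, gt$C_s, sde)
  truth_undirected <- ((gt$structure + t(gt$structure)) > 0) * 1L
  rows <- list()
  for (m in m_values) {
    for (dr in seq_len(n_draws)) {
      set.seed(seed + 10000L * dr + m)
      idx <- sample.int(nrow(pool$matrix), m)
      sub <- replicate_dataset(pool$matrix[idx, , drop = FALSE],
                               pool$metabolite_names, "simulated")
      cfg_d <- cfg
      cfg_d$rng_seed <- as.integer(seed + 100L * dr + m)
      res <- infer_network(data = sub, cfg = cfg_d, bounds = bounds)
      ev <- tpr_fpr(res$structure, gt$structure)
      rows[[length(rows) + 1L]] <-
        data.frame(method = "lyapunov_ga", m = m, draw = dr,
                   tpr = ev$tpr, fpr = ev$fpr, g_score = ev$g_score)
      gg <- ggm_infer(sub, p_cutoff = ggm_cutoff)
      evg <- tpr_fpr(gg$adjacency, truth_undirected, include_diagonal = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(method = "ggm", m = m, draw = dr,
                   tpr = evg$tpr, fpr = evg$fpr, g_score = evg$g_score)
    }
  }
  do.call(rbind, rows)
}

#' Prior-knowledge experiment
#'
#' Selects `n_known_zero` true-zero Jacobian positions at random as known
#' true negatives, repeats inference `n_repeats` times with and without the
#' mask on paired master seeds, and reports both arms.
#'
#' @inheritParams benchmark_exact_recovery
#' @param n_known_zero number of known-zero positions supplied as priors.
#' @param n_repeats repeats (fresh mask draw and seed each time).
#' @return data.frame (arm, repeat_index, tpr, fpr, g_score).
#' @export
benchmark_prior_knowledge <- function(model, n_known_zero = 7L,
                                      n_repeats = 10L, cfg = ga_config(),
                                      bounds = community_bounds(),
                                      fluctuations = 0.005, seed = 1L) {
  gt <- model_ground_truth(model, fluctuations)
  zero_pos <- which(gt$structure == 0L)
  rows <- list()
  for (r in seq_len(n_repeats)) {
    set.seed(seed + r)
    chosen <- sample(zero_pos, n_known_zero)
    ij <- arrayInd(chosen, dim(gt$structure))
    mask <- prior_mask(known_zero = ij, n = model$n)
    cfg_r <- cfg
    cfg_r$rng_seed <- as.integer(seed + 100L * r)
    for (arm in c("masked", "unmasked")) {
      res <- infer_network(C = gt$C_exact, D = gt$D, cfg = cfg_r,
                           bounds = bounds,
                           mask = if (arm == "masked") mask else NULL)
      ev <- tpr_fpr(res$structure, gt$structure)
      rows[[length(rows) + 1L]] <-
        data.frame(arm = arm, repeat_index = r, tpr = ev$tpr, fpr = ev$fpr,
                   g_score = ev$g_score)
    }
  }
  do.call(rbind, rows)
}

#' Normalization experiment on simulated SDE data
#'
#' Runs the pipeline on raw and on globally max-normalized SDE replicates
#' (paired seeds) and reports both, alongside the GGM baseline, which is
#' invariant to such rescaling.
#'
#' @inheritParams benchmark_replicate_count
#' @return data.frame (method, normalized, tpr, fpr, g_score).
#' @export
benchmark_normalization <- function(model, cfg = ga_config(),
                                    bounds = community_bounds(),
                                    sde = sde_config(), ggm_cutoff = 0.01,
                                    seed = 1L) {
  gt <- model_ground_truth(model, sde$fluctuations)
  sde$seed <- as.integer(seed)
  data <- simulate_replicates(model, gt$C_s, sde)
  truth_undirected <- ((gt$structure + t(gt$structure)) > 0) * 1L
  rows <- list()
  for (norm in c(FALSE, TRUE)) {
    res <- infer_network(data = data, cfg = cfg, bounds = bounds,
                         normalize = norm)
    ev <- tpr_fpr(res$structure, gt$structure)
    rows[[length(rows) + 1L]] <-
      data.frame(method = "lyapunov_ga", normalized = norm,
                 tpr = ev$tpr, fpr = ev$fpr, g_score = ev$g_score)
  }
  gg <- ggm_infer(data, p_cutoff = ggm_cutoff)
  evg <- tpr_fpr(gg$adjacency, truth_undirected, include_diagonal = FALSE)
  rows[[length(rows) + 1L]] <-
    data.frame(method = "ggm", normalized = NA,
               tpr = evg$tpr, fpr = evg$fpr, g_score = evg$g_score)
  do.call(rbind, rows)
}
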