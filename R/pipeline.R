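## End-to-end inference: replicate data -> covariance + fluctuation
## estimates -> vectorized Lyapunov system -> lambda-scan GA -> community
## consensus -> evaluated, exportable network.

#' Replicate-by-metabolite dataset
#'
#' @param matrix numeric matrix, m replicates (rows) x n metabolites
#'   (columns), concentration units. Column order defines the Jacobian
#'   index order.
#' @param metabolite_names optional column labels (defaults to existing
#'   colnames or M1..Mn).
#' @param provenance one of "measured", "simulated", "normalized".
#' @return object of class `replicate_dataset`.
#' @export
replicate_dataset <- function(matrix, metabolite_names = NULL,
                              provenance = c("measured", "simulated", "normalized")) {
  provenance <- match.arg(provenance)
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix) || anyNA(matrix)) {
    stop("replicate data must be numeric with no missing values")
  }
  if (nrow(matrix) < 2L) stop("at least 2 replicates are required")
  if (is.null(metabolite_names)) {
    metabolite_names <- colnames(matrix)
    if (is.null(metabolite_names)) metabolite_names <- paste0("M", seq_len(ncol(matrix)))
  }
  if (anyDuplicated(metabolite_names)) stop("duplicate metabolite names")
  colnames(matrix) <- metabolite_names
  structure(list(matrix = matrix, metabolite_names = metabolite_names,
                 provenance = provenance),
            class = "replicate_dataset")
}

#' @export
print.replicate_dataset <- function(x, ...) {
  cat("replicate_dataset: ", nrow(x$matrix), " replicates x ",
      ncol(x$matrix), " metabolites (", x$provenance, ")\n", sep = "")
  invisible(x)
}

#' Sample covariance of replicate data
#'
#' Unbiased sample covariance (m - 1 denominator) across replicates.
#'
#' @param data `replicate_dataset`.
#' @return symmetric covariance matrix with metabolite dimnames.
#' @export
compute_covariance <- function(data) {
  stopifnot(inherits(data, "replicate_dataset"))
  C <- stats::cov(data$matrix)
  if (all(C == 0)) stop("constant dataset: covariance matrix is identically zero")
  (C + t(C)) / 2
}

#' Estimate the fluctuation vector from replicate standard deviations
#'
#' The diagonal fluctuation magnitudes D_i are approximated by the sample
#' standard deviation (m - 1 denominator) of each metabolite across
#' replicates; off-diagonal fluctuations are taken as zero.
#'
#' @param data `replicate_dataset`.
#' @return `fluctuation_spec` named by metabolite.
#' @export
estimate_fluctuation <- function(data) {
  stopifnot(inherits(data, "replicate_dataset"))
  sds <- apply(data$matrix, 2L, stats::sd)
  zero <- which(sds == 0)
  if (length(zero) > 0L) {
    stop("zero replicate standard deviation for metabolite(s): ",
         paste(data$metabolite_names[zero], collapse = ", "))
  }
  fluctuation_spec(sds, names = data$metabolite_names, strict = TRUE)
}

#' Normalize a dataset to the unit interval by its global maximum
#'
#' Every value is divided by the single maximum of the whole matrix, so the
#' maximum of the output is 1. Covariances computed downstream scale by
#' 1/max^2 and fluctuation magnitudes by 1/max.
#'
#' @param data `replicate_dataset`.
#' @return normalized `replicate_dataset` with provenance "normalized".
#' @export
normalize_dataset <- function(data) {
  stopifnot(inherits(data, "replicate_dataset"))
  mx <- max(data$matrix)
  if (mx <= 0) stop("cannot normalize: maximum value of the dataset is nonpositive")
  replicate_dataset(data$matrix / mx, data$metabolite_names, "normalized")
}

#' Infer a directed metabolic network from steady-state data
#'
#' Full inference pipeline. Either replicate `data` or a precomputed
#' covariance `C` plus fluctuation vector `D` is accepted; with both, the
#' user-supplied covariance wins (with a warning). Stages: vectorize the
#' Lyapunov equation, scan the sparsity scaling factor with repeated GA
#' runs, select the elite candidate, gather its community, and combine the
#' binarized community structures into the consensus network. Fully
#' reproducible from `cfg$rng_seed`.
#'
#' @param data `replicate_dataset`, or `NULL` when `C` and `D` are given.
#' @param C optional precomputed covariance matrix.
#' @param D optional fluctuation vector (required with `C`).
#' @param cfg `ga_config`.
#' @param bounds `community_bounds`.
#' @param mask optional `prior_mask`.
#' @param normalize divide the data by its global maximum before estimating
#'   `C` and `D` (ignored when a covariance is supplied).
#' @param progress print one line per completed GA run.
#' @return object of class `inference_result`: `structure` (n x n 0/1
#'   adjacency, entry (i, j) = 1 for a directed influence j -> i),
#'   `support` (fractional support matrix), `jacobian` (elite fitted
#'   values embedded in an n x n matrix), `elite`, `community`,
#'   `candidates`, `diagnostics`.
#' @export
infer_network <- function(data = NULL, C = NULL, D = NULL,
                          cfg = ga_config(), bounds = community_bounds(),
                          mask = NULL, normalize = FALSE, progress = FALSE) {
  if (is.null(data) && (is.null(C) || is.null(D))) {
    stop("supply either replicate data or both a covariance matrix and a fluctuation vector")
  }
  if (!is.null(data) && !is.null(C)) {
    warning("both replicate data and a covariance matrix supplied; using the covariance matrix")
    data <- NULL
  }
  if (!is.null(data)) {
    if (normalize) data <- normalize_dataset(data)
    C <- compute_covariance(data)
    D <- estimate_fluctuation(data)
  }
  C <- as_covariance(C)
  n <- nrow(C)
  names <- colnames(C)
  if (is.null(names) && !is.null(attr(D, "names"))) names <- names(D)
  if (is.null(names)) names <- paste0("M", seq_len(n))
  D <- fluctuation_spec(as.numeric(D), names = names, strict = TRUE)

  sys <- withCallingHandlers(
    vectorize_lyapunov(C, D),
    error = function(e) stop("[vectorize] ", conditionMessage(e), call. = FALSE))
  cond <- kappa(sys$A, exact = FALSE)

  candidates <- lambda_scan(sys, cfg, mask, progress = progress)
  elite <- select_elite(candidates)
  community <- select_community(candidates, elite, bounds)
  consensus <- combine_structures(community, bounds,
                                  min_sparsity = cfg$min_sparsity)

  structure_mat <- matrix(consensus$structure, n, n,
                          dimnames = list(names, names))
  support_mat <- matrix(consensus$support, n, n,
                        dimnames = list(names, names))
  per_lambda <- tapply(vapply(candidates, `[[`, numeric(1), "fitness"),
                       vapply(candidates, attr, numeric(1), "lambda"), max)
  structure(list(structure = structure_mat,
                 support = support_mat,
                 jacobian = embed_jacobian(elite$j_values, elite$support, n, names),
                 elite = elite,
                 community = community,
                 candidates = candidates,
                 metabolite_names = names,
                 diagnostics = list(condition_number = cond,
                                    per_lambda_best_fitness = per_lambda,
                                    community_size = length(community),
                                    seed = cfg$rng_seed)),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  n <- nrow(x$structure)
  n_edges <- sum(x$structure)
  cat("inference_result: ", n, " metabolites, ", n_edges,
      " directed edges (sparsity ",
      format(1 - n_edges / n^2, digits = 3), ")\n",
      "elite: ", x$elite$zero_count, " zeros, residual ",
      format(x$elite$residual, digits = 4),
      "; community of ", x$diagnostics$community_size, " candidates\n",
      "condition number of A: ",
      format(x$diagnostics$condition_number, digits = 3), "\n", sep = "")
  invisible(x)
}
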