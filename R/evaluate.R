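## Evaluation metrics for network reconstruction and the Gaussian graphical
## model baseline.

#' True and false positive rates of a reconstructed structure
#'
#' Positions are all n^2 Jacobian entries by default (consistent with the
#' sparsity definition counting every element); set
#' `include_diagonal = FALSE` to evaluate off-diagonal positions only.
#'
#' @param predicted 0/1 matrix or vector (nonzero = edge).
#' @param truth 0/1 matrix or vector of the true structure.
#' @param include_diagonal include diagonal positions in the counts.
#' @return list of class `evaluation_result`: `tpr`, `fpr`, `g_score`,
#'   `positions_evaluated`, `diagonal_included`.
#' @export
tpr_fpr <- function(predicted, truth, include_diagonal = TRUE) {
  p <- as.integer(as.vector(as.matrix(predicted)) != 0)
  t <- as.integer(as.vector(as.matrix(truth)) != 0)
  if (length(p) != length(t)) stop("predicted and true structures differ in size")
  if (!include_diagonal) {
    n <- as.integer(sqrt(length(t)))
    off <- as.vector(!diag(TRUE, n))
    p <- p[off]; t <- t[off]
  }
  pos <- sum(t == 1L)
  neg <- sum(t == 0L)
  if (pos == 0L) stop("true structure has no positives over the evaluated positions; TPR undefined")
  if (neg == 0L) stop("true structure has no negatives over the evaluated positions; FPR undefined")
  tpr <- sum(p == 1L & t == 1L) / pos
  fpr <- sum(p == 1L & t == 0L) / neg
  structure(list(tpr = tpr, fpr = fpr, g_score = g_score(tpr, fpr),
                 positions_evaluated = length(t),
                 diagonal_included = include_diagonal),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("TPR %.3f  FPR %.3f  g-score %.3f  (%d positions%s)\n",
              x$tpr, x$fpr, x$g_score, x$positions_evaluated,
              if (x$diagonal_included) "" else ", diagonal excluded"))
  invisible(x)
}

#' g-score of a reconstruction
#'
#' Single-parameter summary of reconstruction quality:
#' `sqrt(TPR * (1 - FPR))`. Equals 1 only for a perfect reconstruction and
#' 0 whenever no true edge is recovered.
#'
#' @param tpr true positive rate, in `[0, 1]`.
#' @param fpr false positive rate, in `[0, 1]`.
#' @return the g-score.
#' @export
g_score <- function(tpr, fpr) {
  if (any(tpr < 0 | tpr > 1) || any(fpr < 0 | fpr > 1)) {
    stop("TPR and FPR must lie in [0, 1]")
  }
  sqrt(tpr * (1 - fpr))
}

#' Sparsity of a structure
#'
#' Fraction of zero entries over all elements.
#'
#' @param structure 0/1 matrix or vector.
#' @return fraction in `[0, 1]`.
#' @export
sparsity_of <- function(structure) {
  s <- as.vector(as.matrix(structure))
  if (length(s) == 0L) stop("empty structure")
  mean(s == 0)
}

#' Gaussian graphical model inference by full-order partial correlations
#'
#' The baseline undirected method: partial Pearson correlations are read
#' off the inverted correlation matrix,
#' `rho_ij = -p_ij / sqrt(p_ii * p_jj)`, and tested with the two-sided
#' t-test on `m - n` degrees of freedom (conditioning on the other n - 2
#' variables). An undirected edge is kept when `p < p_cutoff`; no
#' multiple-testing correction is applied.
#'
#' @param data `replicate_dataset` with `m > n + 2`.
#' @param p_cutoff significance cutoff on p-values (default 0.01).
#' @return list with `adjacency` (symmetric 0/1 matrix, zero diagonal),
#'   `partial_correlations`, `p_values`, `df`.
#' @export
ggm_infer <- function(data, p_cutoff = 0.01) {
  stopifnot(inherits(data, "replicate_dataset"))
  X <- data$matrix
  m <- nrow(X); n <- ncol(X)
  if (m <= n + 2) {
    stop("GGM needs more replicates than metabolites (m > n + 2); got m = ",
         m, ", n = ", n)
  }
  R <- stats::cor(X)
  P <- tryCatch(solve(R), error = function(e) {
    stop("correlation matrix is singular; more replicates are needed")
  })
  den <- sqrt(diag(P) %o% diag(P))
  pcor <- -P / den
  diag(pcor) <- 1
  df <- m - n
  tstat <- pcor * sqrt(df / pmax(1 - pcor^2, .Machine$double.eps))
  pval <- 2 * stats::pt(-abs(tstat), df)
  diag(pval) <- 1
  adj <- (pval < p_cutoff) * 1L
  diag(adj) <- 0L
  dimnames(adj) <- dimnames(pcor) <- dimnames(pval) <-
    list(data$metabolite_names, data$metabolite_names)
  list(adjacency = adj, partial_correlations = pcor, p_values = pval, df = df)
}

#' Spearman agreement between fitted and true Jacobian values
#'
#' For each candidate in a community, the Spearman rank correlation between
#' its fitted Jacobian values and the true mechanistic Jacobian over the
#' union of both supports (positions nonzero in either).
#'
#' @param candidates list of `candidate_solution`s.
#' @param true_J true n x n Jacobian matrix.
#' @return data.frame with one row per candidate (`rho`, `p_value`),
#'   with the median rho in attribute `median_rho`.
#' @export
jacobian_value_agreement <- function(candidates, true_J) {
  jt <- as.vector(as.matrix(true_J))
  rows <- lapply(candidates, function(cand) {
    jv <- numeric(length(jt))
    jv[cand$support] <- cand$j_values
    pos <- sort(union(cand$support, which(jt != 0)))
    if (length(pos) < 3L) {
      stop("fewer than 3 comparable Jacobian positions; correlation undefined")
    }
    ct <- stats::cor.test(jv[pos], jt[pos], method = "spearman", exact = FALSE)
    data.frame(rho = unname(ct$estimate), p_value = ct$p.value)
  })
  out <- do.call(rbind, rows)
  attr(out, "median_rho") <- stats::median(out$rho)
  out
}

#' Reproducibility of repeated inference runs
#'
#' With a ground-truth structure: fraction of runs whose final structure
#' exactly matches the truth. Without one: fraction matching the modal
#' (most frequent) structure.
#'
#' @param run_outputs list of final 0/1 structures (vectors or matrices).
#' @param truth optional true structure.
#' @return fraction in `[0, 1]`.
#' @export
reproducibility <- function(run_outputs, truth = NULL) {
  if (length(run_outputs) < 2L) stop("at least 2 runs are required")
  keys <- vapply(run_outputs, function(s) {
    paste(as.integer(as.vector(as.matrix(s)) != 0), collapse = "")
  }, character(1))
  if (!is.null(truth)) {
    tk <- paste(as.integer(as.vector(as.matrix(truth)) != 0), collapse = "")
    mean(keys == tk)
  } else {
    max(table(keys)) / length(keys)
  }
}

#' Flat evaluation report over methods and datasets
#'
#' One row per method x dataset with TPR, FPR and g-score, mirroring the
#' usual benchmark-table layout.
#'
#' @param entries list of lists with fields `method`, `dataset`,
#'   `predicted`, `truth`, and optionally `include_diagonal`.
#' @return data.frame with columns method, dataset, tpr, fpr, g_score.
#' @export
evaluation_report <- function(entries) {
  rows <- lapply(entries, function(e) {
    ev <- tpr_fpr(e$predicted, e$truth,
                  include_diagonal = isTRUE(e$include_diagonal %||% TRUE))
    data.frame(method = e$method, dataset = e$dataset,
               tpr = ev$tpr, fpr = ev$fpr, g_score = ev$g_score)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
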