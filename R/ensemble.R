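## Community-of-candidates consensus: instead of trusting the single elite
## candidate from the lambda scan, combine the binarized structures of all
## best-found candidates in a bounded region around the elite.

#' Bounds defining the candidate community and consensus threshold
#'
#' The community keeps candidates whose zero count lies within
#' `zero_tolerance` (default +/-5\%) of the elite's and whose residual is at
#' least `(1 - residual_tolerance)` times the elite's (a lower residual
#' boundary only; the pool already consists of best-found candidates). The
#' consensus network keeps a position when its fractional support reaches
#' `binarization_threshold` (default 0.5; ties at the threshold count as an
#' edge).
#'
#' @param zero_tolerance fraction, in (0, 1).
#' @param residual_tolerance fraction, in (0, 1).
#' @param binarization_threshold fraction, in (0, 1).
#' @return list of class `community_bounds`.
#' @export
community_bounds <- function(zero_tolerance = 0.05,
                             residual_tolerance = 0.05,
                             binarization_threshold = 0.5) {
  stopifnot(zero_tolerance > 0, zero_tolerance < 1,
            residual_tolerance > 0, residual_tolerance < 1,
            binarization_threshold > 0, binarization_threshold < 1)
  structure(list(zero_tolerance = zero_tolerance,
                 residual_tolerance = residual_tolerance,
                 binarization_threshold = binarization_threshold),
            class = "community_bounds")
}

#' Select the elite candidate from a lambda scan
#'
#' Deterministic rule joining sparsity and residual: among candidates whose
#' log10 residual is at or below the median, pick the one with the most
#' zeros; ties broken by smaller residual, then by earliest run index.
#'
#' @param candidates nonempty list of `candidate_solution`s.
#' @return the elite `candidate_solution`.
#' @export
select_elite <- function(candidates) {
  if (length(candidates) == 0L) stop("cannot select an elite from an empty candidate list")
  res <- .effective_residuals(candidates)
  zc <- vapply(candidates, `[[`, numeric(1), "zero_count")
  logres <- log10(pmax(res, 1e-300))
  eligible <- which(logres <= stats::median(logres))
  ord <- order(-zc[eligible], res[eligible], eligible)
  candidates[[eligible[ord[1L]]]]
}

#' Select the community around the elite candidate
#'
#' Keeps candidates with zero count in the band
#' `[floor((1 - tol) * z_e), ceiling((1 + tol) * z_e)]` (rounded outward)
#' and residual `>= (1 - tol_r) * r_e`. The elite is always included.
#'
#' @param candidates list of `candidate_solution`s.
#' @param elite the elite candidate (an element of `candidates`).
#' @param bounds `community_bounds`.
#' @return list of community members (possibly of size 1).
#' @export
select_community <- function(candidates, elite, bounds = community_bounds()) {
  z_e <- elite$zero_count
  r_e <- max(elite$residual, elite$residual_floor %||% 0)
  z_lo <- floor((1 - bounds$zero_tolerance) * z_e)
  z_hi <- ceiling((1 + bounds$zero_tolerance) * z_e)
  r_lo <- (1 - bounds$residual_tolerance) * r_e
  res <- .effective_residuals(candidates)
  keep <- vapply(seq_along(candidates), function(k) {
    cand <- candidates[[k]]
    (cand$zero_count >= z_lo && cand$zero_count <= z_hi &&
       res[k] >= r_lo) || identical(cand$structure, elite$structure)
  }, logical(1))
  candidates[keep]
}

## Residuals compared across candidates are taken at or above the roundoff
## floor recorded at evaluation time; sub-floor differences carry no signal.
.effective_residuals <- function(candidates) {
  vapply(candidates, function(cand) {
    max(cand$residual, cand$residual_floor %||% 0)
  }, numeric(1))
}

#' Combine a community of structures into the consensus network
#'
#' Binarized candidate structures are stacked and averaged per position; the
#' final structure keeps positions whose fractional support reaches the
#' binarization threshold (ties at the threshold count as edges). Warns when
#' the consensus sparsity falls below `min_sparsity`, as a looser threshold
#' can inflate the edge count.
#'
#' @param community nonempty list of `candidate_solution`s.
#' @param bounds `community_bounds`.
#' @param min_sparsity sparsity level used for the warning check.
#' @return list with `structure` (0/1 consensus vector) and `support`
#'   (fractional support per position).
#' @export
combine_structures <- function(community, bounds = community_bounds(),
                               min_sparsity = 0.5) {
  if (length(community) == 0L) stop("cannot combine an empty community")
  mat <- do.call(rbind, lapply(community, function(cand) as.integer(cand$structure != 0)))
  support <- colMeans(mat)
  final <- as.integer(support >= bounds$binarization_threshold)
  sp <- mean(final == 0L)
  if (sp < min_sparsity) {
    warning("consensus structure sparsity ", format(sp, digits = 3),
            " is below min_sparsity ", min_sparsity,
            "; consider a stricter binarization threshold")
  }
  list(structure = final, support = support)
}
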