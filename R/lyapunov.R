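#' @keywords internal
"_PACKAGE"

## Vectorization convention, fixed package-wide: column-major stacking
## (R's native `as.vector` on a matrix), so entry (i, j) of an n x n matrix
## maps to position (j - 1) * n + i of its vectorized form. The same
## convention is applied to the Jacobian vector j, the fluctuation vector d
## and all bitstring structures.

#' Validate and symmetrize a covariance matrix
#'
#' Checks that `C` is square with `n >= 2`, symmetric within tolerance
#' (`max|C - C'| <= tol * max|C|`) and has a nonnegative diagonal, then
#' returns the symmetrized average `(C + C') / 2`.
#'
#' @param C numeric matrix, candidate covariance.
#' @param tol relative symmetry tolerance.
#' @return symmetrized covariance matrix (dimnames preserved).
#' @export
as_covariance <- function(C, tol = 1e-8) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) {
    stop("covariance matrix must be square, got ", nrow(C), " x ", ncol(C))
  }
  if (nrow(C) < 2L) stop("covariance matrix must be at least 2 x 2")
  if (!is.numeric(C) || anyNA(C)) stop("covariance matrix must be numeric with no missing values")
  asym <- max(abs(C - t(C)))
  if (asym > tol * max(abs(C), .Machine$double.xmin)) {
    stop("covariance matrix is asymmetric beyond tolerance: max|C - C'| = ",
         format(asym))
  }
  if (any(diag(C) < 0)) stop("covariance matrix has a negative diagonal entry")
  (C + t(C)) / 2
}

#' Construct a diagonal fluctuation specification
#'
#' The fluctuation matrix D is diagonal: `diag` holds the per-metabolite
#' noise intensities D_i; off-diagonal entries are assumed zero. Entries
#' must be strictly positive when used for inference.
#'
#' @param diag numeric vector of nonnegative fluctuation magnitudes.
#' @param names optional metabolite names.
#' @param strict require strictly positive entries (default `FALSE`).
#' @return named numeric vector of class `fluctuation_spec`.
#' @export
fluctuation_spec <- function(diag, names = NULL, strict = FALSE) {
  diag <- as.numeric(diag)
  if (anyNA(diag)) stop("fluctuation vector contains missing values")
  if (any(diag < 0)) stop("fluctuation magnitudes must be nonnegative")
  if (strict && any(diag == 0)) stop("fluctuation magnitudes must be strictly positive for inference")
  if (!is.null(names)) names(diag) <- names
  structure(diag, class = "fluctuation_spec")
}

#' Vectorize a diagonal fluctuation matrix
#'
#' Returns the length-n^2 vector d with D_i at the diagonal positions of the
#' column-major vectorization and zeros elsewhere.
#'
#' @param D `fluctuation_spec` or numeric vector of diagonal magnitudes.
#' @return numeric vector of length `n^2`.
#' @export
vec_fluctuation <- function(D) {
  D <- as.numeric(D)
  n <- length(D)
  d <- numeric(n * n)
  d[(seq_len(n) - 1L) * n + seq_len(n)] <- D
  d
}

#' Commutation matrix K(n, n)
#'
#' The permutation matrix with `K %*% vec(M) == vec(t(M))` for any n x n `M`.
#' @param n dimension.
#' @return an `n^2 x n^2` 0/1 matrix.
#' @keywords internal
commutation_matrix <- function(n) {
  n2 <- n * n
  K <- matrix(0, n2, n2)
  idx <- as.vector(t(matrix(seq_len(n2), n, n)))
  K[cbind(seq_len(n2), idx)] <- 1
  K
}

#' Solve the forward Lyapunov equation for the stationary covariance
#'
#' Given a Hurwitz-stable Jacobian `J` and diagonal fluctuation magnitudes
#' `D`, solves `J C + C J' = -2 D` for the stationary covariance C of the
#' linear Langevin system dX = J X dt + sqrt(2 D) dW.
#'
#' @param J stable n x n Jacobian matrix (all eigenvalue real parts < 0).
#' @param D `fluctuation_spec` or numeric vector of diagonal magnitudes.
#' @return symmetric n x n covariance matrix.
#' @export
forward_solve_covariance <- function(J, D) {
  J <- as.matrix(J)
  n <- nrow(J)
  if (ncol(J) != n) stop("Jacobian must be square")
  D <- as.numeric(D)
  if (length(D) != n) {
    stop("dimension mismatch: Jacobian is ", n, " x ", n,
         " but fluctuation vector has length ", length(D))
  }
  if (any(D < 0)) stop("fluctuation magnitudes must be nonnegative")
  ev <- eigen(J, only.values = TRUE)$values
  worst <- ev[which.max(Re(ev))]
  if (Re(worst) >= 0) {
    stop("Jacobian is not Hurwitz-stable: eigenvalue ", format(worst),
         " has nonnegative real part; no stationary covariance exists")
  }
  ## vec(J C + C J') = (I (x) J + J (x) I) vec(C)
  In <- diag(n)
  M <- kronecker(In, J) + kronecker(J, In)
  x <- solve(M, as.vector(-2 * diag(D, n)))
  C <- matrix(x, n, n)
  C <- (C + t(C)) / 2
  dimnames(C) <- dimnames(J)
  C
}

#' Vectorize the Lyapunov equation into a linear system
#'
#' Rewrites `J C + C J' = -2 D` as `A j + 2 d = 0`, with `j = vec(J)`
#' (column-major), `A` an `n^2 x n^2` matrix built from the covariance, and
#' `d = vec(D)`. For every Jacobian `J`, `A %*% vec(J)` equals
#' `vec(J C + C J')`.
#'
#' @param C symmetric covariance matrix (validated by [as_covariance()]).
#' @param D `fluctuation_spec` or numeric vector of diagonal magnitudes.
#' @return list of class `vectorized_system` with elements `A`, `d`, `n`,
#'   and `names` (metabolite labels, possibly `NULL`).
#' @export
vectorize_lyapunov <- function(C, D) {
  C <- as.matrix(C)
  if (length(C) == 1L) {
    ## scalar case: 2 c j + 2 d = 0
    return(base::structure(list(A = matrix(2 * C[1L, 1L], 1, 1),
                                d = as.numeric(D), n = 1L,
                                names = colnames(C)),
                           class = "vectorized_system"))
  }
  C <- as_covariance(C)
  n <- nrow(C)
  D <- as.numeric(D)
  if (length(D) != n) {
    stop("dimension mismatch: covariance is ", n, " x ", n,
         " but fluctuation vector has length ", length(D))
  }
  In <- diag(n)
  A <- kronecker(C, In) + kronecker(In, C) %*% commutation_matrix(n)
  structure(list(A = A, d = vec_fluctuation(D), n = n,
                 names = colnames(C)),
            class = "vectorized_system")
}

#' Reduce the vectorized system to the support of a candidate structure
#'
#' Drops the positions of `j` fixed at zero by the candidate bitstring and
#' the corresponding columns of `A`, giving `A_r j_r + 2 d = 0`.
#'
#' @param sys `vectorized_system` from [vectorize_lyapunov()].
#' @param structure 0/1 vector of length `n^2` marking nonzero Jacobian
#'   entries (column-major).
#' @return list of class `reduced_system` with `A_r`, `support` (retained
#'   positions, increasing), `d`, `n`.
#' @export
reduce_system <- function(sys, structure) {
  stopifnot(inherits(sys, "vectorized_system"))
  structure <- as.integer(structure != 0)
  if (length(structure) != length(sys$d)) {
    stop("structure must have length n^2 = ", length(sys$d))
  }
  support <- which(structure == 1L)
  if (length(support) == 0L) stop("all-zero structure: no Jacobian entries to fit")
  base::structure(list(A_r = sys$A[, support, drop = FALSE],
                       support = support, d = sys$d, n = sys$n),
                  class = "reduced_system")
}

#' Least-squares solution of a reduced Lyapunov system
#'
#' Minimizes the Euclidean norm `||A_r j_r + 2 d||` over the retained
#' Jacobian entries. Solved by singular value decomposition with a relative
#' rank tolerance of 1e-10; rank-deficient systems return the minimum-norm
#' minimizer rather than erroring, because the structure search explores
#' arbitrary supports.
#'
#' @param red `reduced_system` from [reduce_system()].
#' @return list with `j_r` (fitted values on the support) and `residual`
#'   (Euclidean norm of `A_r j_r + 2 d` at the minimizer).
#' @export
solve_reduced <- function(red) {
  stopifnot(inherits(red, "reduced_system"))
  b <- -2 * red$d
  if (all(b == 0)) {
    return(list(j_r = numeric(ncol(red$A_r)), residual = 0))
  }
  sv <- svd(red$A_r)
  tol <- 1e-10 * max(sv$d)
  keep <- sv$d > tol
  z <- crossprod(sv$u, b)[, 1]
  coef <- numeric(length(sv$d))
  coef[keep] <- z[keep] / sv$d[keep]
  j_r <- as.vector(sv$v %*% coef)
  residual <- sqrt(sum((red$A_r %*% j_r - b)^2))
  list(j_r = j_r, residual = residual)
}

## Fast residual/coefficients path used inside the genetic algorithm: QR
## with column pivoting (.lm.fit). Same residual as solve_reduced; aliased
## coefficients of rank-deficient systems are set to zero (a valid, though
## not minimum-norm, minimizer).
.fast_lstsq <- function(A_r, b) {
  fit <- .lm.fit(A_r, b)
  coefs <- numeric(ncol(A_r))
  co <- fit$coefficients
  co[is.na(co)] <- 0
  coefs[fit$pivot] <- co
  list(j_r = coefs, residual = sqrt(sum(fit$residuals^2)))
}

#' Embed reduced Jacobian values into a full matrix
#'
#' @param j_r fitted values on the support.
#' @param support retained column-major positions.
#' @param n network dimension.
#' @param names optional metabolite labels.
#' @return n x n numeric matrix with zeros off the support.
#' @export
embed_jacobian <- function(j_r, support, n, names = NULL) {
  j <- numeric(n * n)
  j[support] <- j_r
  J <- matrix(j, n, n)
  if (!is.null(names)) dimnames(J) <- list(names, names)
  J
}
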