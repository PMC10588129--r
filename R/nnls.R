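#' Non-negative least squares via the Lawson-Hanson active-set algorithm
#'
#' Solves `argmin ||Ax - b||_2` subject to `x >= 0`. Starting from the
#' all-zero solution with an empty passive set, the algorithm repeatedly
#' moves the variable with the largest positive gradient of the residual
#' into the passive set, solves the unconstrained least-squares problem
#' on the passive columns, and steps back along the feasible segment when
#' the unconstrained solution leaves the non-negative orthant. At
#' termination the Karush-Kuhn-Tucker conditions hold: passive
#' coefficients are non-negative with zero gradient, active coefficients
#' are zero with non-positive gradient.
#'
#' @param A numeric matrix (m x n)
#' @param b numeric vector of length m
#' @param tol KKT tolerance on the dual vector `t(A) %*% (b - A x)`
#'   (scaled by the problem's magnitude)
#' @param max_outer cap on outer iterations (default `3 * ncol(A)`)
#' @return list with `x` (solution), `residual` (b - Ax), `deviance`
#'   (squared residual norm), `passive` (indices of the final passive
#'   set), `iterations`
#' @export
nnls_solve <- function(A, b, tol = 1e-10, max_outer = 3 * ncol(A)) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  if (nrow(A) != length(b)) {
    stop(errorCondition(
      sprintf("dimension mismatch: A is %d x %d, b has length %d",
              nrow(A), ncol(A), length(b)),
      class = c("deconvbench_shape_error", "error")))
  }
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  scale <- max(abs(crossprod(A, b)), 1)
  w <- as.numeric(crossprod(A, b))  # gradient at x = 0
  outer_it <- 0L

  solve_passive <- function(p) {
    # least squares on the passive columns; zeros elsewhere
    z <- numeric(n)
    z[p] <- qr.coef(qr(A[, p, drop = FALSE]), b)
    z[p][is.na(z[p])] <- 0  # rank-deficient passive set
    z
  }

  while (any(!passive & w > tol * scale)) {
    outer_it <- outer_it + 1L
    if (outer_it > max_outer) {
      stop(errorCondition(
        sprintf("NNLS failed to converge within %d iterations", max_outer),
        class = c("deconvbench_convergence_error", "error")))
    }
    cand <- which(!passive)
    j <- cand[which.max(w[cand])]
    passive[j] <- TRUE
    z <- solve_passive(passive)
    # inner loop: retreat while the passive solution is infeasible
    while (any(z[passive] <= 0)) {
      viol <- passive & z <= 0
      alpha <- min(x[viol] / (x[viol] - z[viol]))
      x <- x + alpha * (z - x)
      passive[passive & x <= .Machine$double.eps * scale] <- FALSE
      x[!passive] <- 0
      z <- solve_passive(passive)
    }
    x <- z
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  res <- b - as.numeric(A %*% x)
  list(x = x, residual = res, deviance = sum(res^2),
       passive = which(passive), iterations = outer_it)
}
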