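## Thin linear-programming layer over boot::simplex (two-phase tableau).
## Variables are shifted by their lower bounds so the solver's implicit
## x >= 0 applies, and rows are sign-flipped to meet its non-negative
## right-hand-side requirement.

#' Solve a small dense linear program
#'
#' Minimises (or maximises) `obj %*% x` subject to `A_le %*% x <= b_le`,
#' `A_eq %*% x == b_eq` and `lb <= x <= ub`.
#'
#' @param obj objective coefficients.
#' @param lb,ub finite variable bounds (recycled).
#' @param A_le,b_le inequality constraints (optional).
#' @param A_eq,b_eq equality constraints (optional).
#' @param maximize maximise instead of minimise.
#' @param n_iter simplex iteration cap per phase.
#' @return list with `x`, `value`, `solved` (logical).
#' @keywords internal
solve_lp <- function(obj, lb, ub, A_le = NULL, b_le = NULL,
                     A_eq = NULL, b_eq = NULL, maximize = FALSE,
                     n_iter = NULL) {
  n <- length(obj)
  lb <- rep_len(lb, n); ub <- rep_len(ub, n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp requires finite bounds")
  if (any(ub < lb)) return(list(x = NULL, value = NA_real_, solved = FALSE))

  ## drop linearly dependent equality rows (the tableau solver cannot cope
  ## with redundant constraints); they are re-verified on the solution
  A_eq_drop <- NULL; b_eq_drop <- NULL
  if (!is.null(A_eq)) {
    A_eq <- matrix(A_eq, ncol = n); b_eq <- as.numeric(b_eq)
    qa <- qr(t(A_eq))
    if (qa$rank < nrow(A_eq)) {
      keep <- sort(qa$pivot[seq_len(qa$rank)])
      drop <- setdiff(seq_len(nrow(A_eq)), keep)
      A_eq_drop <- A_eq[drop, , drop = FALSE]; b_eq_drop <- b_eq[drop]
      A_eq <- A_eq[keep, , drop = FALSE]; b_eq <- b_eq[keep]
    }
  }

  ## single uniform scale keeps the tableau well conditioned
  sc <- max(abs(c(lb, ub, 1)))
  lb <- lb / sc; ub <- ub / sc
  if (!is.null(b_le)) b_le <- as.numeric(b_le) / sc
  if (!is.null(b_eq)) b_eq <- b_eq / sc

  ## shift: y = x - lb >= 0
  A1 <- diag(n); b1 <- ub - lb
  if (!is.null(A_le)) {
    A_le <- matrix(A_le, ncol = n)
    r <- as.numeric(b_le) - as.numeric(A_le %*% lb)
    A1 <- rbind(A1, A_le); b1 <- c(b1, r)
  }
  ## split <= rows with negative rhs into >= rows with positive rhs
  neg <- b1 < 0
  A2 <- NULL; b2 <- NULL
  if (any(neg)) {
    A2 <- -A1[neg, , drop = FALSE]; b2 <- -b1[neg]
    A1 <- A1[!neg, , drop = FALSE]; b1 <- b1[!neg]
  }
  A3 <- NULL; b3 <- NULL
  if (!is.null(A_eq)) {
    A3 <- matrix(A_eq, ncol = n)
    b3 <- as.numeric(b_eq) - as.numeric(A3 %*% lb)
    flip <- b3 < 0
    A3[flip, ] <- -A3[flip, , drop = FALSE]; b3[flip] <- -b3[flip]
  }
  m <- nrow(A1) + NROW(A2) + NROW(A3)
  if (is.null(n_iter)) n_iter <- 50L * (n + m)
  res <- boot::simplex(a = if (maximize) -obj else obj,
                       A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                       A3 = A3, b3 = b3, maxi = FALSE, n.iter = n_iter)
  if (res$solved != 1)
    return(list(x = NULL, value = NA_real_, solved = FALSE))
  x <- (as.numeric(res$soln) + lb) * sc
  if (!is.null(A_eq_drop) &&
      max(abs(A_eq_drop %*% x - b_eq_drop)) > 1e-6 * sc)
    return(list(x = NULL, value = NA_real_, solved = FALSE))
  list(x = x, value = sum(obj * x), solved = TRUE)
}

#' Orthonormal null-space basis
#' @keywords internal
null_basis <- function(A, tol = 1e-9) {
  A <- as.matrix(A)
  n <- ncol(A)
  if (nrow(A) == 0L) return(diag(n))
  qrA <- qr(t(A), tol = tol)
  r <- qrA$rank
  if (r >= n) return(matrix(0, n, 0))
  qr.Q(qrA, complete = TRUE)[, (r + 1):n, drop = FALSE]
}
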