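# Internal linear / mixed-integer solver layer.
#
# lp_box() solves a bounded-variable LP by shifting every variable to the
# nonnegative orthant and handing a pure `max c'x, Ax <= b, x >= 0` system to
# the compiled two-phase simplex.  milp_box() adds exact branch-and-bound on a
# designated set of integer variables.  Problem sizes here are tiny (tens of
# variables), so dense rebuilds per node are cheaper than warm starts.

#' @useDynLib pathmdf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Solve a small dense LP with box bounds
#'
#' @param obj objective coefficients (length n).
#' @param mat constraint matrix (may have 0 rows).
#' @param dir character vector of "<=", ">=", "==" per row.
#' @param rhs right-hand sides.
#' @param lower,upper finite variable bounds (length n).
#' @param maximize logical.
#' @return list(status, x, objective); status one of "optimal", "infeasible",
#'   "unbounded", "maxit".
#' @noRd
lp_box <- function(obj, mat, dir, rhs, lower, upper, maximize = TRUE) {
  n <- length(obj)
  stopifnot(length(lower) == n, length(upper) == n,
            all(is.finite(lower)), all(is.finite(upper)))
  if (any(upper < lower - 1e-12)) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  if (is.null(mat)) mat <- matrix(0, 0, n)
  mat <- as.matrix(mat)
  m <- nrow(mat)
  # substitute x = lower + y, y >= 0
  rhs2 <- rhs - if (m) drop(mat %*% lower) else numeric(0)
  A <- mat
  b <- rhs2
  if (m) {
    rows <- list(); bs <- numeric(0)
    for (i in seq_len(m)) {
      if (dir[i] == "<=") { rows[[length(rows) + 1L]] <- mat[i, ]; bs <- c(bs, rhs2[i]) }
      else if (dir[i] == ">=") { rows[[length(rows) + 1L]] <- -mat[i, ]; bs <- c(bs, -rhs2[i]) }
      else { # equality as a pair
        rows[[length(rows) + 1L]] <- mat[i, ]; bs <- c(bs, rhs2[i])
        rows[[length(rows) + 1L]] <- -mat[i, ]; bs <- c(bs, -rhs2[i])
      }
    }
    A <- do.call(rbind, rows)
    b <- bs
  } else {
    A <- matrix(0, 0, n); b <- numeric(0)
  }
  # upper bounds as rows (only where the box has finite width above 0)
  span <- upper - lower
  bnd <- which(span < 1e12)
  if (length(bnd)) {
    U <- matrix(0, length(bnd), n)
    U[cbind(seq_along(bnd), bnd)] <- 1
    A <- rbind(A, U)
    b <- c(b, span[bnd])
  }
  cc <- if (maximize) obj else -obj
  res <- simplex_core(A, b, cc)
  st <- switch(as.character(res$status),
               "0" = "optimal", "1" = "infeasible",
               "2" = "unbounded", "3" = "maxit")
  if (st != "optimal") {
    return(list(status = st, x = NULL, objective = NA_real_))
  }
  x <- as.numeric(lower) + res$x
  objective <- sum(obj * x)
  list(status = "optimal", x = x, objective = objective)
}

#' Branch-and-bound MILP over lp_box
#'
#' @param int_idx indices of integer-constrained variables.
#' @param int_tol integrality tolerance.
#' @return as lp_box, plus x rounded on integer coordinates when optimal.
#' @noRd
milp_box <- function(obj, mat, dir, rhs, lower, upper, int_idx,
                     maximize = TRUE, int_tol = 1e-6) {
  best <- list(status = "infeasible", x = NULL, objective = NA_real_)
  best_val <- -Inf
  sgn <- if (maximize) 1 else -1
  # depth-first stack of (lower, upper) boxes
  stack <- list(list(lo = lower, up = upper))
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    rel <- lp_box(obj, mat, dir, rhs, nd$lo, nd$up, maximize = maximize)
    if (rel$status == "unbounded") return(rel)
    if (rel$status != "optimal") next
    if (sgn * rel$objective <= best_val + 1e-9) next  # bound
    frac <- rel$x[int_idx] - round(rel$x[int_idx])
    viol <- which(abs(frac) > int_tol)
    if (!length(viol)) {
      val <- sgn * rel$objective
      if (val > best_val + 1e-9) {
        rel$x[int_idx] <- round(rel$x[int_idx])
        best <- rel
        best_val <- val
      }
      next
    }
    # branch on the most fractional integer variable
    j <- int_idx[viol[which.max(abs(frac[viol]))]]
    xj <- rel$x[j]
    lo1 <- nd$lo; up1 <- nd$up
    up1[j] <- floor(xj)
    lo2 <- nd$lo; up2 <- nd$up
    lo2[j] <- ceiling(xj)
    # push the "down" branch last so it is explored first (deterministic)
    if (lo2[j] <= up2[j]) stack[[length(stack) + 1L]] <- list(lo = lo2, up = up2)
    if (up1[j] >= lo1[j]) stack[[length(stack) + 1L]] <- list(lo = lo1, up = up1)
  }
  best
}
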