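#' @useDynLib fluxcond, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif sd setNames
#' @importFrom utils head tail
NULL

#' Solve a small linear program
#'
#' Minimizes (or maximizes) `obj %*% x` subject to equality constraints
#' `A_eq x = b_eq`, inequality constraints `A_le x <= b_le`, and finite box
#' bounds `lb <= x <= ub`. Inequalities are converted to equalities with
#' bounded slack variables; the core is a dense two-phase simplex.
#'
#' @param obj numeric objective coefficients.
#' @param A_eq,b_eq equality constraint matrix / right-hand side (may be NULL).
#' @param A_le,b_le inequality (<=) constraint matrix / rhs (may be NULL).
#' @param lb,ub finite variable bounds.
#' @param maximize maximize instead of minimize.
#' @return list with `status` ("optimal", "infeasible", "iteration_limit"),
#'   `x` (solution over the original variables) and `obj` (objective value).
#' @keywords internal
lp_solve <- function(obj, A_eq = NULL, b_eq = NULL, A_le = NULL, b_le = NULL,
                     lb, ub, maximize = FALSE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n, all(is.finite(lb)),
            all(is.finite(ub)))
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), obj = NA_real_))
  }
  A <- matrix(0, 0, n)
  b <- numeric(0)
  if (!is.null(A_eq) && nrow(A_eq) > 0) {
    A <- rbind(A, A_eq)
    b <- c(b, b_eq)
  }
  lbs <- lb
  ubs <- ub
  cc <- obj
  if (!is.null(A_le) && nrow(A_le) > 0) {
    k <- nrow(A_le)
    # slack range from the row's attainable minimum over the box
    rowmin <- vapply(seq_len(k), function(i) {
      a <- A_le[i, ]
      sum(pmin(a * lb, a * ub))
    }, numeric(1))
    smax <- b_le - rowmin
    if (any(smax < -1e-9)) {
      return(list(status = "infeasible", x = rep(NA_real_, n), obj = NA_real_))
    }
    smax <- pmax(smax, 0)
    A <- cbind(A, matrix(0, nrow(A), k))
    A <- rbind(A, cbind(A_le, diag(k)))
    b <- c(b, b_le)
    lbs <- c(lbs, rep(0, k))
    ubs <- c(ubs, smax)
    cc <- c(cc, rep(0, k))
  }
  if (maximize) cc <- -cc
  res <- simplex_core(cc, A, b, lbs, ubs, FALSE, 20000L)
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "infeasible", "infeasible")
  x <- res$x[seq_len(n)]
  objval <- sum(obj * x)
  list(status = status, x = x, obj = objval)
}

#' Feasibility check for {A_eq x = b_eq, lb <= x <= ub}
#' @return list(feasible = logical, x = a feasible point if found)
#' @keywords internal
lp_feasible <- function(A_eq, b_eq, lb, ub) {
  n <- length(lb)
  if (any(lb > ub + 1e-12)) return(list(feasible = FALSE, x = NULL))
  res <- simplex_core(rep(0, n), A_eq, b_eq, lb, ub, TRUE, 20000L)
  list(feasible = res$status == 0, x = if (res$status == 0) res$x else NULL)
}

#' Solve a small mixed-integer linear program by branch and bound
#'
#' Depth-first branch and bound over the integer variables, with LP
#' relaxations solved by [lp_solve()]. Suited to the small iMAT-style
#' problems this package builds (tens of binaries).
#'
#' @inheritParams lp_solve
#' @param int_idx indices of integer-constrained variables.
#' @param int_tol integrality tolerance.
#' @return list with `status` ("optimal", "infeasible"), `x`, `obj`.
#' @keywords internal
milp_solve <- function(obj, A_eq = NULL, b_eq = NULL, A_le = NULL, b_le = NULL,
                       lb, ub, int_idx = integer(0), maximize = FALSE,
                       int_tol = 1e-6, max_nodes = 200000L) {
  sgn <- if (maximize) -1 else 1
  cmin <- sgn * obj          # always minimize internally
  best_obj <- Inf
  best_x <- NULL
  stack <- list(list(lb = lb, ub = ub))
  nodes <- 0L
  while (length(stack) > 0) {
    nodes <- nodes + 1L
    if (nodes > max_nodes) stop("milp_solve: node limit exceeded")
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    rel <- lp_solve(cmin, A_eq, b_eq, A_le, b_le, nd$lb, nd$ub,
                    maximize = FALSE)
    if (rel$status != "optimal") next
    if (rel$obj >= best_obj - 1e-9) next   # bound
    frac <- rel$x[int_idx] - round(rel$x[int_idx])
    viol <- which(abs(frac) > int_tol)
    if (length(viol) == 0) {
      xi <- rel$x
      xi[int_idx] <- round(xi[int_idx])
      best_obj <- rel$obj
      best_x <- xi
      next
    }
    j <- int_idx[viol[which.max(abs(frac[viol]))]]
    xf <- rel$x[j]
    lo <- nd$lb; hi <- nd$ub
    hi_down <- hi; hi_down[j] <- floor(xf)
    lo_up <- lo; lo_up[j] <- ceiling(xf)
    # push "up" branch last so it is explored first (tends to satisfy
    # maximization objectives over indicator sums sooner)
    stack[[length(stack) + 1L]] <- list(lb = lo, ub = hi_down)
    stack[[length(stack) + 1L]] <- list(lb = lo_up, ub = hi)
  }
  if (is.null(best_x)) {
    return(list(status = "infeasible", x = NULL, obj = NA_real_))
  }
  list(status = "optimal", x = best_x, obj = sgn * best_obj)
}
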