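#' Augmented-Lagrangian maximizer for concave programs
#'
#' Maximizes a smooth concave objective over the polyhedron
#' \code{\{x : A x <= b, lower <= x <= upper\}}. Inequality constraints are
#' handled by an augmented Lagrangian whose multipliers converge to the
#' Karush-Kuhn-Tucker duals (shadow prices) of the constraint rows; bound
#' constraints are passed to the inner L-BFGS-B solves directly. For a concave
#' objective and linear constraints every stationary point is the global
#' optimum, so the routine is deterministic given the starting point.
#'
#' @param fn objective function of \code{x}, to be maximized.
#' @param gr gradient of \code{fn}.
#' @param A,b linear inequality constraints \code{A x <= b}; \code{A} may be
#'   \code{NULL} for box-constrained problems.
#' @param x0 starting point (any point within the bounds; feasibility with
#'   respect to \code{A x <= b} is not required).
#' @param lower,upper bounds, recycled to \code{length(x0)}.
#' @param control list overriding any of: \code{tol_feas} (maximum absolute
#'   constraint violation accepted, default \code{1e-8}), \code{tol_x}
#'   (stationarity of iterates, default \code{1e-9}), \code{max_outer} (outer
#'   multiplier updates, default 80), \code{rho0}, \code{rho_max},
#'   \code{rho_growth} (penalty schedule), \code{inner_maxit}.
#'
#' @return list with elements \code{par}, \code{value}, \code{duals}
#'   (multipliers of the rows of \code{A}, in the units of objective per unit
#'   of \code{b}), \code{max_violation}, \code{iterations}, \code{converged}.
#' @export
al_maximize <- function(fn, gr, A = NULL, b = NULL, x0,
                        lower = 0, upper = Inf, control = list()) {
  ctrl <- utils::modifyList(
    list(tol_feas = 1e-8, tol_x = 1e-9, max_outer = 80,
         rho0 = 10, rho_max = 1e10, rho_growth = 10, inner_maxit = 1000),
    control)
  n <- length(x0)
  m <- if (is.null(A)) 0L else nrow(A)
  rnorm_ <- NULL
  if (m > 0L) {
    A <- as.matrix(A)
    stopifnot(ncol(A) == n, length(b) == m)
    # normalize rows so the penalty curvature is comparable across
    # constraints; multipliers are mapped back to the original scaling
    rnorm_ <- pmax(sqrt(rowSums(A^2)), 1e-12)
    A <- A / rnorm_
    b <- b / rnorm_
  }
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  x <- pmin(pmax(x0, lower), upper)
  lam <- numeric(m)
  rho <- ctrl$rho0
  viol_prev <- Inf
  viol <- 0
  it <- 0L
  repeat {
    it <- it + 1L
    obj <- function(z) {
      v <- -fn(z)
      if (m > 0L) {
        g <- drop(A %*% z) - b
        s <- pmax(0, g + lam / rho)
        v <- v + 0.5 * rho * sum(s^2) - sum(lam^2) / (2 * rho)
      }
      v
    }
    grad <- function(z) {
      gv <- -gr(z)
      if (m > 0L) {
        g <- drop(A %*% z) - b
        s <- pmax(0, g + lam / rho)
        act <- which(s > 0)
        if (length(act))
          gv <- gv + drop(crossprod(A[act, , drop = FALSE], rho * s[act]))
      }
      gv
    }
    opt <- stats::optim(x, obj, grad, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = ctrl$inner_maxit,
                                       factr = 10, pgtol = 0))
    if (opt$convergence != 0)  # line-search abort: restart with fresh memory
      opt <- stats::optim(opt$par, obj, grad, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = ctrl$inner_maxit,
                                         factr = 10, pgtol = 0))
    x_new <- opt$par
    if (m > 0L) {
      g <- drop(A %*% x_new) - b
      viol <- max(0, g)
      lam <- pmax(0, lam + rho * g)
    } else viol <- 0
    dx <- max(abs(x_new - x))
    x <- x_new
    if ((viol <= ctrl$tol_feas && dx <= ctrl$tol_x) || it >= ctrl$max_outer)
      break
    # raise the penalty only when infeasibility stalls
    if (viol > 0.25 * viol_prev && rho < ctrl$rho_max)
      rho <- rho * ctrl$rho_growth
    viol_prev <- viol
  }
  list(par = x, value = fn(x),
       duals = if (m > 0L) lam / rnorm_ else lam,
       max_violation = viol,
       iterations = it, converged = viol <= max(ctrl$tol_feas, 1e-6))
}
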