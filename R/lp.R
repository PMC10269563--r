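#' Solve a bounded linear program
#'
#' Thin interface over the package's dense bounded-variable two-phase simplex.
#' Solves `max/min c'x` subject to `A x = b` and `lb <= x <= ub`. The pivot
#' rules are deterministic, so repeated calls with identical inputs return
#' identical solutions — a property the dynamic FBA integrator and the
#' parsimonious-FBA tie-break rely on.
#'
#' @param A constraint matrix (dense, rows = equality constraints).
#' @param b right-hand side vector.
#' @param obj objective coefficient vector.
#' @param lb,ub variable bounds; `-Inf`/`Inf` allowed.
#' @param maximize logical; maximize (default) or minimize.
#' @return list with `status` (one of `"optimal"`, `"infeasible"`,
#'   `"unbounded"`, `"iteration_limit"`), `x` (solution or `NULL`) and
#'   `objective`.
#' @keywords internal
lp_solve <- function(A, b, obj, lb, ub, maximize = TRUE) {
  stopifnot(is.matrix(A), nrow(A) == length(b), ncol(A) == length(obj),
            length(lb) == ncol(A), length(ub) == ncol(A))
  if (any(lb > ub + 1e-12))
    stop("inconsistent bounds: lower > upper for variable(s) ",
         paste(which(lb > ub + 1e-12), collapse = ", "))
  r <- .lp_simplex(A, as.numeric(b), as.numeric(obj),
                   as.numeric(lb), as.numeric(ub), maximize)
  r$status <- switch(as.character(r$status),
                     "0" = "optimal", "1" = "infeasible",
                     "2" = "unbounded", "3" = "iteration_limit")
  r
}
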