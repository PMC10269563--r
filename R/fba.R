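#' Solve the FBA problem for a model, with the parsimonious (pFBA) refinement
#'
#' Two-stage linear programming. Stage one maximizes the phase objective, a
#' nonnegative weighted sum of fluxes, under the steady-state constraint
#' `S v = 0` and the flux bounds. Stage two fixes the achieved objective value
#' (to a relative tolerance) and minimizes the total absolute flux, which
#' resolves degenerate alternate optima deterministically — the shortest of
#' two equivalent routes carries the flux.
#'
#' @param model a `metabolic_model`.
#' @param objective named numeric vector of nonnegative weights on reaction
#'   ids (missing reactions get weight 0).
#' @param lb,ub optional named numeric vectors overriding selected reaction
#'   bounds (names = reaction ids).
#' @param pfba run the parsimonious second stage (default `TRUE`).
#' @param obj_tol relative tolerance with which stage two must hold the
#'   stage-one objective value.
#' @return a `flux_solution`: list with `v` (named flux vector,
#'   mmol/(gDW h)), `objective_value`, `status` (`"optimal"`,
#'   `"infeasible"`, `"unbounded"`), and `total_flux` (sum of |v|, `NA`
#'   unless pFBA ran).
#' @export
solve_fba <- function(model, objective, lb = NULL, ub = NULL,
                      pfba = TRUE, obj_tol = 1e-9) {
  rids <- model$reactions$id
  L <- setNames(model$reactions$lower_bound, rids)
  U <- setNames(model$reactions$upper_bound, rids)
  if (!is.null(lb)) L[names(lb)] <- lb
  if (!is.null(ub)) U[names(ub)] <- ub
  if (any(L > U + 1e-12)) {
    bad <- names(L)[L > U + 1e-12]
    stop("inconsistent bounds (lb > ub) for: ", paste(bad, collapse = ", "))
  }
  S <- stoichiometric_matrix(model)
  cvec <- setNames(numeric(length(rids)), rids)
  cvec[names(objective)] <- objective
  if (any(cvec < 0)) stop("objective weights must be nonnegative")

  sol <- fba_lp(S, L, U, cvec, pfba = pfba, obj_tol = obj_tol)
  if (sol$status != "optimal") {
    diag_ids <- rids[abs(L - U) < 1e-12 & abs(L) > 0]
    return(structure(list(v = NULL, objective_value = NA_real_,
                          status = sol$status, total_flux = NA_real_,
                          diagnostics = list(equality_constraints = diag_ids)),
                     class = "flux_solution"))
  }
  structure(list(v = setNames(sol$v, rids),
                 objective_value = sol$objective_value, status = "optimal",
                 total_flux = sol$total_flux), class = "flux_solution")
}

# Matrix-level FBA core shared by solve_fba and the dFBA engine: stage one
# maximizes cvec'v under S v = 0 and bounds; the optional parsimonious stage
# fixes the optimum and minimizes total |v| (directionally split variables).
fba_lp <- function(S, L, U, cvec, pfba = TRUE, obj_tol = 1e-9) {
  r1 <- lp_solve(S, rep(0, nrow(S)), cvec, L, U, maximize = TRUE)
  if (r1$status != "optimal")
    return(list(v = NULL, objective_value = NA_real_, status = r1$status,
                total_flux = NA_real_))
  z <- r1$objective
  v <- r1$x
  total <- NA_real_
  if (pfba) {
    n <- ncol(S)
    split <- L < -1e-12 & U > 1e-12
    neg <- U <= 1e-12     # flux always <= 0, |v| = -v
    ncols <- sum(!split) + 2 * sum(split)
    A2 <- matrix(0, nrow(S) + 1, ncols)
    c2 <- numeric(ncols); l2 <- numeric(ncols); u2 <- numeric(ncols)
    map_p <- integer(n); map_q <- integer(n)
    k <- 0L
    for (j in seq_len(n)) {
      if (split[j]) {
        k <- k + 1L; map_p[j] <- k
        A2[seq_len(nrow(S)), k] <- S[, j]; A2[nrow(S) + 1, k] <- cvec[j]
        c2[k] <- 1; l2[k] <- 0; u2[k] <- U[j]
        k <- k + 1L; map_q[j] <- k
        A2[seq_len(nrow(S)), k] <- -S[, j]; A2[nrow(S) + 1, k] <- -cvec[j]
        c2[k] <- 1; l2[k] <- 0; u2[k] <- -L[j]
      } else {
        k <- k + 1L; map_p[j] <- k
        A2[seq_len(nrow(S)), k] <- S[, j]; A2[nrow(S) + 1, k] <- cvec[j]
        c2[k] <- if (neg[j]) -1 else 1
        l2[k] <- L[j]; u2[k] <- U[j]
      }
    }
    # pin the objective: c'v + s = z with 0 <= s <= tol (v may not exceed z)
    tol_abs <- obj_tol * max(1, abs(z))
    A2 <- cbind(A2, c(rep(0, nrow(S)), 1))
    c2 <- c(c2, 0); l2 <- c(l2, 0); u2 <- c(u2, tol_abs)
    b2 <- c(rep(0, nrow(S)), z)
    r2 <- lp_solve(A2, b2, c2, l2, u2, maximize = FALSE)
    if (r2$status == "optimal") {
      vp <- r2$x
      v <- ifelse(split, vp[map_p] - vp[pmax(map_q, 1L)], vp[map_p])
      total <- sum(abs(v))
    }
  }
  list(v = v, objective_value = z, status = "optimal", total_flux = total)
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("FBA solution:", x$status, "\n")
  if (x$status == "optimal") {
    cat("  objective:", format(x$objective_value), "\n")
    if (!is.na(x$total_flux)) cat("  total |flux| (pFBA):", format(x$total_flux), "\n")
    cat("  nonzero fluxes:", sum(abs(x$v) > 1e-9), "/", length(x$v), "\n")
  }
  invisible(x)
}

#' Maximum steady-state residual of a flux vector
#'
#' `max |S v|` — the steady-state conservation defect. Any optimal flux
#' solution produced by the package must keep this below 1e-8.
#'
#' @param model a `metabolic_model`.
#' @param v named flux vector.
#' @return numeric scalar.
#' @export
steady_state_residual <- function(model, v) {
  S <- stoichiometric_matrix(model)
  max(abs(S %*% v[colnames(S)]))
}
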