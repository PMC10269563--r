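#' Apply a named parameter vector to a preset's parameters and schedule
#'
#' Parameter names address scalar kinetic constants directly (`vmax_G`,
#' `K_Ei`, `gam_f`, `k_d`, ...), vector entries with a dot
#' (`k_P.ethanol`, `k_AA.aa1`), and phase times as `T_L`, `T_E`, `T_S`,
#' `T_D`, `t_end`. Phase-time ordering is validated; a violated ordering
#' returns `NULL` (the objective treats it as an infeasible trial point).
#'
#' @param preset a [scenario_preset()].
#' @param theta named numeric vector.
#' @return list with modified `params` and `schedule`, or `NULL` when the
#'   phase ordering is violated.
#' @export
apply_theta <- function(preset, theta) {
  params <- preset$params
  sched <- unclass(preset$schedule)
  for (nm in names(theta)) {
    val <- unname(theta[[nm]])
    if (nm %in% c("T_L", "T_E", "T_S", "T_D", "t_end")) {
      sched[[nm]] <- val
    } else if (grepl(".", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      params[[parts[1]]][[parts[2]]] <- val
    } else if (nm %in% names(params$protein_curve)) {
      params$protein_curve[[nm]] <- val
    } else {
      params[[nm]] <- val
    }
  }
  if (!(0 < sched$T_L && sched$T_L < sched$T_E && sched$T_E < sched$T_S &&
        sched$T_S < sched$T_D && sched$T_D <= sched$t_end)) return(NULL)
  list(params = params,
       schedule = phase_schedule(sched$T_L, sched$T_E, sched$T_S, sched$T_D,
                                 sched$t_end))
}

#' Least-squares objective of the fermentation model
#'
#' `J(theta) = sum_j sum_i ((y_ji(theta) - y_ji^m) / q_j)^2` over all
#' measured variables j and sampling times i, with `q_j` the mean of
#' variable j's observed readout (mean-normalized weighting, so rescaling a
#' variable's unit — values and weight together — leaves J unchanged).
#' Model predictions are interpolated to the sampling times from the
#' simulated trajectory by monotone cubic interpolation. A failed simulation
#' returns a large finite penalty so global search can continue.
#'
#' @param theta named parameter vector (see [apply_theta()]).
#' @param measurements a [measurement_set()].
#' @param preset the base [scenario_preset()] supplying every parameter not
#'   in `theta`.
#' @param model the metabolic model.
#' @param options integrator options (defaults to the cheap fixed-step
#'   configuration used during fitting).
#' @param penalty value returned on simulation failure.
#' @return nonnegative scalar J.
#' @export
lsq_objective <- function(theta, measurements, preset,
                          model = build_toy_model(),
                          options = fit_sim_options(), penalty = 1e8) {
  ap <- apply_theta(preset, theta)
  if (is.null(ap)) return(penalty)
  traj <- tryCatch(
    simulate_dfba(model, ap$params, ap$schedule, preset$initial_state,
                  options = options),
    error = function(e) NULL)
  if (is.null(traj)) return(penalty)
  measurement_loss(traj, measurements)
}

# sum of squared mean-normalized residuals of a trajectory vs a measurement set
measurement_loss <- function(traj, measurements) {
  J <- 0
  df <- measurements$data
  for (v in unique(df$variable)) {
    if (!v %in% colnames(traj$states)) next
    sub <- df[df$variable == v, ]
    pred <- interp_state(traj, v, sub$time_h)
    J <- J + sum(((pred - sub$value) / measurements$q[[v]])^2)
  }
  J
}

#' Integrator options used during parameter estimation
#'
#' Fixed-step second-order integration with a modest number of steps per
#' phase and no parsimonious refinement inside the right-hand side: the
#' exchange fluxes that drive the extracellular dynamics are pinned by the
#' kinetic equalities or selected by the phase objective, so the cheap
#' configuration tracks the adaptive one closely at a small fraction of the
#' LP count. Used for the thousands of simulations of a global search.
#'
#' @param steps_per_phase fixed steps per phase.
#' @return a [dfba_options()] list.
#' @export
fit_sim_options <- function(steps_per_phase = 10) {
  dfba_options(method = "heun", steps_per_phase = steps_per_phase,
               compute_fluxes = FALSE, pfba_rhs = FALSE,
               normalize_each_step = FALSE)
}

#' Fit the fermentation model to measurements by global least squares
#'
#' Scatter-search-style global optimization of [lsq_objective()]: a
#' Latin-hypercube diversification seeds a reference set, which is evolved
#' by pairwise convex/reflective recombination, and the incumbent is
#' polished with Nelder-Mead local search. Deterministic for a given seed;
#' the returned solution is never worse than the best initial sample; every
#' evaluated point respects the box bounds.
#'
#' @param measurements a [measurement_set()].
#' @param preset base [scenario_preset()] (fixed values for everything not
#'   fitted).
#' @param free named list of `c(lower, upper)` bounds for each fitted
#'   parameter (names as in [apply_theta()]).
#' @param model the metabolic model.
#' @param seed integer seed.
#' @param budget maximum number of objective evaluations.
#' @param options integrator options for the fitting simulations.
#' @param refset_size reference-set size.
#' @return object of class `dfba_fit`.
#' @export
fit_dfba <- function(measurements, preset, free, model = build_toy_model(),
                     seed = 1, budget = 2000, options = fit_sim_options(),
                     refset_size = 8) {
  stopifnot(length(free) >= 1, budget >= 1)
  lower <- vapply(free, `[`, numeric(1), 1)
  upper <- vapply(free, `[`, numeric(1), 2)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower > upper))
    stop("bounds must be finite with lower <= upper")
  d <- length(free); pnames <- names(free)
  set.seed(as.integer(seed) %% .Machine$integer.max)

  evals <- 0L
  best_trace <- numeric(0)
  J_of <- function(x) {
    theta <- setNames(pmin(pmax(x, lower), upper), pnames)
    evals <<- evals + 1L
    lsq_objective(theta, measurements, preset, model = model,
                  options = options)
  }

  n_init <- max(min(10 * d, floor(budget / 3)), 1)
  X <- if (n_init > 1)
    t(lower + t(as.matrix(lhs::randomLHS(n_init, d))) * (upper - lower))
  else matrix((lower + upper) / 2, 1, d)
  colnames(X) <- pnames
  J <- apply(X, 1, J_of)
  best_initial <- min(J)
  best_trace <- c(best_trace, cummin(J))

  ord <- order(J)
  nref <- min(refset_size, nrow(X))
  R <- X[ord[seq_len(nref)], , drop = FALSE]
  RJ <- J[ord[seq_len(nref)]]

  polish_every <- 6L; round <- 0L
  while (evals < budget) {
    round <- round + 1L
    improved <- FALSE
    pairs <- utils::combn(min(nref, 4), 2)
    for (k in seq_len(ncol(pairs))) {
      if (evals >= budget) break
      i <- pairs[1, k]; j <- pairs[2, k]
      lam <- runif(1, -0.4, 1.4)      # convex combination with reflection
      x <- R[i, ] + lam * (R[j, ] - R[i, ])
      x <- pmin(pmax(x, lower), upper)
      jx <- J_of(x)
      w <- which.max(RJ)
      if (jx < RJ[w]) { R[w, ] <- x; RJ[w] <- jx; improved <- TRUE }
      best_trace <- c(best_trace, min(min(RJ), tail(best_trace, 1)))
    }
    if (round %% polish_every == 0L || (!improved && evals < budget)) {
      # coordinate sweep: probe each dimension of the incumbent on a coarse
      # grid across its box — escapes one-dimensional local basins that
      # recombination alone tends to miss
      b <- which.min(RJ)
      for (dim_k in seq_len(d)) {
        if (evals >= budget) break
        grid <- lower[dim_k] + (upper[dim_k] - lower[dim_k]) *
          seq(0.05, 0.95, length.out = 7)
        for (g in grid) {
          if (evals >= budget) break
          x <- R[b, ]; x[dim_k] <- g
          jx <- J_of(x)
          if (jx < RJ[b]) { R[b, ] <- x; RJ[b] <- jx; improved <- TRUE }
        }
      }
      rem <- budget - evals
      if (rem > 2 * d) {
        op <- local_polish(R[b, ], J_of, lower, upper,
                           maxit = min(rem - d, 30 * d))
        if (op$value < RJ[b]) { R[b, ] <- pmin(pmax(op$par, lower), upper)
                                RJ[b] <- op$value }
        best_trace <- c(best_trace, min(RJ))
      }
      if (!improved && round > polish_every) {
        # diversify the worst half around the incumbent
        b <- which.min(RJ)
        for (w in order(RJ, decreasing = TRUE)[seq_len(max(1, nref %/% 2))]) {
          if (evals >= budget) break
          x <- pmin(pmax(R[b, ] + runif(d, -0.15, 0.15) * (upper - lower),
                         lower), upper)
          jx <- J_of(x)
          if (jx < RJ[w]) { R[w, ] <- x; RJ[w] <- jx }
        }
      }
    }
  }

  # final polish of the incumbent with whatever budget remains (or a little
  # extra: Nelder-Mead converges in tens of iterations for a handful of
  # parameters and the polish is what pins weakly-curved parameters down)
  b <- which.min(RJ)
  op <- local_polish(R[b, ], J_of, lower, upper,
                     maxit = max(60 * d, budget - evals))
  if (op$value < RJ[b]) {
    R[b, ] <- pmin(pmax(op$par, lower), upper); RJ[b] <- op$value
  }
  b <- which.min(RJ)
  theta_hat <- setNames(R[b, ], pnames)
  Jbest <- RJ[b]
  stopifnot(Jbest <= best_initial + 1e-12)

  ap <- apply_theta(preset, theta_hat)
  traj <- simulate_dfba(model, ap$params, ap$schedule, preset$initial_state,
                        options = options)
  r2 <- r_squared_trajectory(traj, measurements)

  structure(list(theta_hat = theta_hat, J = Jbest, r2 = r2,
                 bounds = cbind(lower = lower, upper = upper),
                 seed = seed, budget = budget, evaluations = evals,
                 best_initial = best_initial, trace = best_trace,
                 measurements = measurements, preset = preset, model = model,
                 options = options, trajectory = traj),
            class = "dfba_fit")
}

# Nelder-Mead for d > 1; golden-section/Brent for a single parameter
local_polish <- function(x0, fn, lower, upper, maxit) {
  if (length(x0) > 1)
    optim(x0, fn, method = "Nelder-Mead",
          control = list(maxit = maxit, reltol = 1e-10))
  else
    optim(x0, fn, method = "Brent", lower = lower, upper = upper,
          control = list(maxit = maxit))
}

#' Per-variable coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` for each variable, matching predictions to
#' observations on (variable, time). Variables with zero observational
#' variance have an undefined R^2 and are reported as `NA`.
#'
#' @param predictions data.frame with columns `variable`, `time_h`, `value`.
#' @param observations data.frame with the same columns (>= 2 observations
#'   per variable).
#' @return named numeric vector of R^2 values.
#' @export
r_squared <- function(predictions, observations) {
  out <- c()
  for (v in unique(observations$variable)) {
    obs <- observations[observations$variable == v, ]
    if (nrow(obs) < 2) stop("need >= 2 observations for variable ", v)
    prd <- predictions[predictions$variable == v, ]
    m <- merge(obs, prd, by = c("variable", "time_h"),
               suffixes = c("_obs", "_pred"))
    sstot <- sum((m$value_obs - mean(m$value_obs))^2)
    out[v] <- if (sstot <= 0) NA_real_
              else 1 - sum((m$value_pred - m$value_obs)^2) / sstot
  }
  out
}

r_squared_trajectory <- function(traj, measurements) {
  df <- measurements$data
  keep <- df$variable %in% colnames(traj$states)
  df <- df[keep, ]
  pred <- df
  for (v in unique(df$variable))
    pred$value[pred$variable == v] <-
      interp_state(traj, v, df$time_h[df$variable == v])
  r_squared(pred, df)
}

#' @export
print.dfba_fit <- function(x, ...) {
  cat("Fitted dynamic FBA model (", length(x$theta_hat), " parameters, J = ",
      format(x$J, digits = 6), ")\n", sep = "")
  print(round(x$theta_hat, 6))
  cat("evaluations:", x$evaluations, " seed:", x$seed, "\n")
  invisible(x)
}

#' @export
summary.dfba_fit <- function(object, ...) {
  cat("Dynamic FBA fit on preset '", object$preset$name, "'\n", sep = "")
  cat("J =", format(object$J, digits = 6), "after", object$evaluations,
      "evaluations (seed ", object$seed, ")\n")
  est <- data.frame(estimate = object$theta_hat,
                    lower = object$bounds[, "lower"],
                    upper = object$bounds[, "upper"])
  print(est)
  cat("\nPer-variable R^2 (median ", round(median(object$r2, na.rm = TRUE), 3),
      "):\n", sep = "")
  print(round(sort(object$r2, decreasing = TRUE), 3))
  invisible(object)
}

#' @export
coef.dfba_fit <- function(object, ...) object$theta_hat

#' @export
predict.dfba_fit <- function(object, times = NULL, options = NULL, ...) {
  if (is.null(times) && is.null(options)) return(object$trajectory)
  ap <- apply_theta(object$preset, object$theta_hat)
  traj <- simulate_dfba(object$model, ap$params, ap$schedule,
                        object$preset$initial_state,
                        options = options %||% object$options)
  if (is.null(times)) return(traj)
  vars <- colnames(traj$states)
  out <- lapply(vars, function(v)
    data.frame(variable = v, time_h = times,
               value = interp_state(traj, v, times)))
  do.call(rbind, out)
}

#' @export
residuals.dfba_fit <- function(object, ...) {
  df <- object$measurements$data
  df <- df[df$variable %in% colnames(object$trajectory$states), ]
  pred <- numeric(nrow(df))
  for (v in unique(df$variable)) {
    i <- df$variable == v
    pred[i] <- interp_state(object$trajectory, v, df$time_h[i])
  }
  setNames(pred - df$value, paste(df$variable, df$time_h, sep = "@"))
}

#' @export
plot.dfba_fit <- function(x, vars = NULL, ...) {
  df <- x$measurements$data
  if (is.null(vars))
    vars <- intersect(c("glucose", "ethanol", "NH4", "biomass"),
                      unique(df$variable))
  old <- par(mfrow = c(ceiling(length(vars) / 2), 2), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  traj <- x$trajectory
  for (v in vars) {
    sub <- df[df$variable == v, ]
    plot(sub$time_h, sub$value, xlab = "time (h)", ylab = v,
         main = v, ...)
    lines(traj$times, traj$states[, v], col = 2)
  }
  invisible(x)
}

#' Simulate new noisy datasets from a fitted model
#'
#' @param object a `dfba_fit`.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param noise_cv measurement noise CV.
#' @param ... unused.
#' @return list of `measurement_set` objects (length `nsim`).
#' @export
simulate.dfba_fit <- function(object, nsim = 1, seed = 1, noise_cv = 0.05,
                              ...) {
  traj <- object$trajectory
  df0 <- object$measurements$data
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sigma <- sqrt(log(1 + noise_cv^2))
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    df <- df0
    for (v in unique(df$variable)) {
      i <- df$variable == v
      if (!v %in% colnames(traj$states)) next
      mu <- interp_state(traj, v, df$time_h[i])
      df$value[i] <- mu * exp(rnorm(sum(i), -sigma^2 / 2, sigma))
    }
    out[[s]] <- measurement_set(df)
  }
  out
}
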