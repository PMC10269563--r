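#' Accumulated flux ratio of a reaction over a fermentation phase
#'
#' Integrates the reaction's flux weighted by biomass over the phase window
#' (trapezoidal quadrature on the trajectory's accepted samples) and
#' normalizes by the accumulated hexose consumption over the same window,
#' times 100 — millimoles of compound per 100 millimoles of hexose:
#' `S = 100 * Int(v_i DW dt) / Int((v_Glx + v_F) DW dt)`.
#'
#' Windows: growth `[T_L, T_S]` (lag excluded), stationary `[T_S, T_D]`,
#' decay `[T_D, t_end]`. `whole_run = TRUE` makes the decay window the
#' literal whole fermentation `[0, t_end]`.
#'
#' Orientation of the denominator: with `orientation = "production"` (the
#' default used for reporting) the denominator is the *magnitude* of hexose
#' consumption, so produced compounds get positive ratios and uptaken
#' compounds negative ones. With `orientation = "consumption"` the signed
#' hexose integral is used as printed in the defining formula, so the hexose
#' exchanges themselves sum to exactly +100 (self-normalization).
#'
#' @param traj a `dfba_trajectory` with a flux matrix.
#' @param reaction reaction id.
#' @param phase `"growth"`, `"stationary"` or `"decay"`.
#' @param whole_run literal whole-fermentation window for `"decay"`.
#' @param orientation `"production"` or `"consumption"` (see above).
#' @return S value (mmol per 100 mmol hexose), or `NA` when the hexose
#'   integral over the window is zero.
#' @export
phase_flux_ratio <- function(traj, reaction, phase = c("growth", "stationary",
                                                       "decay"),
                             whole_run = FALSE,
                             orientation = c("production", "consumption")) {
  phase <- match.arg(phase)
  orientation <- match.arg(orientation)
  if (is.null(traj$fluxes)) stop("trajectory has no flux matrix")
  w <- ratio_window(traj$schedule, phase, whole_run)
  num <- integrate_flux(traj, reaction, w)
  den <- integrate_flux(traj, traj$exchange_map[["glucose"]], w) +
    integrate_flux(traj, traj$exchange_map[["fructose"]], w)
  if (abs(den) < 1e-12) return(NA_real_)
  if (orientation == "production") 100 * num / abs(den) else 100 * num / den
}

ratio_window <- function(schedule, phase, whole_run = FALSE) {
  switch(phase,
         growth = c(schedule$T_L, schedule$T_S),
         stationary = c(schedule$T_S, schedule$T_D),
         decay = if (whole_run) c(0, schedule$t_end)
                 else c(schedule$T_D, schedule$t_end))
}

# trapezoidal integral of v_i(t) * DW(t) over [a, b]; window endpoints are
# linearly interpolated when they fall between samples
integrate_flux <- function(traj, reaction, window) {
  a <- window[1]; b <- window[2]
  tt <- traj$times
  g <- traj$fluxes[, reaction] * traj$states[, "biomass"]
  dup <- duplicated(tt)
  tt <- tt[!dup]; g <- g[!dup]
  inside <- tt > a & tt < b
  ts <- c(a, tt[inside], b)
  gs <- c(approx(tt, g, xout = a, rule = 2)$y, g[inside],
          approx(tt, g, xout = b, rule = 2)$y)
  pracma::trapz(ts, gs)
}

#' Flux-ratio table of a trajectory
#'
#' One row per reaction, columns `S_growth`, `S_stationary`, `S_decay`
#' (production orientation).
#'
#' @param traj a `dfba_trajectory` with fluxes.
#' @param reactions reaction ids (default: all).
#' @param whole_run literal whole-run decay window.
#' @return data.frame of class `flux_ratio_table`.
#' @export
flux_ratio_table <- function(traj, reactions = NULL, whole_run = FALSE) {
  if (is.null(reactions)) reactions <- colnames(traj$fluxes)
  out <- data.frame(reaction = reactions, stringsAsFactors = FALSE)
  for (ph in c("growth", "stationary", "decay"))
    out[[paste0("S_", ph)]] <- vapply(reactions, function(r)
      phase_flux_ratio(traj, r, ph, whole_run = whole_run), numeric(1))
  nm <- traj$model$reactions$name[match(reactions, traj$model$reactions$id)]
  out$name <- nm
  class(out) <- c("flux_ratio_table", "data.frame")
  out
}

#' Base-2 logarithm of a flux-ratio fold change
#'
#' @param S_a,S_b flux ratios of the same reaction under two conditions;
#'   both must be strictly positive (ratios are compared within the same
#'   sign; use magnitudes for uptakes).
#' @return `log2(S_a / S_b)`.
#' @export
log2_fold <- function(S_a, S_b) {
  if (any(c(S_a, S_b) <= 0))
    stop("sign change: log2 fold defined only for positive ratios of ",
         "consistent sign")
  log2(S_a / S_b)
}

#' Select differentially used reactions between two conditions
#'
#' A reaction is selected when at least one of its two flux ratios exceeds
#' the magnitude threshold and the absolute base-2 log fold of their
#' magnitudes exceeds the fold threshold. Pairs whose ratios have opposite
#' signs (a direction reversal rather than a fold change) are flagged
#' `sign_change` and excluded from the fold ranking.
#'
#' @param tableA,tableB `flux_ratio_table`s sharing the reaction index.
#' @param phase which phase column to compare (default `"stationary"`).
#' @param mag_threshold minimum magnitude of max(|S_A|, |S_B|).
#' @param fold_threshold minimum |log2 fold|.
#' @return data.frame (reaction, S_A, S_B, log2_fold) sorted by decreasing
#'   |log2 fold|; attribute `sign_changes` lists the excluded reactions.
#' @export
select_differential <- function(tableA, tableB, phase = "stationary",
                                mag_threshold = 0.1, fold_threshold = 1) {
  col <- paste0("S_", phase)
  stopifnot(identical(tableA$reaction, tableB$reaction))
  Sa <- tableA[[col]]; Sb <- tableB[[col]]
  ok <- !is.na(Sa) & !is.na(Sb)
  mag <- pmax(abs(Sa), abs(Sb)) > mag_threshold
  signchg <- ok & mag & (sign(Sa) * sign(Sb) < 0)
  eligible <- ok & mag & !signchg & abs(Sa) > 0 & abs(Sb) > 0
  lf <- rep(NA_real_, length(Sa))
  lf[eligible] <- log2(abs(Sa[eligible]) / abs(Sb[eligible]))
  sel <- eligible & abs(lf) > fold_threshold
  out <- data.frame(reaction = tableA$reaction[sel], S_A = Sa[sel],
                    S_B = Sb[sel], log2_fold = lf[sel],
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$log2_fold)), ]
  rownames(out) <- NULL
  attr(out, "sign_changes") <- tableA$reaction[signchg]
  out
}
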