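#' Read a run configuration from YAML
#'
#' A run configuration bundles everything a simulation or fit needs beside
#' the model: the kinetic constants (`kinetics:` block, merged over the
#' [kinetic_parameters()] defaults; nested vectors like `k_P` merge by
#' name), the phase boundaries (`schedule:` block with `T_L`, `T_E`, `T_S`,
#' `T_D`, `t_end`), the initial extracellular state (`initial_state:` block,
#' mM and gDW/L), and optionally `seed` and `tolerances` (`rtol`, `atol`,
#' both > 0).
#'
#' @param path YAML file.
#' @return list with `params` (a `kinetic_parameters`), `schedule` (a
#'   `phase_schedule`), `initial_state` (named numeric vector or `NULL`),
#'   `seed`, and `options` (a [dfba_options()] list).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- kinetic_parameters()
  if (!is.null(cfg$kinetics)) {
    for (nm in names(cfg$kinetics)) {
      v <- cfg$kinetics[[nm]]
      if (is.list(v) || !is.null(names(v))) {
        v <- unlist(v)
        base[[nm]][names(v)] <- v
      } else base[[nm]] <- v
    }
  }
  params <- do.call(kinetic_parameters, base[setdiff(names(base), character(0))])
  sc <- cfg$schedule
  schedule <- if (is.null(sc)) NULL
  else phase_schedule(sc$T_L, sc$T_E, sc$T_S, sc$T_D, sc$t_end)
  init <- if (is.null(cfg$initial_state)) NULL else unlist(cfg$initial_state)
  opts <- dfba_options()
  if (!is.null(cfg$tolerances)) {
    if (any(unlist(cfg$tolerances) <= 0)) stop("tolerances must be > 0")
    opts$rtol <- cfg$tolerances$rtol %||% opts$rtol
    opts$atol <- cfg$tolerances$atol %||% opts$atol
  }
  list(params = params, schedule = schedule, initial_state = init,
       seed = cfg$seed %||% 1L, options = opts)
}
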