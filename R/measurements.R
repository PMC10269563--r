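#' Construct a measurement set from long-format observations
#'
#' Observed extracellular time series in long format. Each variable gets a
#' normalization weight `q` equal to the mean of its observed readout — the
#' weighting used by the least-squares objective so that variables measured
#' on different scales contribute comparably. Duplicated (variable, time)
#' rows are kept as replicate observations.
#'
#' @param data data.frame with columns `variable`, `time_h`, `value` and
#'   optionally `unit` (`"mM"`, `"g/L"`, `"gDW/L"`; g/L values are converted
#'   to mM via `molar_mass`).
#' @param molar_mass named vector, g/mmol, required for g/L rows.
#' @return object of class `measurement_set`: the (converted) long data and
#'   the per-variable weights `q`.
#' @export
measurement_set <- function(data, molar_mass = toy_molar_mass()) {
  need <- c("variable", "time_h", "value")
  if (!all(need %in% names(data))) stop("data must have columns: ",
                                        paste(need, collapse = ", "))
  if (nrow(data) == 0L) stop("no records")
  if (is.null(data$unit)) data$unit <- "mM"
  if (any(bad <- data$value < 0))
    stop("negative value at row(s): ", paste(which(bad), collapse = ", "))
  known <- c("mM", "g/L", "gDW/L", "OD")
  if (any(!data$unit %in% known))
    stop("unknown unit(s): ", paste(setdiff(unique(data$unit), known),
                                    collapse = ", "))
  gl <- data$unit == "g/L"
  if (any(gl)) {
    mm <- molar_mass[data$variable[gl]]
    if (anyNA(mm))
      stop("no molar mass for: ",
           paste(unique(data$variable[gl][is.na(mm)]), collapse = ", "))
    data$value[gl] <- data$value[gl] / mm
    data$unit[gl] <- "mM"
  }
  q <- tapply(data$value, data$variable, mean)
  if (any(q <= 0))
    warning("zero-mean variable(s) get unit weight: ",
            paste(names(q)[q <= 0], collapse = ", "))
  q[q <= 0] <- 1
  structure(list(data = data[order(data$variable, data$time_h), ],
                 q = q), class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat("Measurement set:", length(x$q), "variables,", nrow(x$data),
      "observations over", format(max(x$data$time_h)), "h\n")
  invisible(x)
}

#' Read measurements from a long-format CSV
#'
#' Expected header: `variable,time_h,value,unit`.
#'
#' @param path CSV file path.
#' @param molar_mass conversion table for g/L values.
#' @return a [measurement_set()].
#' @export
read_measurements <- function(path, molar_mass = toy_molar_mass()) {
  if (!file.exists(path)) stop("measurements file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  measurement_set(df, molar_mass = molar_mass)
}
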