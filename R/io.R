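#' Read and write voltage traces as CSV
#'
#' Traces are stored with header columns `time_ms`, `V_mV`, `I_uAcm2`;
#' additional columns (gating variables, open fractions) are preserved.
#'
#' @param trace a `voltage_trace` data frame.
#' @param path file path.
#' @return `write_voltage_trace` invisibly returns `path`;
#'   `read_voltage_trace` returns a `voltage_trace` data frame.
#' @export
write_voltage_trace <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_voltage_trace
#' @export
read_voltage_trace <- function(path) {
  df <- read.csv(path)
  need <- c("time_ms", "V_mV")
  if (!all(need %in% names(df)))
    stop("trace file must contain columns time_ms and V_mV")
  if (nrow(df) >= 3) {
    dts <- diff(df$time_ms)
    if (max(abs(dts - dts[1])) > 1e-8)
      stop("trace time grid is not uniform")
    attr(df, "dt") <- dts[1]
  }
  class(df) <- c("voltage_trace", "data.frame")
  df
}

#' Write ensemble statistics as CSV
#'
#' Columns: `time_ms`, `mean_open_Na`, `var_open_Na`, `mean_open_K`,
#' `var_open_K`.
#'
#' @param stats an `ensemble_stats` data frame from [replay_ensemble()].
#' @param path file path.
#' @export
write_ensemble_stats <- function(stats, path) {
  write.csv(as.data.frame(stats), path, row.names = FALSE)
  invisible(path)
}
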