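# Observed time-course container: a thin data.frame (time_s, signal_nM)
# with metadata attributes, matching the tabular layout used for
# gel-quantified product-formation data.

#' Construct an observed time course
#'
#' @param time_s Numeric vector of times in seconds, strictly increasing,
#'   first time >= 0.
#' @param signal_nM Numeric vector of observed signal (product) in nM.
#' @param experiment_id Experiment identifier (e.g. `"dCTP"`).
#' @param replicate Replicate identifier (integer).
#' @param temperature_K Optional temperature in kelvin.
#' @param protocol Optional protocol name.
#' @param truth Optional named list of generating parameters (kept for
#'   parameter-recovery testing of synthetic data).
#' @return A data.frame of class `polbkin_tc` with columns `time_s` and
#'   `signal_nM` and metadata stored as attributes.
#' @export
observed_timecourse <- function(time_s, signal_nM, experiment_id = NA_character_,
                                replicate = 1L, temperature_K = NA_real_,
                                protocol = NA_character_, truth = NULL) {
  time_s <- as.numeric(time_s)
  signal_nM <- as.numeric(signal_nM)
  if (length(time_s) != length(signal_nM)) {
    stop("time_s and signal_nM must have equal length")
  }
  if (any(!is.finite(time_s)) || time_s[1] < 0 ||
      any(diff(time_s) <= 0)) {
    stop("times must be finite, non-negative and strictly increasing")
  }
  out <- data.frame(time_s = time_s, signal_nM = signal_nM)
  attr(out, "experiment_id") <- experiment_id
  attr(out, "replicate") <- replicate
  attr(out, "temperature_K") <- temperature_K
  attr(out, "protocol") <- protocol
  attr(out, "truth") <- truth
  class(out) <- c("polbkin_tc", "data.frame")
  out
}

#' @export
print.polbkin_tc <- function(x, ...) {
  cat("<observed time course>",
      if (!is.na(attr(x, "experiment_id"))) attr(x, "experiment_id") else "",
      sprintf("(%d points, replicate %s)\n", nrow(x),
              as.character(attr(x, "replicate"))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
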