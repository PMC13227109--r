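# Mechanistic diagnostics derived from fitted parameters: sulfur
# elemental effects against the revised 10-160 benchmark, slope-derived
# rate constants for near-linear time courses, pulse-quench/pulse-chase
# amplitude partitioning, and the rate-limiting-step decision table.

#' Sulfur elemental effect from oxygen- and thio-substrate rates
#'
#' The elemental effect is the ratio of the observed rate constants for
#' the natural (oxygen) nucleotide and its alpha-thio analog. When
#' per-replicate rate vectors are supplied the ratio is computed per
#' replicate and averaged; with scalar inputs the ratio of means is
#' taken. The ratio is classified against the revised benchmark for a
#' rate-limiting chemical step (10-160, endpoints inclusive): below the
#' benchmark the chemical step is not rate-limiting; within it, the
#' chemical step is rate-limiting; above it the result is flagged
#' indeterminate.
#'
#' @param k_oxygen Rate constant(s) for the natural dNTP (s^-1).
#' @param k_thio Rate constant(s) for the Sp-dNTPalphaS analog (s^-1);
#'   same length as `k_oxygen` when per-replicate.
#' @param benchmark_range Length-2 numeric, the chemistry-limited band
#'   (default `c(10, 160)`).
#' @return A list of class `elemental_effect`: `k_oxygen`, `k_thio`,
#'   `ratio`, `replicate_ratios`, `sd_ratio`, `classification`,
#'   `benchmark_range`.
#' @export
#' @examples
#' elemental_effect(0.77, 0.21) # 3.7: not chemistry limited
#' elemental_effect(5.2e-4, 2.2e-5) # 24: chemistry limited
elemental_effect <- function(k_oxygen, k_thio, benchmark_range = c(10, 160)) {
  if (any(k_oxygen <= 0) || any(k_thio <= 0)) {
    stop("rate constants must be positive")
  }
  replicate_ratios <- NULL
  sd_ratio <- NA_real_
  if (length(k_oxygen) > 1 || length(k_thio) > 1) {
    if (length(k_oxygen) != length(k_thio)) {
      stop("paired replicate lists must have equal length")
    }
    replicate_ratios <- k_oxygen / k_thio
    ratio <- mean(replicate_ratios)
    sd_ratio <- stats::sd(replicate_ratios)
  } else {
    ratio <- k_oxygen / k_thio
  }
  classification <- if (ratio < benchmark_range[1]) {
    "not_chemistry_limited"
  } else if (ratio <= benchmark_range[2]) {
    "chemistry_limited"
  } else {
    "indeterminate"
  }
  structure(list(k_oxygen = k_oxygen, k_thio = k_thio,
                 ratio = unname(ratio), replicate_ratios = replicate_ratios,
                 sd_ratio = sd_ratio, classification = classification,
                 benchmark_range = benchmark_range),
            class = "elemental_effect")
}

#' @export
print.elemental_effect <- function(x, ...) {
  cat(sprintf("<elemental_effect> ratio = %.3g -> %s (benchmark %g-%g)\n",
              x$ratio, x$classification,
              x$benchmark_range[1], x$benchmark_range[2]))
  invisible(x)
}

#' Observed rate constant from an initial slope and amplitude
#'
#' For a reaction too slow to reach its plateau, the early-time
#' linearization of the single-exponential model gives
#' `k_obs = slope / A`, where the amplitude is taken to reflect the
#' active enzyme concentration.
#'
#' @param slope Initial rate, nM/s (>= 0).
#' @param amplitude Reaction amplitude, nM (> 0).
#' @return Rate constant in s^-1.
#' @export
#' @examples
#' kobs_from_slope(5.2e-4, 23.8) # 2.2e-5 s^-1
kobs_from_slope <- function(slope, amplitude) {
  if (amplitude <= 0) stop("amplitude must be positive")
  if (slope < 0) stop("slope must be non-negative")
  slope / amplitude
}

#' Pulse-quench / pulse-chase amplitude partitioning
#'
#' From quench and chase amplitudes `A_q <= A_c`, the intermediate pool
#' revealed by the chase is `A_c - A_q`; the forward commitment fraction
#' is `f = A_q / A_c`; the internal equilibrium constant of the chemical
#' step is `K_int = A_q / (A_c - A_q)`; and, treating the chase-phase
#' rate constant as the total decay of the intermediate, the substrate
#' release rate is `k_release = k_obs_chase * (1 - f) / f`.
#'
#' @param A_quench Pulse-quench amplitude (nM, > 0).
#' @param A_chase Pulse-chase amplitude (nM, >= A_quench).
#' @param k_obs_chase Pulse-chase observed rate constant (s^-1, > 0).
#' @return A list of class `partition_analysis`: `A_quench`, `A_chase`,
#'   `amplitude_ratio`, `amplitude_difference`, `forward_fraction`,
#'   `K_int`, `release_rate`.
#' @export
#' @examples
#' partition_analysis(16.3, 24.5, 0.55)
partition_analysis <- function(A_quench, A_chase, k_obs_chase) {
  if (A_quench <= 0) stop("A_quench must be positive")
  if (k_obs_chase <= 0) stop("k_obs_chase must be positive")
  if (A_chase < A_quench) {
    stop("A_chase < A_quench violates the chase >= quench invariant")
  }
  diff <- A_chase - A_quench
  f <- A_quench / A_chase
  structure(list(A_quench = A_quench, A_chase = A_chase,
                 amplitude_ratio = A_chase / A_quench,
                 amplitude_difference = diff,
                 forward_fraction = f,
                 K_int = if (diff > 0) A_quench / diff else Inf,
                 release_rate = k_obs_chase * (1 - f) / f),
            class = "partition_analysis")
}

#' @export
print.partition_analysis <- function(x, ...) {
  cat(sprintf(
    "<partition_analysis> A_chase/A_quench = %.3g, diff = %.3g nM, f = %.3g, K_int = %.3g, release = %.3g s^-1\n",
    x$amplitude_ratio, x$amplitude_difference, x$forward_fraction,
    x$K_int, x$release_rate))
  invisible(x)
}

#' Classify the rate-limiting step from the available evidence
#'
#' Decision table over up to three evidence channels: the sulfur
#' elemental effect (an [elemental_effect()] object), the relative
#' change of `k_obs` per unit relative viscosity, and the
#' pulse-chase/pulse-quench amplitude ratio.
#' \itemize{
#'   \item elemental ratio below benchmark AND amplitude ratio > 1 AND
#'     |viscosity slope| below `viscosity_threshold`: a pre-chemical
#'     local active-site rearrangement is rate-limiting;
#'   \item elemental ratio within the benchmark: the chemical step is
#'     rate-limiting;
#'   \item viscosity slope near -1 (inverse proportionality to
#'     viscosity): a large-scale diffusive motion is rate-limiting;
#'   \item anything else: indeterminate.
#' }
#'
#' @param elemental Optional `elemental_effect`.
#' @param viscosity_slope Optional relative change in `k_obs` per unit
#'   relative viscosity (0 = flat, -1 = inverse proportionality).
#' @param amplitude_ratio Optional pulse-chase/pulse-quench amplitude
#'   ratio.
#' @param viscosity_threshold Flatness threshold (default 0.1 per unit).
#' @return A list of class `rate_limiting_verdict`: `verdict` (one of
#'   `"pre_chemical_local_step"`, `"chemistry"`, `"large_scale_motion"`,
#'   `"indeterminate"`) and `channels`, the evidence that fired.
#' @export
classify_rate_limiting <- function(elemental = NULL, viscosity_slope = NULL,
                                   amplitude_ratio = NULL,
                                   viscosity_threshold = 0.1) {
  if (is.null(elemental) && is.null(viscosity_slope) &&
      is.null(amplitude_ratio)) {
    stop("at least one evidence channel must be supplied")
  }
  channels <- character(0)
  verdict <- "indeterminate"
  if (!is.null(elemental) &&
      elemental$classification == "chemistry_limited") {
    verdict <- "chemistry"
    channels <- "elemental_within_benchmark"
  } else if (!is.null(viscosity_slope) &&
             abs(viscosity_slope - (-1)) <= 0.25) {
    verdict <- "large_scale_motion"
    channels <- "viscosity_inverse_proportional"
  } else if (!is.null(elemental) &&
             elemental$classification == "not_chemistry_limited" &&
             !is.null(amplitude_ratio) && amplitude_ratio > 1 &&
             !is.null(viscosity_slope) &&
             abs(viscosity_slope) < viscosity_threshold) {
    verdict <- "pre_chemical_local_step"
    channels <- c("elemental_below_benchmark", "amplitude_ratio_gt_1",
                  "viscosity_flat")
  }
  structure(list(verdict = verdict, channels = channels),
            class = "rate_limiting_verdict")
}

#' @export
print.rate_limiting_verdict <- function(x, ...) {
  cat("<rate_limiting_verdict>", x$verdict, "\n")
  if (length(x$channels)) {
    cat("  evidence:", paste(x$channels, collapse = ", "), "\n")
  }
  invisible(x)
}
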