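# Estimation layer: single-exponential product-formation fits, linear
# fits for slow misincorporation, the linearized Eyring fit, activation
# free-energy propagation, and replicate aggregation.

#' Fit a single-exponential product-formation time course
#'
#' Least-squares fit of `signal = A * (1 - exp(-k_obs * t))` by
#' Levenberg-Marquardt. Default starting values are `A0 = max(signal)`
#' and `k0 = ln(2) / t_half`, where `t_half` is the earliest time at
#' which the signal reaches half its maximum. Both parameters are
#' bounded below at zero.
#'
#' @param tc An observed time course ([observed_timecourse()]) or a
#'   data.frame with columns `time_s` and `signal_nM`.
#' @param init Optional named vector `c(A = , k_obs = )` of starting
#'   values.
#' @return A list of class `exp_fit`: `A`, `k_obs`, `se_A`, `se_k`,
#'   `rss`, `n`, `converged`.
#' @export
#' @examples
#' tc <- generate_exponential_timecourse(18.8, 0.77,
#'   rfq_time_grid(0.77), noise_model(sd_nM = 0))[[1]]
#' fit_single_exponential(tc)
fit_single_exponential <- function(tc, init = NULL) {
  t <- tc$time_s
  y <- tc$signal_nM
  if (length(t) < 3) stop("at least 3 points are required")
  if (any(t < 0)) stop("times must be non-negative")
  if (max(y) - min(y) <= 0 || stats::sd(y) == 0) {
    return(structure(list(A = max(y), k_obs = NA_real_, se_A = NA_real_,
                          se_k = NA_real_, rss = 0, n = length(t),
                          converged = FALSE), class = "exp_fit"))
  }
  if (is.null(init)) {
    A0 <- max(y)
    half_idx <- which(y >= A0 / 2)
    t_half <- if (length(half_idx) && t[min(half_idx)] > 0) {
      t[min(half_idx)]
    } else {
      max(t) / 2
    }
    init <- c(A = A0, k_obs = log(2) / t_half)
  }
  fit <- try(minpack.lm::nlsLM(
    y ~ A * (1 - exp(-k_obs * t)),
    start = as.list(init),
    lower = c(A = 0, k_obs = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(A = NA_real_, k_obs = NA_real_, se_A = NA_real_,
                          se_k = NA_real_, rss = NA_real_, n = length(t),
                          converged = FALSE), class = "exp_fit"))
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(A = NA_real_, k_obs = NA_real_))
  structure(list(A = unname(est["A"]), k_obs = unname(est["k_obs"]),
                 se_A = unname(se["A"]), se_k = unname(se["k_obs"]),
                 rss = sum(stats::resid(fit)^2), n = length(t),
                 converged = TRUE),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> A = %.4g +/- %.2g nM, k_obs = %.4g +/- %.2g s^-1 (n = %d, %s)\n",
              x$A, x$se_A, x$k_obs, x$se_k, x$n,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit a linear time course
#'
#' Ordinary least squares of signal on time; used for misincorporation
#' time courses too slow to show curvature.
#'
#' @inheritParams fit_single_exponential
#' @return A list of class `linear_fit`: `slope` (nM/s), `intercept`
#'   (nM), `se_slope`, `se_intercept`, `n`.
#' @export
fit_linear <- function(tc) {
  t <- tc$time_s
  y <- tc$signal_nM
  if (length(t) < 2) stop("at least 2 points are required")
  if (stats::sd(t) == 0) stop("all times are equal; slope is undefined")
  fit <- stats::lm(y ~ t)
  # noise-free inputs trigger a harmless "essentially perfect fit" warning
  cf <- suppressWarnings(summary(fit)$coefficients)
  se <- if (nrow(cf) == 2 && ncol(cf) >= 2) cf[, "Std. Error"] else
    c(NA_real_, NA_real_)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 se_slope = unname(se[2]), se_intercept = unname(se[1]),
                 n = length(t)),
            class = "linear_fit")
}

#' Fit the linearized Eyring equation
#'
#' Linear regression of `ln(k/T)` on `1/T` with transmission coefficient
#' fixed at 1: the activation enthalpy is `-slope * R` and the activation
#' entropy is `(intercept - ln(kB/h)) * R`. Standard errors come from
#' the regression covariance; the (strongly anticorrelated) parameter
#' covariance is retained for the optional covariance-aware free-energy
#' propagation.
#'
#' @param T_K Temperatures in kelvin (>= 2 distinct values).
#' @param k_obs Observed rate constants (s^-1, positive) at each
#'   temperature.
#' @return A list of class `eyring_fit`: `dH_kcal`, `dS_cal`, `se_dH`,
#'   `se_dS`, `cov_HS` (kcal x kcal/K), `kappa`, `n`.
#' @export
#' @examples
#' T_K <- c(293.15, 298.15, 303.15, 310.15)
#' fit_eyring(T_K, eyring_rate(21.5, 11.5, T_K))
fit_eyring <- function(T_K, k_obs) {
  if (length(T_K) != length(k_obs)) stop("T_K and k_obs lengths differ")
  if (length(unique(T_K)) < 2) stop("at least 2 distinct temperatures needed")
  if (any(k_obs <= 0)) stop("all rate constants must be positive")
  if (any(T_K <= 0)) stop("temperatures must be positive (kelvin)")
  x <- 1 / T_K
  yv <- log(k_obs / T_K)
  fit <- stats::lm(yv ~ x)
  cf <- stats::coef(fit)
  R_kcal <- tst_constants$R_kcal
  R_cal <- tst_constants$R_cal
  dH <- -unname(cf["x"]) * R_kcal
  dS <- (unname(cf["(Intercept)"]) - log(tst_constants$kB_over_h)) * R_cal
  V <- suppressWarnings(stats::vcov(fit))
  se_dH <- sqrt(V["x", "x"]) * R_kcal
  se_dS <- sqrt(V["(Intercept)", "(Intercept)"]) * R_cal
  # Cov(dH [kcal], dS [cal]) -> kcal * kcal units for propagation:
  cov_HS <- -V["x", "(Intercept)"] * R_kcal * R_cal / 1000
  if (length(T_K) == 2) {
    se_dH <- 0; se_dS <- 0; cov_HS <- 0  # exact interpolation
  }
  structure(list(dH_kcal = dH, dS_cal = dS, se_dH = se_dH, se_dS = se_dS,
                 cov_HS = cov_HS, kappa = 1, n = length(T_K)),
            class = "eyring_fit")
}

#' @export
print.eyring_fit <- function(x, ...) {
  cat(sprintf("<eyring_fit> dH = %.4g +/- %.2g kcal/mol, dS = %.4g +/- %.2g cal/(mol K)\n",
              x$dH_kcal, x$se_dH, x$dS_cal, x$se_dS))
  invisible(x)
}

#' Activation free energy at a temperature, with propagated error
#'
#' `dG = dH - T * dS` (entropy converted to kcal). By default the
#' uncertainty is propagated assuming independent dH and dS,
#' `s_G = sqrt(s_H^2 + T^2 s_S^2)`, the convention used when activation
#' parameters are reported as independent mean +/- SD values. Because a
#' linear Eyring fit makes dH and dS strongly anticorrelated, a
#' covariance-aware mode is available and gives a smaller (more
#' realistic) uncertainty.
#'
#' @param fit An `eyring_fit`, or a list/vector with `dH_kcal`, `dS_cal`
#'   and optionally `se_dH`, `se_dS`.
#' @param T_K Temperature in kelvin.
#' @param use_covariance Include the dH-dS covariance term (default
#'   FALSE).
#' @return Named vector `c(dG_kcal = , se_dG = )`.
#' @export
#' @examples
#' delta_g(list(dH_kcal = 21.5, dS_cal = 11.5, se_dH = 0.2, se_dS = 0.5),
#'         310.15)
delta_g <- function(fit, T_K, use_covariance = FALSE) {
  if (T_K <= 0) stop("temperature must be positive")
  dH <- fit$dH_kcal
  dS_kcal <- fit$dS_cal / 1000
  se_dH <- if (is.null(fit$se_dH) || is.na(fit$se_dH)) 0 else fit$se_dH
  se_dS_kcal <- if (is.null(fit$se_dS) || is.na(fit$se_dS)) 0 else
    fit$se_dS / 1000
  dG <- dH - T_K * dS_kcal
  var_G <- se_dH^2 + T_K^2 * se_dS_kcal^2
  if (use_covariance && !is.null(fit$cov_HS)) {
    var_G <- var_G - 2 * T_K * fit$cov_HS
  }
  c(dG_kcal = dG, se_dG = sqrt(max(var_G, 0)))
}

#' Aggregate a parameter across replicates
#'
#' Arithmetic mean and sample (n-1) standard deviation, the convention
#' for reporting kinetic parameters as mean +/- SD over independent
#' experiments. With a single replicate the SD is returned as `NA`.
#'
#' @param values Numeric vector of per-replicate parameter estimates.
#' @return A list of class `replicate_summary`: `values`, `mean`, `sd`,
#'   `n`.
#' @export
aggregate_replicates <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("no replicate values supplied")
  structure(list(values = values, mean = mean(values),
                 sd = if (length(values) > 1) stats::sd(values) else NA_real_,
                 n = length(values)),
            class = "replicate_summary")
}
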