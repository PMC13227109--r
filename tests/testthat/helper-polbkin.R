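# Shared test helpers.

# Rate set with every constant zero (frozen system).
zero_rates <- function(variant = "crosslinked") {
  r <- default_rates(variant)
  rate_set(variant, stats::setNames(rep(0, length(r$values)),
                                    names(r$values)))
}

# Crosslinked rate set where only the named constants are nonzero;
# isolates small sub-networks with closed-form solutions.
only_rates <- function(...) {
  update_rates(zero_rates("crosslinked"), ...)
}

# Simulate a single-turnover run and fit it, returning the exp_fit.
measure_kobs <- function(rates, dNTP_uM = 25, ...) {
  cfg <- protocol_config("single_turnover", dNTP_uM = dNTP_uM, ...)
  fit_single_exponential(simulate_single_turnover(rates, cfg))
}

# Relative difference helper.
rel_err <- function(x, ref) abs(x - ref) / abs(ref)
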