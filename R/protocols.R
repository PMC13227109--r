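# Emulators of the pre-steady-state experimental designs: single-turnover
# rapid quench, pulse-quench, pulse-chase (with explicit labeled/unlabeled
# nucleotide bookkeeping), and temperature/viscosity series.

#' Protocol configuration
#'
#' @param protocol One of `"single_turnover"`, `"pulse_quench"`,
#'   `"pulse_chase"`, `"temperature_series"`, `"viscosity_series"`.
#' @param enzyme_complex_nM Active enzyme-DNA complex concentration
#'   (default 30 nM, the standard assay concentration).
#' @param dNTP_uM Nucleotide concentration in uM (25 for saturating
#'   correct incorporation; 1.5 for the radiolabeled pulse assays).
#' @param chase_dNTP_uM Unlabeled chase nucleotide concentration
#'   (default 1500 uM, a 1000-fold excess over the 1.5 uM pulse).
#' @param chase_duration_s Chase duration before quenching (default 20 s).
#' @param quench_times_s Optional quench-time grid (s); when NULL a
#'   rapid-quench grid spanning five half-lives of the rate-limiting step
#'   is generated.
#' @param temperature_K Assay temperature (default 310.15 K, i.e. 37 C).
#' @param relative_viscosity Relative solvent viscosity (default 1).
#' @param elemental_factor Reduction factor applied to the chemistry-step
#'   rates for an alpha-thio (Sp-dNTPalphaS) substrate (default 1: oxygen).
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(protocol = c("single_turnover", "pulse_quench",
                                         "pulse_chase", "temperature_series",
                                         "viscosity_series"),
                            enzyme_complex_nM = 30, dNTP_uM = 25,
                            chase_dNTP_uM = 1500, chase_duration_s = 20,
                            quench_times_s = NULL, temperature_K = 310.15,
                            relative_viscosity = 1, elemental_factor = 1) {
  protocol <- match.arg(protocol)
  if (enzyme_complex_nM <= 0) stop("enzyme_complex_nM must be positive")
  if (dNTP_uM < 0) stop("dNTP_uM must be non-negative")
  if (chase_duration_s < 0) stop("chase_duration_s must be non-negative")
  if (!is.null(quench_times_s) && any(quench_times_s < 0)) {
    stop("quench times must be non-negative")
  }
  if (protocol == "pulse_chase" && dNTP_uM > 0 &&
      chase_dNTP_uM / dNTP_uM < 1) {
    stop("chase nucleotide must be at least as concentrated as the pulse")
  }
  structure(list(protocol = protocol, enzyme_complex_nM = enzyme_complex_nM,
                 dNTP_uM = dNTP_uM, chase_dNTP_uM = chase_dNTP_uM,
                 chase_duration_s = chase_duration_s,
                 quench_times_s = quench_times_s,
                 temperature_K = temperature_K,
                 relative_viscosity = relative_viscosity,
                 elemental_factor = elemental_factor),
            class = "protocol_config")
}

.effective_rates <- function(rates, cfg) {
  if (cfg$elemental_factor != 1) {
    rates <- apply_elemental_substitution(rates, cfg$elemental_factor)
  }
  if (cfg$relative_viscosity != 1) {
    rates <- apply_viscosity(rates, cfg$relative_viscosity)
  }
  rates
}

# Quench-time grid matched to the expected observed rate, as an
# experimenter would choose it: the rate-limiting forward step scaled by
# the pre-equilibrium ternary occupancy, in series with the chemical
# step when that is slow.
.quench_grid <- function(rates, cfg) {
  if (!is.null(cfg$quench_times_s)) return(cfg$quench_times_s)
  v <- rates$values
  S_nM <- cfg$dNTP_uM * 1000
  if (rates$variant == "crosslinked") {
    fB <- if (v[["k3"]] + v[["k-3"]] > 0) {
      v[["k3"]] / (v[["k3"]] + v[["k-3"]])  # bindable binary fraction
    } else {
      0.5
    }
    k_bind <- (v[["k4"]] / 1000) * S_nM * fB
    r_occ <- if (v[["k-4"]] > 0) k_bind / v[["k-4"]] else Inf
    a <- if (v[["k3"]] > 0) v[["k-3"]] / v[["k3"]] else 0
    theta <- if (is.infinite(r_occ)) 1 else r_occ / (1 + a + r_occ)
    k_fwd <- v[["k5"]] * theta
    k_chem <- v[["k6"]]
  } else {
    k_bind <- (v[["k2"]] / 1000) * S_nM
    r_occ <- if (v[["k-2"]] > 0) k_bind / v[["k-2"]] else Inf
    theta <- if (is.infinite(r_occ)) 1 else r_occ / (1 + r_occ)
    k_fwd <- v[["k3"]] * theta
    k_chem <- v[["k4"]]
  }
  ks <- c(k_bind, k_fwd, k_chem)
  ks <- ks[ks > 0]
  k_lim <- if (length(ks)) 1 / sum(1 / ks) else 1e-6
  rfq_time_grid(k_lim)
}

# Initial state: all enzyme as the pre-formed binary complex. For the
# crosslinked variant the two binary substates start at their Step-3
# equilibrium occupancies.
.initial_state <- function(scheme, rates, cfg, dNTP_species = "dNTP") {
  init <- stats::setNames(numeric(0), character(0))
  pool <- scheme$binary_pool
  if (length(pool) == 2) {
    k3 <- rates$values[["k3"]]; km3 <- rates$values[["k-3"]]
    fB <- if (k3 + km3 > 0) k3 / (k3 + km3) else 0.5
    init[pool] <- cfg$enzyme_complex_nM * c(1 - fB, fB)
  } else {
    init[pool] <- cfg$enzyme_complex_nM
  }
  init[dNTP_species] <- cfg$dNTP_uM * 1000  # uM -> nM
  init
}

#' Simulate a single-turnover rapid-quench experiment
#'
#' The pre-formed enzyme-DNA complex (covalently crosslinked binary
#' complex for the crosslinked variant, E.DNA for the uncrosslinked one)
#' is mixed with nucleotide at time zero and the quench-counted product
#' signal (every species at or downstream of phosphodiester bond
#' formation) is read at each quench time.
#'
#' @param rates A `rate_set`.
#' @param cfg A [protocol_config()]; its `elemental_factor` and
#'   `relative_viscosity` are applied to `rates` before simulation.
#' @param scheme Optional pre-built [build_scheme()] scheme (its compiled
#'   constants are re-resolved against the effective rates).
#' @param observable Observable set name (default `"acid_quench_product"`).
#' @return An observed time course (`polbkin_tc`).
#' @export
#' @examples
#' cfg <- protocol_config("single_turnover", dNTP_uM = 25)
#' tc <- simulate_single_turnover(default_rates("crosslinked"), cfg)
simulate_single_turnover <- function(rates, cfg = protocol_config(),
                                     scheme = NULL,
                                     observable = "acid_quench_product") {
  eff <- .effective_rates(rates, cfg)
  if (is.null(scheme)) scheme <- build_scheme(eff$variant, eff)
  times <- .quench_grid(eff, cfg)
  init <- .initial_state(scheme, eff, cfg)
  pos_times <- times[times > 0]
  traj <- integrate_scheme(scheme, init, pos_times, rates = eff)
  tc <- observe(traj, scheme, observable,
                protocol = cfg$protocol, temperature_K = cfg$temperature_K)
  if (any(times == 0)) {
    tc <- observed_timecourse(c(0, tc$time_s), c(0, tc$signal_nM),
                              protocol = cfg$protocol,
                              temperature_K = cfg$temperature_K)
  }
  tc
}

#' Simulate a pulse-quench experiment
#'
#' Radiolabeled nucleotide (typically 1.5 uM) reacts with the enzyme
#' complex and the reaction is acid-quenched at each time; only species
#' that have completed phosphodiester bond formation count as product.
#' Without a chase every nucleotide is labeled, so this is the
#' single-turnover readout at the pulse nucleotide concentration.
#'
#' @inheritParams simulate_single_turnover
#' @return An observed time course.
#' @export
simulate_pulse_quench <- function(rates, cfg, scheme = NULL) {
  simulate_single_turnover(rates, cfg, scheme = scheme,
                           observable = "acid_quench_product")
}

# Duplicate nucleotide-carrying species of a scheme into labeled (_L)
# and unlabeled (_U) copies. Every reaction touching a carrier species
# is emitted once per label; label identity follows the alpha-phosphate,
# so PPi and HPP remain unlabeled.
.labeled_scheme <- function(scheme) {
  carriers <- scheme$label_carrying
  relabel <- function(v, suffix) {
    nm <- names(v)
    nm[nm %in% carriers] <- paste0(nm[nm %in% carriers], suffix)
    stats::setNames(unname(v), nm)
  }
  species <- unlist(lapply(scheme$species, function(s) {
    if (s %in% carriers) paste0(s, c("_L", "_U")) else s
  }))
  reactions <- list()
  rate_values <- numeric(0)
  for (j in seq_along(scheme$reactions)) {
    rx <- scheme$reactions[[j]]
    touches <- any(c(names(rx$reactants), names(rx$products)) %in% carriers)
    if (!touches) {
      reactions[[length(reactions) + 1]] <- rx
      rate_values <- c(rate_values, scheme$rate_values[j])
    } else {
      for (suffix in c("_L", "_U")) {
        reactions[[length(reactions) + 1]] <-
          .reaction(rx$step, rx$label, relabel(rx$reactants, suffix),
                    relabel(rx$products, suffix))
        rate_values <- c(rate_values, scheme$rate_values[j])
      }
    }
  }
  stoich <- matrix(0, nrow = length(species), ncol = length(reactions),
                   dimnames = list(species, NULL))
  for (j in seq_along(reactions)) {
    rx <- reactions[[j]]
    stoich[names(rx$reactants), j] <-
      stoich[names(rx$reactants), j] - rx$reactants
    stoich[names(rx$products), j] <-
      stoich[names(rx$products), j] + rx$products
  }
  expand <- function(set) {
    unlist(lapply(set, function(s) {
      if (s %in% carriers) paste0(s, c("_L", "_U")) else s
    }))
  }
  product_set <- scheme$observables$acid_quench_product
  out <- scheme
  out$species <- species
  out$reactions <- reactions
  out$stoich <- stoich
  out$rate_values <- rate_values
  out$observables <- c(
    lapply(scheme$observables, expand),
    list(labeled_product = paste0(product_set, "_L"),
         unlabeled_product = paste0(product_set, "_U"))
  )
  out$composition <- lapply(scheme$composition, expand)
  out$label_carrying <- character(0)
  out
}

#' Simulate a pulse-chase experiment
#'
#' Nucleotide-carrying species are duplicated into labeled and unlabeled
#' copies. The complex reacts with labeled nucleotide; at each quench
#' time the free label is diluted into a large unlabeled pool (the
#' chase), integration continues for `chase_duration_s`, and the labeled
#' product is then read out. Enzyme-bound labeled intermediates that are
#' committed forward convert to product during the chase, so the chase
#' signal is at least the pulse-quench signal at every time.
#'
#' @inheritParams simulate_single_turnover
#' @return An observed time course of labeled product (nM) versus pulse
#'   duration.
#' @export
simulate_pulse_chase <- function(rates, cfg, scheme = NULL) {
  eff <- .effective_rates(rates, cfg)
  if (is.null(scheme)) scheme <- build_scheme(eff$variant, eff)
  lsc <- .labeled_scheme(scheme)
  times <- .quench_grid(eff, cfg)
  init <- .initial_state(scheme, eff, cfg)
  names(init)[names(init) == "dNTP"] <- "dNTP_L"
  pos_times <- times[times > 0]
  traj <- integrate_scheme(lsc, init, pos_times)
  labeled_set <- lsc$observables$labeled_product
  signal <- vapply(seq_len(nrow(traj)), function(i) {
    state <- stats::setNames(as.numeric(traj[i, lsc$species]), lsc$species)
    if (cfg$chase_duration_s > 0) {
      state["dNTP_U"] <- state["dNTP_U"] + cfg$chase_dNTP_uM * 1000
      chase <- integrate_scheme(lsc, state,
                                times = cfg$chase_duration_s)
      sum(chase[nrow(chase), labeled_set])
    } else {
      sum(state[labeled_set])
    }
  }, numeric(1))
  if (any(times == 0)) {
    pos_times <- c(0, pos_times)
    signal <- c(0, signal)
  }
  observed_timecourse(pos_times, signal, protocol = "pulse_chase",
                      temperature_K = cfg$temperature_K)
}

#' Simulate a temperature series
#'
#' At each temperature the designated rates are recomputed from their
#' activation parameters ([apply_temperature()]) and a single-turnover
#' time course is simulated on a grid matched to the expected rate.
#'
#' @param rates A `rate_set` (constants at the reference temperature).
#' @param temperatures_K Vector of assay temperatures (K).
#' @param activation Named list of activation parameters per rate label,
#'   as for [apply_temperature()]; by default applied to the
#'   rate-limiting step only.
#' @param cfg A [protocol_config()].
#' @return List of observed time courses, one per temperature (each
#'   carries its temperature as metadata).
#' @export
simulate_temperature_series <- function(rates, temperatures_K, activation,
                                        cfg = protocol_config()) {
  lapply(temperatures_K, function(T_K) {
    rT <- apply_temperature(rates, T_K, activation)
    cfgT <- cfg
    cfgT$temperature_K <- T_K
    cfgT$quench_times_s <- NULL  # re-span the grid at each temperature
    simulate_single_turnover(rT, cfgT)
  })
}

#' Simulate a viscosity series
#'
#' @param rates A `rate_set`.
#' @param relative_viscosities Vector of relative viscosities (>= 1).
#' @param cfg A [protocol_config()].
#' @param affected_labels Optional override of the diffusion-sensitive
#'   rate labels (see [apply_viscosity()]).
#' @return List of observed time courses, one per viscosity.
#' @export
simulate_viscosity_series <- function(rates, relative_viscosities,
                                      cfg = protocol_config(),
                                      affected_labels = NULL) {
  lapply(relative_viscosities, function(eta) {
    r_eta <- apply_viscosity(rates, eta, affected_labels)
    cfg_eta <- cfg
    cfg_eta$relative_viscosity <- 1  # already applied
    simulate_single_turnover(r_eta, cfg_eta)
  })
}
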