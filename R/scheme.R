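# Reaction-network representation of the minimal kinetic mechanisms.
#
# A scheme is a list of elementary reactions with integer stoichiometry
# and symbolic rate labels, compiled against a rate_set into a
# mass-action ODE system. Internal concentrations are nM and time is
# seconds; bimolecular constants supplied in uM^-1 s^-1 are divided by
# 1000 on compilation.

.reaction <- function(step, label, reactants, products) {
  list(step = step, label = label, reactants = reactants,
       products = products)
}

.crosslinked_reactions <- function(explicit_step3, explicit_step5i) {
  bin <- if (explicit_step3) c("ExDNAn_A", "ExDNAn_B") else "ExDNAn"
  bind_state <- bin[length(bin)]
  closed <- if (explicit_step5i) c("ExDNAn.dNTP_c1", "ExDNAn.dNTP_c2") else
    "ExDNAn.dNTP_c"
  species <- c("E", "DNAn", "E.DNAn", bin, "dNTP", "ExDNAn.dNTP", closed,
               "ExDNAn1.PPi_c", "ExDNAn1.PPi", "ExDNAn1", "PPi", "HPP",
               "E.DNAn1", "DNAn1")
  rx <- list(
    .reaction("1", "k1", c(E = 1, DNAn = 1), c(E.DNAn = 1)),
    .reaction("1", "k-1", c(E.DNAn = 1), c(E = 1, DNAn = 1)),
    .reaction("2", "k2", c(E.DNAn = 1), stats::setNames(1, bin[1]))
  )
  if (explicit_step3) {
    rx <- c(rx, list(
      .reaction("3", "k3", c(ExDNAn_A = 1), c(ExDNAn_B = 1)),
      .reaction("3", "k-3", c(ExDNAn_B = 1), c(ExDNAn_A = 1))
    ))
  }
  rx <- c(rx, list(
    .reaction("4", "k4", stats::setNames(c(1, 1), c(bind_state, "dNTP")),
              c(ExDNAn.dNTP = 1)),
    .reaction("4", "k-4", c(ExDNAn.dNTP = 1),
              stats::setNames(c(1, 1), c(bind_state, "dNTP")))
  ))
  if (explicit_step5i) {
    # two sequential first-order sub-steps; each at 2*k5 so the harmonic
    # sum of the pair equals the configured composite k5
    rx <- c(rx, list(
      .reaction("5", "k5", c(ExDNAn.dNTP = 1), c(ExDNAn.dNTP_c1 = 1)),
      .reaction("5", "k-5", c(ExDNAn.dNTP_c1 = 1), c(ExDNAn.dNTP = 1)),
      .reaction("5i", "k5", c(ExDNAn.dNTP_c1 = 1), c(ExDNAn.dNTP_c2 = 1))
    ))
  } else {
    rx <- c(rx, list(
      .reaction("5", "k5", c(ExDNAn.dNTP = 1), c(ExDNAn.dNTP_c = 1)),
      .reaction("5", "k-5", c(ExDNAn.dNTP_c = 1), c(ExDNAn.dNTP = 1))
    ))
  }
  chem_in <- closed[length(closed)]
  rx <- c(rx, list(
    .reaction("6", "k6", stats::setNames(1, chem_in), c(ExDNAn1.PPi_c = 1)),
    .reaction("6", "k-6", c(ExDNAn1.PPi_c = 1), stats::setNames(1, chem_in)),
    .reaction("7", "k7", c(ExDNAn1.PPi_c = 1), c(ExDNAn1.PPi = 1)),
    .reaction("7", "k-7", c(ExDNAn1.PPi = 1), c(ExDNAn1.PPi_c = 1)),
    .reaction("8", "k8", c(ExDNAn1.PPi = 1), c(ExDNAn1 = 1, PPi = 1)),
    .reaction("9", "k9", c(ExDNAn1 = 1), c(E.DNAn1 = 1, HPP = 1)),
    .reaction("10", "k10", c(E.DNAn1 = 1), c(E = 1, DNAn1 = 1))
  ))
  product_species <- c("ExDNAn1.PPi_c", "ExDNAn1.PPi", "ExDNAn1",
                       "E.DNAn1", "DNAn1")
  list(
    species = species, reactions = rx,
    # species whose rates are scaled 2x when step 5 is split into 5 + 5i
    split5 = if (explicit_step5i) "5/5i" else NULL,
    observables = list(
      acid_quench_product = product_species,
      edta_quench_product = product_species
    ),
    label_carrying = c("dNTP", "ExDNAn.dNTP", closed, product_species),
    composition = list(
      enzyme = c("E", "E.DNAn", bin, "ExDNAn.dNTP", closed,
                 "ExDNAn1.PPi_c", "ExDNAn1.PPi", "ExDNAn1", "E.DNAn1"),
      dna = c("DNAn", "E.DNAn", bin, "ExDNAn.dNTP", closed,
              "ExDNAn1.PPi_c", "ExDNAn1.PPi", "ExDNAn1", "E.DNAn1", "DNAn1")
    ),
    initial_enzyme_species = bind_state,
    binary_pool = bin
  )
}

.uncrosslinked_reactions <- function() {
  species <- c("E", "DNAn", "E.DNAn", "dNTP", "E.DNAn.dNTP", "Ec.DNAn.dNTP",
               "Ec.DNAn1.PPi", "E.DNAn1.PPi", "E.DNAn1", "PPi", "DNAn1")
  rx <- list(
    .reaction("1", "k1", c(E = 1, DNAn = 1), c(E.DNAn = 1)),
    .reaction("1", "k-1", c(E.DNAn = 1), c(E = 1, DNAn = 1)),
    .reaction("2", "k2", c(E.DNAn = 1, dNTP = 1), c(E.DNAn.dNTP = 1)),
    .reaction("2", "k-2", c(E.DNAn.dNTP = 1), c(E.DNAn = 1, dNTP = 1)),
    .reaction("3", "k3", c(E.DNAn.dNTP = 1), c(Ec.DNAn.dNTP = 1)),
    .reaction("3", "k-3", c(Ec.DNAn.dNTP = 1), c(E.DNAn.dNTP = 1)),
    .reaction("4", "k4", c(Ec.DNAn.dNTP = 1), c(Ec.DNAn1.PPi = 1)),
    .reaction("4", "k-4", c(Ec.DNAn1.PPi = 1), c(Ec.DNAn.dNTP = 1)),
    .reaction("5", "k5", c(Ec.DNAn1.PPi = 1), c(E.DNAn1.PPi = 1)),
    .reaction("5", "k-5", c(E.DNAn1.PPi = 1), c(Ec.DNAn1.PPi = 1)),
    .reaction("6", "k6", c(E.DNAn1.PPi = 1), c(E.DNAn1 = 1, PPi = 1)),
    .reaction("7", "k7", c(E.DNAn1 = 1), c(E = 1, DNAn1 = 1))
  )
  product_species <- c("Ec.DNAn1.PPi", "E.DNAn1.PPi", "E.DNAn1", "DNAn1")
  list(
    species = species, reactions = rx, split5 = NULL,
    observables = list(
      acid_quench_product = product_species,
      edta_quench_product = product_species
    ),
    label_carrying = c("dNTP", "E.DNAn.dNTP", "Ec.DNAn.dNTP",
                       product_species),
    composition = list(
      enzyme = c("E", "E.DNAn", "E.DNAn.dNTP", "Ec.DNAn.dNTP",
                 "Ec.DNAn1.PPi", "E.DNAn1.PPi", "E.DNAn1"),
      dna = c("DNAn", "E.DNAn", "E.DNAn.dNTP", "Ec.DNAn.dNTP",
              "Ec.DNAn1.PPi", "E.DNAn1.PPi", "E.DNAn1", "DNAn1")
    ),
    initial_enzyme_species = "E.DNAn",
    binary_pool = "E.DNAn"
  )
}

#' Build a kinetic scheme for a mechanism variant
#'
#' Enumerates the elementary reactions of the minimal kinetic mechanism
#' as a mass-action network and compiles the supplied rate constants
#' onto it (bimolecular uM^-1 s^-1 values are converted to the internal
#' nM scale). For the crosslinked variant, Steps 2-9 are unimolecular:
#' the covalent complex cannot dissociate its DNA until beta-elimination
#' (Step 9) and product release (Step 10). The chemical step (Step 6) is
#' reversible with labels `k6`/`k-6`.
#'
#' Observable sets `acid_quench_product` and `edta_quench_product` both
#' count every species at or downstream of phosphodiester bond
#' formation; acid (HCl) and EDTA quenches are treated identically as
#' instantaneous stop reagents.
#'
#' @param variant `"crosslinked"` or `"uncrosslinked"`; must match
#'   `rates$variant`.
#' @param rates A `rate_set` providing every referenced rate label.
#' @param explicit_step3 Model the crosslinked binary substate exchange
#'   (E-DNAn)_A <-> (E-DNAn)_B explicitly (default TRUE).
#' @param explicit_step5i Split the pre-chemistry rearrangement into two
#'   sequential sub-steps (Step 5 and 5i) whose harmonic sum equals the
#'   configured `k5` (default FALSE: lumped).
#' @return An object of class `kinetic_scheme` with elements `species`,
#'   `reactions`, `stoich` (species x reaction matrix), `rate_values`
#'   (nM-scale per reaction), `observables`, and composition bookkeeping.
#' @export
#' @examples
#' sc <- build_scheme("crosslinked", default_rates("crosslinked"))
#' length(sc$species)
build_scheme <- function(variant = c("crosslinked", "uncrosslinked"), rates,
                         explicit_step3 = TRUE, explicit_step5i = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(rates, "rate_set"))
  if (variant != rates$variant) {
    stop("variant '", variant, "' does not match rates variant '",
         rates$variant, "'")
  }
  def <- if (variant == "crosslinked") {
    .crosslinked_reactions(explicit_step3, explicit_step5i)
  } else {
    .uncrosslinked_reactions()
  }
  species <- def$species
  stopifnot(!anyDuplicated(species))
  n_rx <- length(def$reactions)
  stoich <- matrix(0, nrow = length(species), ncol = n_rx,
                   dimnames = list(species, NULL))
  for (j in seq_len(n_rx)) {
    rx <- def$reactions[[j]]
    for (nm in c(names(rx$reactants), names(rx$products))) {
      if (!nm %in% species) stop("reaction references unknown species ", nm)
    }
    stoich[names(rx$reactants), j] <-
      stoich[names(rx$reactants), j] - rx$reactants
    stoich[names(rx$products), j] <-
      stoich[names(rx$products), j] + rx$products
  }
  scheme <- structure(
    list(variant = variant, species = species, reactions = def$reactions,
         stoich = stoich, observables = def$observables,
         label_carrying = def$label_carrying,
         composition = def$composition,
         initial_enzyme_species = def$initial_enzyme_species,
         binary_pool = def$binary_pool,
         explicit_step3 = explicit_step3,
         explicit_step5i = explicit_step5i),
    class = "kinetic_scheme")
  scheme$rate_values <- resolve_rate_values(scheme, rates)
  scheme
}

#' Resolve per-reaction rate constants on the internal nM scale
#'
#' Looks up each reaction's rate label in `rates`, converts bimolecular
#' uM^-1 s^-1 constants to nM^-1 s^-1, and doubles the rate of the two
#' step-5 sub-steps when they are modeled explicitly (so their harmonic
#' sum equals the configured composite `k5`).
#'
#' @param scheme A `kinetic_scheme`.
#' @param rates A `rate_set` covering every label the scheme references.
#' @return Numeric vector of per-reaction rate constants.
#' @export
resolve_rate_values <- function(scheme, rates) {
  stopifnot(inherits(scheme, "kinetic_scheme"), inherits(rates, "rate_set"))
  if (rates$variant != scheme$variant) {
    stop("rates variant does not match scheme variant")
  }
  vapply(scheme$reactions, function(rx) {
    if (!rx$label %in% names(rates$values)) {
      stop("missing rate label ", rx$label)
    }
    v <- unname(rates$values[rx$label])
    order <- sum(rx$reactants)
    if (order >= 2) v <- v / 1000  # uM^-1 s^-1 -> nM^-1 s^-1
    if (scheme$explicit_step5i && rx$label == "k5") v <- 2 * v
    v
  }, numeric(1))
}

#' Number of distinct numbered mechanism steps in a scheme
#'
#' Sub-step 5i counts with Step 5, so the crosslinked mechanism reports
#' 10 numbered steps whether or not 5i is modeled explicitly.
#'
#' @param scheme A `kinetic_scheme`.
#' @return Integer count of numbered steps.
#' @export
scheme_steps <- function(scheme) {
  steps <- vapply(scheme$reactions, `[[`, character(1), "step")
  length(unique(sub("i$", "", steps)))
}

#' Mass-action rate of change for every species
#'
#' For each species the derivative is the sum over reactions of the
#' stoichiometric coefficient times the reaction flux, where the flux is
#' the rate constant times the product of reactant concentrations
#' (mass-action law).
#'
#' @param scheme A `kinetic_scheme`.
#' @param state Named numeric vector of concentrations (nM) covering all
#'   scheme species.
#' @param rates Optional `rate_set`; defaults to the constants the scheme
#'   was compiled with.
#' @param neg_tol Concentrations below `-neg_tol` raise an error; small
#'   negative excursions (integrator round-off) are treated as zero.
#' @return Named numeric vector of derivatives, nM/s.
#' @export
mass_action_derivative <- function(scheme, state, rates = NULL,
                                   neg_tol = 1e-6) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  missing <- setdiff(scheme$species, names(state))
  if (length(missing)) {
    stop("state is missing species: ", paste(missing, collapse = ", "))
  }
  x <- state[scheme$species]
  if (any(x < -neg_tol)) {
    stop("negative concentration beyond tolerance for ",
         paste(names(x)[x < -neg_tol], collapse = ", "))
  }
  x <- pmax(x, 0)
  kvals <- if (is.null(rates)) scheme$rate_values else
    resolve_rate_values(scheme, rates)
  flux <- vapply(seq_along(scheme$reactions), function(j) {
    rx <- scheme$reactions[[j]]
    kvals[j] * prod(x[names(rx$reactants)]^rx$reactants)
  }, numeric(1))
  drop(scheme$stoich %*% flux)
}

#' Conserved moiety totals of a state
#'
#' @param scheme A `kinetic_scheme`.
#' @param state Named concentrations (nM).
#' @return Named vector with total enzyme and total DNA (nM).
#' @export
conserved_totals <- function(scheme, state) {
  c(enzyme = sum(state[scheme$composition$enzyme]),
    dna = sum(state[scheme$composition$dna]))
}

#' Integrate a kinetic scheme
#'
#' Deterministic solution of the mass-action ODE system with a
#' stiff-capable integrator (`deSolve::lsoda`), relative tolerance 1e-8
#' and absolute tolerance 1e-6 nM by default. Small negative excursions
#' in the output are clamped to zero.
#'
#' @param scheme A `kinetic_scheme`.
#' @param initial Named numeric vector of initial concentrations (nM);
#'   species not named start at 0.
#' @param times Strictly increasing output time grid in seconds.
#' @param rates Optional `rate_set` overriding the compiled constants.
#' @param rtol,atol Integration tolerances.
#' @return A data.frame with column `time_s` followed by one column per
#'   species (nM), of class `polbkin_trajectory`.
#' @export
integrate_scheme <- function(scheme, initial, times, rates = NULL,
                             rtol = 1e-8, atol = 1e-6) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(times < 0)) stop("times must be non-negative")
  y0 <- stats::setNames(numeric(length(scheme$species)), scheme$species)
  unknown <- setdiff(names(initial), scheme$species)
  if (length(unknown)) {
    stop("initial state names unknown species: ",
         paste(unknown, collapse = ", "))
  }
  y0[names(initial)] <- initial
  if (any(y0 < 0)) stop("initial concentrations must be non-negative")
  kvals <- if (is.null(rates)) scheme$rate_values else
    resolve_rate_values(scheme, rates)
  S <- scheme$stoich
  rx_reactants <- lapply(scheme$reactions, function(rx) {
    list(idx = match(names(rx$reactants), scheme$species),
         stoich = unname(rx$reactants))
  })
  deriv <- function(t, y, parms) {
    yc <- pmax(y, 0)
    flux <- vapply(seq_along(rx_reactants), function(j) {
      r <- rx_reactants[[j]]
      kvals[j] * prod(yc[r$idx]^r$stoich)
    }, numeric(1))
    list(drop(S %*% flux))
  }
  # integration grid must include t = 0 for deSolve even when the first
  # requested output time is later
  grid <- times
  prepend <- grid[1] > 0
  if (prepend) grid <- c(0, grid)
  # lsoda first; on step failure fall back to the BDF solver (vode),
  # which copes better with the stiffest label-dilution transients
  sol <- suppressWarnings(
    deSolve::ode(y = y0, times = grid, func = deriv, parms = NULL,
                 method = "lsoda", rtol = rtol, atol = atol,
                 maxsteps = 50000))
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(grid)) {
    sol <- suppressWarnings(
      deSolve::ode(y = y0, times = grid, func = deriv, parms = NULL,
                   method = "vode", rtol = rtol, atol = atol,
                   maxsteps = 50000))
  }
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(grid)) {
    stop("integration failed; last good time ", max(sol[, "time"]))
  }
  sol <- as.data.frame(sol)
  if (prepend) sol <- sol[-1, , drop = FALSE]
  conc <- sol[, scheme$species, drop = FALSE]
  if (any(conc < -1e-3)) {
    warning("negative concentrations beyond tolerance were clamped")
  }
  conc[conc < 0] <- 0
  out <- cbind(data.frame(time_s = sol$time), conc)
  rownames(out) <- NULL
  class(out) <- c("polbkin_trajectory", "data.frame")
  attr(out, "scheme_variant") <- scheme$variant
  out
}

#' Project a full trajectory onto an observable
#'
#' The observed signal at each time is the sum of the concentrations of
#' the species in the named observable set (the mechanistic counterpart
#' of a background-corrected product band on a quantified gel).
#'
#' @param trajectory A `polbkin_trajectory` from [integrate_scheme()].
#' @param scheme The `kinetic_scheme` that produced it.
#' @param observable Name of an observable set defined by the scheme, or
#'   a character vector of species names.
#' @param ... Metadata passed to [observed_timecourse()].
#' @return An observed time course (`polbkin_tc`).
#' @export
observe <- function(trajectory, scheme, observable = "acid_quench_product",
                    ...) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (length(observable) == 1 && observable %in% names(scheme$observables)) {
    set <- scheme$observables[[observable]]
  } else if (all(observable %in% scheme$species)) {
    set <- observable
  } else {
    stop("unknown observable '", paste(observable, collapse = ","), "'")
  }
  sig <- if (length(set)) {
    rowSums(trajectory[, set, drop = FALSE])
  } else {
    rep(0, nrow(trajectory))
  }
  observed_timecourse(trajectory$time_s, sig, ...)
}
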