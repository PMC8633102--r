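#' Boltzmann statistical weight
#'
#' `w = exp(-G / RT)`, the unnormalised statistical weight of a conformation
#' with free energy `G`.
#'
#' @param G Free energy (kcal/mol); vectorised.
#' @param temperature Temperature, Kelvin.
#' @param gas_constant Gas constant, kcal/(mol K).
#' @return Dimensionless weight(s), strictly positive and strictly decreasing
#'   in `G`.
#' @examples
#' boltzmann_weight(0)                      # 1
#' boltzmann_weight(-1, temperature = 298)  # ~5.41
#' @export
boltzmann_weight <- function(G, temperature = DEFAULT_TEMPERATURE,
                             gas_constant = R_KCAL) {
  check_temperature(temperature)
  check_gas_constant(gas_constant)
  exp(-G / (gas_constant * temperature))
}

#' Equilibrium conformation frequencies
#'
#' Normalised Boltzmann weights, `f_c = w_c / sum(w)`. Computed with a
#' max-shift so that arbitrarily large energies do not overflow; frequencies
#' are invariant to adding a constant to every energy.
#'
#' @param energies Named (or unnamed) numeric vector of conformation free
#'   energies, kcal/mol.
#' @inheritParams boltzmann_weight
#' @return Numeric vector of frequencies summing to 1, same names as input.
#' @examples
#' conformation_frequencies(c(i = -1, j = 0, k = 0))
#' @export
conformation_frequencies <- function(energies,
                                     temperature = DEFAULT_TEMPERATURE,
                                     gas_constant = R_KCAL) {
  check_temperature(temperature)
  check_gas_constant(gas_constant)
  if (length(energies) == 0) {
    abort_invalid_input("`energies` must contain at least one conformation.")
  }
  if (!is.numeric(energies) || any(!is.finite(energies))) {
    abort_invalid_input("`energies` must be finite numbers.")
  }
  rt <- temperature * gas_constant
  w <- exp(-(energies - min(energies)) / rt)
  w / sum(w)
}

#' Boltzmann-weighted average free energy of a sub-ensemble
#'
#' The free energy of a set of conformations treated as one thermodynamic
#' state: \eqn{\langle G\rangle = -RT \ln \sum_c e^{-G_c/RT}}. Computed as a
#' max-shifted log-sum-exp, so it is finite for energies of arbitrary
#' magnitude. Satisfies `min(G) - RT*log(n) <= <G> <= min(G)` and shifts by
#' exactly `c` when all inputs shift by `c`.
#'
#' @inheritParams conformation_frequencies
#' @return A single free energy, kcal/mol.
#' @examples
#' ensemble_avg_energy(c(0, 0))            # -RT log 2
#' ensemble_avg_energy(c(0.35, -0.35))     # ~ -0.508
#' @export
ensemble_avg_energy <- function(energies,
                                temperature = DEFAULT_TEMPERATURE,
                                gas_constant = R_KCAL) {
  check_temperature(temperature)
  check_gas_constant(gas_constant)
  if (length(energies) == 0) {
    abort_invalid_input("`energies` must be a non-empty set of free energies.")
  }
  if (!is.numeric(energies) || any(!is.finite(energies))) {
    abort_invalid_input("`energies` must be finite numbers.")
  }
  rt <- temperature * gas_constant
  m <- min(energies)
  m - rt * log(sum(exp(-(energies - m) / rt)))
}

# Effects supplied to genotype_energies(): a named list of named numeric
# vectors (mutation id -> conformation -> dG), or a tidy ddG table with
# columns site, wt, mut, conformation, dG (converted via effect_list()).
as_effect_list <- function(effects) {
  if (is.data.frame(effects)) {
    return(effect_list(effects))
  }
  if (is.null(effects)) {
    return(list())
  }
  if (!is.list(effects)) {
    abort_invalid_input(
      "`effects` must be a named list of named numeric vectors or a ddG table.")
  }
  effects
}

#' Convert a tidy ddG table to a list of per-mutation effect vectors
#'
#' @param ddg_table Data frame with columns `site`, `wt`, `mut`,
#'   `conformation`, `dG` (one row per mutation and conformation).
#' @return Named list keyed by mutation label (e.g. `"F78A"`); each element a
#'   named numeric vector of per-conformation effects, kcal/mol.
#' @examples
#' tbl <- tibble::tibble(
#'   site = 78, wt = "F", mut = "A",
#'   conformation = c("capep", "ca", "apo"), dG = c(0.2, 1.4, 0.3)
#' )
#' effect_list(tbl)
#' @export
effect_list <- function(ddg_table) {
  validate_ddg_table(ddg_table)
  id <- mutation_label(ddg_table$wt, ddg_table$site, ddg_table$mut)
  split(setNames(ddg_table$dG, ddg_table$conformation), id)
}

#' Mutation labels of the form `F78A`
#'
#' @param wt,mut One-letter wild-type and mutant residues.
#' @param site 1-based residue position.
#' @return Character vector of labels.
#' @export
mutation_label <- function(wt, site, mut) {
  paste0(wt, site, mut)
}

#' Per-conformation free energies of a genotype
#'
#' Within each conformation, mutational effects are additive:
#' `G_c = G_c0 + sum(dG_c)` over the mutations present, plus optional
#' within-conformation pair couplings `ddG_c` for mutation pairs that are both
#' present. Any nonadditivity of the *observable* that remains with zero
#' couplings is therefore purely ensemble epistasis.
#'
#' @inheritParams ens_temperature
#' @param genotype Character vector of mutation identifiers present (empty =
#'   reference genotype).
#' @param effects Named list of per-mutation effect vectors (see
#'   [effect_list()]), or a tidy ddG table. Every present mutation must cover
#'   every conformation of the ensemble.
#' @param couplings Optional data frame with columns `mut_a`, `mut_b`,
#'   `conformation`, `ddG`. Rows naming a mutation that has no effect entry
#'   are dropped with a warning; rows for pairs not jointly present in the
#'   genotype are silently inapplicable.
#' @param mu Optional named ligand chemical potentials (see
#'   [baseline_energies()]).
#' @return Named numeric vector of free energies (kcal/mol), one per
#'   conformation, in ensemble order.
#' @examples
#' ens <- three_state_ensemble()
#' eff <- list(A = c(i = 0, j = 0.35, k = -0.35))
#' genotype_energies(ens, "A", eff)
#' @export
genotype_energies <- function(ensemble, genotype = character(),
                              effects = list(), couplings = NULL, mu = NULL) {
  check_ensemble(ensemble)
  effects <- as_effect_list(effects)
  g <- baseline_energies(ensemble, mu)
  labs <- names(g)
  genotype <- as.character(genotype)
  if (length(genotype) > 0) {
    missing <- setdiff(genotype, names(effects))
    if (length(missing) > 0) {
      abort_missing_data(paste0(
        "no effect entry for mutation(s): ", paste(missing, collapse = ", ")))
    }
    for (m in genotype) {
      e <- effects[[m]]
      if (!all(labs %in% names(e))) {
        abort_missing_data(paste0(
          "effect for ", m, " does not cover conformation(s): ",
          paste(setdiff(labs, names(e)), collapse = ", ")))
      }
      g <- g + e[labs]
    }
  }
  if (!is.null(couplings) && nrow(couplings) > 0) {
    need <- c("mut_a", "mut_b", "conformation", "ddG")
    if (!all(need %in% names(couplings))) {
      abort_invalid_input(
        "`couplings` needs columns mut_a, mut_b, conformation, ddG.")
    }
    known <- c(couplings$mut_a, couplings$mut_b) %in% names(effects)
    known <- known[seq_len(nrow(couplings))] &
      known[nrow(couplings) + seq_len(nrow(couplings))]
    if (any(!known)) {
      warn(paste0(
        "dropping ", sum(!known),
        " coupling row(s) referencing mutations without effect entries"))
      couplings <- couplings[known, , drop = FALSE]
    }
    on <- couplings$mut_a %in% genotype & couplings$mut_b %in% genotype
    if (any(on)) {
      cc <- couplings[on, , drop = FALSE]
      bad <- setdiff(cc$conformation, labs)
      if (length(bad) > 0) {
        abort_missing_data(paste0(
          "coupling rows name unknown conformation(s): ",
          paste(bad, collapse = ", ")))
      }
      add <- tapply(cc$ddG, factor(cc$conformation, levels = labs), sum,
                    default = 0)
      g <- g + as.numeric(add)
    }
  }
  names(g) <- labs
  g
}

#' Observable free-energy difference of an ensemble
#'
#' \eqn{\Delta G_{obs} = \langle G_{active}\rangle -
#' \langle G_{inactive}\rangle}: the Boltzmann-averaged energy of the active
#' sub-ensemble minus that of the inactive sub-ensemble. This is the linear
#' scale on which mutational effects would add if the ensemble did not
#' redistribute.
#'
#' @inheritParams ens_temperature
#' @param energies Named numeric vector covering every conformation of the
#'   ensemble (e.g. from [genotype_energies()]).
#' @return `delta_g_obs()`: a single free energy, kcal/mol. `k_obs()`: the
#'   corresponding equilibrium constant `exp(-dG_obs / RT)` (inactive ->
#'   active).
#' @examples
#' ens <- three_state_ensemble()
#' delta_g_obs(ens, c(i = 0, j = 0, k = 0))  # +RT log 2
#' k_obs(ens, c(i = 0, j = 0, k = 0))        # 0.5
#' @export
delta_g_obs <- function(ensemble, energies) {
  check_ensemble(ensemble)
  labs <- ensemble$conformation
  if (is.null(names(energies)) || !all(labs %in% names(energies))) {
    abort_invalid_input(
      "`energies` must be named and cover every conformation of the ensemble.")
  }
  tt <- attr(ensemble, "temperature")
  rr <- attr(ensemble, "gas_constant")
  ensemble_avg_energy(energies[active_labels(ensemble)], tt, rr) -
    ensemble_avg_energy(energies[inactive_labels(ensemble)], tt, rr)
}

#' @rdname delta_g_obs
#' @export
k_obs <- function(ensemble, energies) {
  exp(-delta_g_obs(ensemble, energies) / ens_rt(ensemble))
}
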