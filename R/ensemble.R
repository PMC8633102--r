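#' Define a conformational ensemble
#'
#' An ensemble is the set of interconverting conformations a macromolecule
#' adopts, split into an "active" and an "inactive" sub-ensemble. Each
#' conformation carries a baseline free energy for the reference genotype and
#' (optionally) a ligand stoichiometry that couples its energy to ligand
#' chemical potentials (see [baseline_energies()]).
#'
#' The observable studied throughout the package is
#' \eqn{\Delta G_{obs} = \langle G_{active}\rangle - \langle G_{inactive}\rangle},
#' where the brackets denote the Boltzmann-weighted average free energy
#' ([ensemble_avg_energy()]).
#'
#' @param conformations Character vector of unique conformation labels
#'   (case-sensitive).
#' @param G0 Numeric vector of baseline free energies (kcal/mol) of the
#'   reference genotype, one per conformation, at zero chemical potential.
#' @param active Character vector: labels forming the active sub-ensemble.
#'   The remaining conformations form the inactive sub-ensemble; both must be
#'   non-empty.
#' @param stoich Optional ligand stoichiometry. Either a named list mapping a
#'   conformation label to a named numeric vector of bound-ligand counts
#'   (e.g. `list(ca = c(ca = 4))`), or a long data frame with columns
#'   `conformation`, `ligand`, `count`. Conformations not mentioned bind
#'   nothing.
#' @param temperature Temperature in Kelvin. Default 298.
#' @param gas_constant Gas constant, kcal/(mol K). Default 1.9872e-3.
#'
#' @return A tibble of class `"ens_def"` with columns `conformation`, `role`
#'   (`"active"`/`"inactive"`), `G0` and a `stoich` list-column, carrying the
#'   temperature and gas constant as attributes.
#'
#' @examples
#' three_state_ensemble()
#' s100a4_ensemble()
#' @seealso [s100a4_ensemble()], [three_state_ensemble()], [delta_g_obs()]
#' @export
define_ensemble <- function(conformations, G0, active, stoich = NULL,
                            temperature = DEFAULT_TEMPERATURE,
                            gas_constant = R_KCAL) {
  check_temperature(temperature)
  check_gas_constant(gas_constant)
  if (!is.character(conformations) || length(conformations) < 2 ||
      anyDuplicated(conformations) > 0 || any(!nzchar(conformations))) {
    abort_invalid_input(
      "`conformations` must be >= 2 unique, non-empty labels.")
  }
  if (!is.numeric(G0) || length(G0) != length(conformations) ||
      any(!is.finite(G0))) {
    abort_invalid_input(
      "`G0` must be finite and have one value per conformation.")
  }
  if (!all(active %in% conformations)) {
    abort_invalid_input("`active` must be a subset of `conformations`.")
  }
  inactive <- setdiff(conformations, active)
  if (length(active) == 0 || length(inactive) == 0) {
    abort_invalid_input(
      "active and inactive sub-ensembles must both be non-empty.")
  }

  stoich_col <- rep(list(numeric()), length(conformations))
  names(stoich_col) <- conformations
  if (!is.null(stoich)) {
    if (is.data.frame(stoich)) {
      need <- c("conformation", "ligand", "count")
      if (!all(need %in% names(stoich))) {
        abort_invalid_input(
          "long-form `stoich` needs columns conformation, ligand, count.")
      }
      stoich <- split(
        setNames(stoich$count, stoich$ligand),
        factor(stoich$conformation, levels = conformations)
      )
      stoich <- stoich[lengths(stoich) > 0]
    }
    if (!is.list(stoich) || is.null(names(stoich))) {
      abort_invalid_input("`stoich` must be a named list or long data frame.")
    }
    bad <- setdiff(names(stoich), conformations)
    if (length(bad) > 0) {
      abort_invalid_input(paste0(
        "stoichiometry given for unknown conformation(s): ",
        paste(bad, collapse = ", ")))
    }
    for (lab in names(stoich)) {
      s <- stoich[[lab]]
      if (length(s) > 0 &&
          (!is.numeric(s) || is.null(names(s)) || any(s < 0))) {
        abort_invalid_input(
          "each stoichiometry must be a named non-negative numeric vector.")
      }
      stoich_col[[lab]] <- s
    }
  }

  out <- tibble::tibble(
    conformation = conformations,
    role = ifelse(conformations %in% active, "active", "inactive"),
    G0 = as.numeric(G0),
    stoich = unname(stoich_col)
  )
  structure(
    out,
    temperature = temperature,
    gas_constant = gas_constant,
    class = c("ens_def", class(out))
  )
}

#' @export
print.ens_def <- function(x, ...) {
  cat(sprintf(
    "# Conformational ensemble: %d conformations (%d active), T = %g K\n",
    nrow(x), sum(x$role == "active"), attr(x, "temperature")))
  NextMethod()
}

check_ensemble <- function(ensemble) {
  if (!inherits(ensemble, "ens_def")) {
    abort_invalid_input("`ensemble` must be created with define_ensemble().")
  }
  invisible(ensemble)
}

#' Ensemble accessors
#'
#' @param ensemble An ensemble from [define_ensemble()].
#' @return `ens_temperature()`, `ens_gas_constant()` and `ens_rt()` return
#'   single numbers; `active_labels()` and `inactive_labels()` return
#'   character vectors of conformation labels.
#' @export
ens_temperature <- function(ensemble) {
  check_ensemble(ensemble)
  attr(ensemble, "temperature")
}

#' @rdname ens_temperature
#' @export
ens_gas_constant <- function(ensemble) {
  check_ensemble(ensemble)
  attr(ensemble, "gas_constant")
}

#' @rdname ens_temperature
#' @export
ens_rt <- function(ensemble) {
  check_ensemble(ensemble)
  attr(ensemble, "temperature") * attr(ensemble, "gas_constant")
}

#' @rdname ens_temperature
#' @export
active_labels <- function(ensemble) {
  check_ensemble(ensemble)
  ensemble$conformation[ensemble$role == "active"]
}

#' @rdname ens_temperature
#' @export
inactive_labels <- function(ensemble) {
  check_ensemble(ensemble)
  ensemble$conformation[ensemble$role == "inactive"]
}

#' Re-parameterise an ensemble
#'
#' Returns a copy of the ensemble with a different temperature and/or baseline
#' energies; used e.g. to study temperature limits of epistasis.
#'
#' @inheritParams ens_temperature
#' @param temperature,G0 New values (either may be `NULL` to keep current).
#' @return A new `ens_def` object.
#' @export
update_ensemble <- function(ensemble, temperature = NULL, G0 = NULL) {
  check_ensemble(ensemble)
  if (!is.null(temperature)) {
    check_temperature(temperature)
    attr(ensemble, "temperature") <- temperature
  }
  if (!is.null(G0)) {
    if (length(G0) != nrow(ensemble)) {
      abort_invalid_input("`G0` must have one value per conformation.")
    }
    ensemble$G0 <- as.numeric(G0)
  }
  ensemble
}

#' Baseline conformation energies at given chemical potentials
#'
#' Applies the linkage relation \eqn{G_c(\mu) = G_c^0 - \sum_l n_{c,l}\,\mu_l},
#' where \eqn{n_{c,l}} is the number of ligands `l` bound in conformation `c`.
#' For S100A4, e.g., the calcium-bound conformation with four bound ions obeys
#' `G_ca = G_ca0 - 4 * mu["ca"]`, so energy is linear in each potential with
#' slope minus the stoichiometry.
#'
#' @inheritParams ens_temperature
#' @param mu Named numeric vector of ligand chemical potentials (kcal/mol,
#'   relative to the reference concentration). Ligands not named are at
#'   potential 0. `NULL` means all zero.
#' @return Named numeric vector of conformation energies, kcal/mol.
#' @examples
#' baseline_energies(s100a4_ensemble(), mu = c(ca = 2.5))
#' @export
baseline_energies <- function(ensemble, mu = NULL) {
  check_ensemble(ensemble)
  g <- setNames(ensemble$G0, ensemble$conformation)
  if (is.null(mu) || length(mu) == 0) {
    return(g)
  }
  if (!is.numeric(mu) || is.null(names(mu))) {
    abort_invalid_input("`mu` must be a named numeric vector.")
  }
  for (i in seq_len(nrow(ensemble))) {
    s <- ensemble$stoich[[i]]
    common <- intersect(names(s), names(mu))
    if (length(common) > 0) {
      g[i] <- g[i] - sum(s[common] * mu[common])
    }
  }
  g
}

#' Ready-made ensembles
#'
#' `three_state_ensemble()` builds the minimal analytical model: one active
#' conformation `i` against two inactive conformations `j` and `k` (no
#' ligands). `s100a4_ensemble()` builds the three-conformation model of the
#' allosteric calcium sensor S100A4: the peptide-bound `capep` conformation
#' (active, binding 4 Ca2+ and one target peptide) against the calcium-bound
#' `ca` (4 Ca2+) and ligand-free `apo` conformations.
#'
#' The S100A4 defaults place `apo` at 0 and `ca` at +10 kcal/mol at zero
#' chemical potential, so the closed apo form dominates until calcium is
#' raised; `G_capep` only offsets the active state and cancels from epistasis,
#' so its value is a free choice.
#'
#' @param G_i,G_j,G_k Baseline energies (kcal/mol) of the generic model.
#' @param G_apo,G_ca,G_capep Baseline energies (kcal/mol) at zero chemical
#'   potential for S100A4.
#' @param n_ca Calcium ions bound by the `ca` and `capep` conformations.
#' @inheritParams define_ensemble
#' @return An `ens_def` object.
#' @examples
#' delta_g_obs(three_state_ensemble(), c(i = 0, j = 0, k = 0))
#' @export
three_state_ensemble <- function(G_i = 0, G_j = 0, G_k = 0,
                                 temperature = DEFAULT_TEMPERATURE,
                                 gas_constant = R_KCAL) {
  define_ensemble(
    conformations = c("i", "j", "k"),
    G0 = c(G_i, G_j, G_k),
    active = "i",
    temperature = temperature,
    gas_constant = gas_constant
  )
}

#' @rdname three_state_ensemble
#' @export
s100a4_ensemble <- function(G_apo = 0, G_ca = 10, G_capep = 30, n_ca = 4,
                            temperature = DEFAULT_TEMPERATURE,
                            gas_constant = R_KCAL) {
  define_ensemble(
    conformations = c("capep", "ca", "apo"),
    G0 = c(G_capep, G_ca, G_apo),
    active = "capep",
    stoich = list(
      capep = c(ca = n_ca, pep = 1),
      ca = c(ca = n_ca)
    ),
    temperature = temperature,
    gas_constant = gas_constant
  )
}
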