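#' Conformation energy under ligand linkage
#'
#' A conformation that binds `n` copies of a ligand at chemical potential
#' `mu` has energy `G = G0 - sum(n * mu) + sum(dG)` for the mutations
#' carried: energy is linear in each potential with slope minus the
#' stoichiometry. This is the elementary linkage relation behind
#' [baseline_energies()] and the titration functions.
#'
#' @param G0 Baseline free energy at zero chemical potential, kcal/mol.
#' @param stoich Named numeric vector of bound-ligand counts (may be empty or
#'   `NULL`).
#' @param mu Named numeric vector of ligand chemical potentials, kcal/mol.
#'   Ligands absent from `mu` are at potential 0.
#' @param dG Numeric vector of mutational effects to add, kcal/mol.
#' @return Free energy, kcal/mol.
#' @examples
#' energy_at(10, c(ca = 4), c(ca = 2.5))  # 0
#' @export
energy_at <- function(G0, stoich = NULL, mu = NULL, dG = 0) {
  g <- G0 + sum(dG)
  if (length(stoich) > 0 && length(mu) > 0) {
    common <- intersect(names(stoich), names(mu))
    if (length(common) > 0) {
      g <- g - sum(stoich[common] * mu[common])
    }
  }
  g
}

#' Titrate ensemble epistasis against a ligand chemical potential
#'
#' Recomputes the full mutant cycle of a mutation pair at each value of one
#' ligand's chemical potential, holding any other potentials fixed. Epistasis
#' is effector-dependent because only some potentials populate several
#' conformations at once; when a single conformation dominates every genotype
#' (at extreme potentials) epistasis vanishes.
#'
#' @inheritParams mutant_cycle
#' @param ligand Name of the ligand whose potential is varied.
#' @param mu_grid Strictly increasing numeric grid of chemical potentials,
#'   kcal/mol. The default 0..5 by 0.1 spans the interesting range of the
#'   S100A4 calcium model.
#' @param mu_base Named numeric vector of fixed potentials for the other
#'   ligands (e.g. `c(pep = 20)` for saturating peptide).
#' @param populations If `TRUE` (default), per-genotype conformation
#'   frequencies at each grid point are retained in a list-column.
#' @return A tibble of class `"titration_curve"` with columns `mu`,
#'   `epsilon`, `eclass` and (optionally) `populations`, plus the four
#'   background-dependent effect columns used for classification. Attributes
#'   `ligand` and `cutoff` record the run. Has an [autoplot()] method.
#' @examples
#' ens <- s100a4_ensemble()
#' curve <- titrate_epistasis(ens,
#'   effect_a = c(capep = 0, ca = 1.2, apo = -0.8),
#'   effect_b = c(capep = 0, ca = -0.9, apo = 1.1)
#' )
#' peak_epistasis(curve)
#' @seealso [peak_epistasis()], [count_type_switches()]
#' @export
titrate_epistasis <- function(ensemble, effect_a, effect_b, ligand = "ca",
                              mu_grid = seq(0, 5, by = 0.1), mu_base = NULL,
                              couplings = NULL, cutoff = 0.6,
                              sign_tol = 1e-6, require_effect_cutoff = FALSE,
                              populations = TRUE) {
  check_ensemble(ensemble)
  if (length(mu_grid) == 0) {
    abort_invalid_input("`mu_grid` must be a non-empty numeric grid.")
  }
  if (is.unsorted(mu_grid, strictly = TRUE)) {
    abort_invalid_input("`mu_grid` must be strictly increasing.")
  }
  rows <- lapply(mu_grid, function(m) {
    mu <- c(setNames(m, ligand),
            mu_base[setdiff(names(mu_base), ligand)])
    cyc <- mutant_cycle(
      ensemble, effect_a, effect_b, couplings = couplings, mu = mu,
      cutoff = cutoff, sign_tol = sign_tol,
      require_effect_cutoff = require_effect_cutoff)
    pop <- NULL
    if (populations) {
      tt <- attr(ensemble, "temperature")
      rr <- attr(ensemble, "gas_constant")
      pop <- purrr::imap_dfr(cyc$energies, function(e, g) {
        f <- conformation_frequencies(e, tt, rr)
        tibble::tibble(genotype = g, conformation = names(f),
                       frequency = as.numeric(f))
      })
    }
    list(
      epsilon = cyc$epsilon, eclass = cyc$eclass,
      effects = cyc$effects, populations = pop
    )
  })

  out <- tibble::tibble(
    mu = as.numeric(mu_grid),
    epsilon = vapply(rows, function(r) r$epsilon, numeric(1)),
    eclass = vapply(rows, function(r) r$eclass, character(1)),
    effect_a_in_ab = vapply(rows, function(r) r$effects[["a_in_ab"]],
                            numeric(1)),
    effect_a_in_aB = vapply(rows, function(r) r$effects[["a_in_aB"]],
                            numeric(1)),
    effect_b_in_ab = vapply(rows, function(r) r$effects[["b_in_ab"]],
                            numeric(1)),
    effect_b_in_Ab = vapply(rows, function(r) r$effects[["b_in_Ab"]],
                            numeric(1))
  )
  if (populations) {
    out$populations <- lapply(rows, function(r) r$populations)
  }
  structure(
    out,
    ligand = ligand,
    cutoff = cutoff,
    mu_base = mu_base,
    class = c("titration_curve", class(out))
  )
}

#' Peak epistasis of a titration curve
#'
#' The grid point with the largest absolute epistasis; ties are broken
#' towards the lowest chemical potential. The signed value at that point is
#' reported.
#'
#' @param curve A [titrate_epistasis()] result.
#' @return One-row tibble with `mu_peak`, `epsilon_peak`, `class_peak`.
#' @export
peak_epistasis <- function(curve) {
  if (!inherits(curve, "titration_curve") || nrow(curve) == 0) {
    abort_invalid_input("`curve` must be a non-empty titration_curve.")
  }
  i <- which.max(abs(curve$epsilon))
  tibble::tibble(
    mu_peak = curve$mu[i],
    epsilon_peak = curve$epsilon[i],
    class_peak = curve$eclass[i]
  )
}

#' Count epistasis-type switches along a titration
#'
#' The same mutation pair can change epistatic type (magnitude, sign,
#' reciprocal-sign) as the effector potential changes. This counts class
#' changes between consecutive grid points whose epistasis magnitude is at or
#' above `cutoff`; sub-cutoff points are skipped entirely, so an excursion
#' below the cutoff with the same class on both sides contributes nothing.
#'
#' @param curve A [titrate_epistasis()] result.
#' @param cutoff Magnitude threshold, kcal/mol; defaults to the cutoff the
#'   curve was computed with.
#' @return Integer count of type switches.
#' @export
count_type_switches <- function(curve, cutoff = NULL) {
  if (!inherits(curve, "titration_curve")) {
    abort_invalid_input("`curve` must be a titration_curve.")
  }
  cutoff <- cutoff %||% attr(curve, "cutoff")
  supra <- abs(curve$epsilon) >= cutoff
  cls <- curve$eclass[supra]
  if (length(cls) < 2) {
    return(0L)
  }
  sum(cls[-1] != cls[-length(cls)])
}
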