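#' Pairwise epistasis from a four-genotype mutant cycle
#'
#' The mutant-cycle (double-difference) coupling on the observable scale:
#' `epsilon = (dG_AB - dG_aB) - (dG_Ab - dG_ab)`, i.e. how much the effect of
#' the first mutation changes when measured in the background of the second.
#' The value is symmetric in the two mutations.
#'
#' @param dg_obs Named numeric vector with the observable free energies of
#'   the four genotypes `ab`, `Ab`, `aB`, `AB` (kcal/mol).
#' @return Epistasis `epsilon`, kcal/mol.
#' @examples
#' epistasis_full(c(ab = 0, Ab = 1, aB = 1, AB = 2))  # additive: 0
#' @export
epistasis_full <- function(dg_obs) {
  need <- c("ab", "Ab", "aB", "AB")
  if (is.null(names(dg_obs)) || !all(need %in% names(dg_obs))) {
    abort_invalid_input(
      "`dg_obs` must be named with all of: ab, Ab, aB, AB.")
  }
  unname((dg_obs[["AB"]] - dg_obs[["aB"]]) - (dg_obs[["Ab"]] - dg_obs[["ab"]]))
}

# Reduced-form epistasis over one sub-ensemble: the negated double
# difference of its Boltzmann-averaged energy across the cycle. For the
# inactive sub-ensemble this equals epistasis_full() whenever couplings do
# not touch the active conformations, because every active-conformation term
# is genotype-additive and cancels from the double difference.
epistasis_reduced <- function(avg, sign = -1) {
  sign * ((avg[["AB"]] - avg[["aB"]]) - (avg[["Ab"]] - avg[["ab"]]))
}

#' Classify pairwise epistasis as magnitude, sign, or reciprocal-sign
#'
#' A pair is non-epistatic (`"none"`) when `|epsilon| < cutoff`. Otherwise the
#' class follows the background dependence of each single mutation's effect on
#' the observable: a mutation shows a sign change when its effect is positive
#' in one background and negative in the other (each side exceeding
#' `sign_tol` in magnitude). Both mutations changing sign is reciprocal-sign
#' epistasis, exactly one is sign epistasis, neither is magnitude epistasis.
#'
#' All arguments are vectorised; the classes are mutually exclusive and
#' exhaustive.
#'
#' @param epsilon Epistasis values, kcal/mol.
#' @param effect_a_in_ab,effect_a_in_aB Effect of mutation a on the
#'   observable in the reference and in the B background.
#' @param effect_b_in_ab,effect_b_in_Ab Likewise for mutation b.
#' @param cutoff Magnitude threshold (kcal/mol, >= 0) below which a pair is
#'   called non-epistatic. The scale of thermal fluctuations, ~0.6 kcal/mol at
#'   298 K, is a natural choice.
#' @param sign_tol Minimum effect magnitude (kcal/mol) for a sign comparison,
#'   suppressing floating-point sign flips around zero. Default 1e-6.
#' @param require_effect_cutoff If `TRUE`, a sign change is only called when
#'   both background effects also exceed `cutoff` in magnitude (a stricter
#'   convention some analyses use). Default `FALSE`.
#' @return Character vector over
#'   `c("none", "magnitude", "sign", "reciprocal_sign")`.
#' @export
classify_epistasis <- function(epsilon,
                               effect_a_in_ab, effect_a_in_aB,
                               effect_b_in_ab, effect_b_in_Ab,
                               cutoff, sign_tol = 1e-6,
                               require_effect_cutoff = FALSE) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || !is.finite(cutoff) ||
      cutoff < 0) {
    abort_invalid_parameter("`cutoff` must be a single non-negative number.")
  }
  if (!is.numeric(sign_tol) || length(sign_tol) != 1 || sign_tol < 0) {
    abort_invalid_parameter("`sign_tol` must be a single non-negative number.")
  }
  min_mag <- if (require_effect_cutoff) max(sign_tol, cutoff) else sign_tol
  flips <- function(ref, alt) {
    (ref > min_mag & alt < -min_mag) | (ref < -min_mag & alt > min_mag)
  }
  flip_a <- flips(effect_a_in_ab, effect_a_in_aB)
  flip_b <- flips(effect_b_in_ab, effect_b_in_Ab)
  out <- rep("magnitude", length(epsilon))
  out[xor(flip_a, flip_b)] <- "sign"
  out[flip_a & flip_b] <- "reciprocal_sign"
  out[abs(epsilon) < cutoff] <- "none"
  out
}

epistasis_classes <- function() {
  c("none", "magnitude", "sign", "reciprocal_sign")
}

#' Ensemble epistasis between two mutations
#'
#' Builds the four genotypes of the mutant cycle on the ensemble, computes
#' each observable [delta_g_obs()], and takes the double difference
#' ([epistasis_full()]). With zero couplings the within-conformation energies
#' are strictly additive, so any nonzero `epsilon` arises purely from
#' Boltzmann redistribution of the conformational populations; in that case
#' the full-cycle value provably equals the reduced form computed from the
#' inactive sub-ensemble alone, and the agreement is verified numerically.
#'
#' @inheritParams ens_temperature
#' @param effect_a,effect_b Named numeric vectors: each mutation's
#'   per-conformation energetic effect (kcal/mol), covering every
#'   conformation.
#' @param couplings Optional within-conformation pair interaction table (see
#'   [genotype_energies()]). Couplings on active conformations make the full
#'   and reduced forms legitimately differ; the full-cycle value is reported.
#' @param mu Optional named ligand chemical potentials.
#' @inheritParams classify_epistasis
#' @return An object of class `"mutant_cycle"`: a list with elements
#'   `dg_obs` (named length-4), `epsilon`, `epsilon_reduced`, `effects`
#'   (the four background-dependent single-mutation effects), `eclass`, and
#'   the call parameters. Has [tidy()] and [glance()] methods.
#' @examples
#' ens <- three_state_ensemble()
#' cyc <- mutant_cycle(ens,
#'   effect_a = c(i = 0, j = 0.35, k = -0.35),
#'   effect_b = c(i = 0, j = -0.35, k = 0.35)
#' )
#' glance(cyc)
#' @export
mutant_cycle <- function(ensemble, effect_a, effect_b, couplings = NULL,
                         mu = NULL, cutoff = 0.6, sign_tol = 1e-6,
                         require_effect_cutoff = FALSE) {
  check_ensemble(ensemble)
  effects <- list(a = effect_a, b = effect_b)
  genos <- list(
    ab = character(), Ab = "a", aB = "b", AB = c("a", "b")
  )
  energies <- lapply(genos, function(g) {
    genotype_energies(ensemble, g, effects, couplings = couplings, mu = mu)
  })
  dg <- vapply(energies, function(e) delta_g_obs(ensemble, e), numeric(1))

  tt <- attr(ensemble, "temperature")
  rr <- attr(ensemble, "gas_constant")
  inact <- inactive_labels(ensemble)
  avg_inactive <- vapply(
    energies, function(e) ensemble_avg_energy(e[inact], tt, rr), numeric(1))

  eps <- epistasis_full(dg)
  eps_red <- epistasis_reduced(avg_inactive)

  active_coupled <- !is.null(couplings) && nrow(couplings) > 0 &&
    any(couplings$conformation %in% active_labels(ensemble))
  if (!active_coupled) {
    gap <- abs(eps - eps_red)
    scale <- max(1, abs(eps))
    if (is.finite(gap) && gap > 1e-8 * scale) {
      abort(sprintf(
        "internal inconsistency: full-cycle epsilon (%.12g) and reduced-form epsilon (%.12g) disagree with no active-conformation couplings",
        eps, eps_red), class = "epiensemble_error_internal")
    }
  }

  eff <- c(
    a_in_ab = dg[["Ab"]] - dg[["ab"]],
    a_in_aB = dg[["AB"]] - dg[["aB"]],
    b_in_ab = dg[["aB"]] - dg[["ab"]],
    b_in_Ab = dg[["AB"]] - dg[["Ab"]]
  )
  eclass <- classify_epistasis(
    eps, eff[["a_in_ab"]], eff[["a_in_aB"]], eff[["b_in_ab"]],
    eff[["b_in_Ab"]], cutoff = cutoff, sign_tol = sign_tol,
    require_effect_cutoff = require_effect_cutoff
  )

  structure(
    list(
      dg_obs = dg,
      epsilon = eps,
      epsilon_reduced = eps_red,
      effects = eff,
      eclass = eclass,
      energies = energies,
      cutoff = cutoff,
      sign_tol = sign_tol,
      temperature = tt
    ),
    class = "mutant_cycle"
  )
}

#' @export
print.mutant_cycle <- function(x, ...) {
  cat("# Mutant cycle (ensemble epistasis)\n")
  cat(sprintf("  epsilon = %+.4f kcal/mol  [%s at cutoff %g]\n",
              x$epsilon, x$eclass, x$cutoff))
  cat(sprintf("  dG_obs: ab = %+.4f, Ab = %+.4f, aB = %+.4f, AB = %+.4f\n",
              x$dg_obs[["ab"]], x$dg_obs[["Ab"]], x$dg_obs[["aB"]],
              x$dg_obs[["AB"]]))
  invisible(x)
}

cube_genotype_names <- function() {
  c("abc", "Abc", "aBc", "abC", "ABc", "AbC", "aBC", "ABC")
}

#' Third-order epistasis from a three-mutation cube
#'
#' `high_order_epistasis()` takes the eight observables of the genotype cube
#' and returns the third-order coupling: the change in the pairwise epistasis
#' of mutations a and b when c is introduced,
#' `eps3 = eps(a,b | C) - eps(a,b | c)`. It vanishes for any additive or
#' purely pairwise observable surface. `epistasis_cube()` builds the cube on
#' an ensemble from three per-conformation effect vectors.
#'
#' @param dg_obs Named numeric vector over the eight genotypes
#'   `abc, Abc, aBc, abC, ABc, AbC, aBC, ABC` (kcal/mol).
#' @return `high_order_epistasis()`: the scalar `eps3`, kcal/mol.
#' @examples
#' g <- c(abc = 0, Abc = 1, aBc = 1, abC = 1, ABc = 2, AbC = 2, aBC = 2,
#'        ABC = 3)
#' high_order_epistasis(g)  # additive cube: 0
#' @export
high_order_epistasis <- function(dg_obs) {
  need <- cube_genotype_names()
  if (is.null(names(dg_obs)) || !all(need %in% names(dg_obs))) {
    abort_invalid_input(paste0(
      "`dg_obs` must be named with all of: ", paste(need, collapse = ", ")))
  }
  d <- as.list(dg_obs)
  (d$ABC - d$ABc - d$AbC - d$aBC + d$Abc + d$aBc + d$abC - d$abc)
}

#' @rdname high_order_epistasis
#' @inheritParams mutant_cycle
#' @param effect_a,effect_b,effect_c Per-conformation effect vectors of the
#'   three mutations.
#' @return `epistasis_cube()`: an object of class `"epistasis_cube"` with the
#'   eight observables, the pairwise epsilon of (a,b) in both c backgrounds,
#'   and `eps3`.
#' @export
epistasis_cube <- function(ensemble, effect_a, effect_b, effect_c,
                           couplings = NULL, mu = NULL) {
  check_ensemble(ensemble)
  effects <- list(a = effect_a, b = effect_b, c = effect_c)
  present <- list(
    abc = character(), Abc = "a", aBc = "b", abC = "c",
    ABc = c("a", "b"), AbC = c("a", "c"), aBC = c("b", "c"),
    ABC = c("a", "b", "c")
  )
  dg <- vapply(present, function(g) {
    delta_g_obs(
      ensemble,
      genotype_energies(ensemble, g, effects, couplings = couplings, mu = mu))
  }, numeric(1))

  eps_ab_c <- epistasis_full(
    c(ab = dg[["abc"]], Ab = dg[["Abc"]], aB = dg[["aBc"]], AB = dg[["ABc"]]))
  eps_ab_C <- epistasis_full(
    c(ab = dg[["abC"]], Ab = dg[["AbC"]], aB = dg[["aBC"]], AB = dg[["ABC"]]))

  structure(
    list(
      dg_obs = dg,
      eps_ab_in_c = eps_ab_c,
      eps_ab_in_C = eps_ab_C,
      eps3 = high_order_epistasis(dg)
    ),
    class = "epistasis_cube"
  )
}

#' @export
print.epistasis_cube <- function(x, ...) {
  cat("# Three-mutation genotype cube\n")
  cat(sprintf("  eps(a,b | c) = %+.4f, eps(a,b | C) = %+.4f kcal/mol\n",
              x$eps_ab_in_c, x$eps_ab_in_C))
  cat(sprintf("  third-order eps3 = %+.4f kcal/mol\n", x$eps3))
  invisible(x)
}
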