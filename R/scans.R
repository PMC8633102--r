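# Vectorised mutant-cycle engine for an ensemble with two inactive
# conformations j and k and an unaffected active conformation. Used by the
# parameter-space scans; the generic object-based route (mutant_cycle())
# serves as its independent check in the test-suite.

# Boltzmann-average of two energies, elementwise.
lse2 <- function(x, y, rt) {
  m <- pmin(x, y)
  d <- pmax(x, y) - m
  m - rt * log1p(exp(-d / rt))
}

# Returns epsilon and the four background-dependent effects on the
# observable for vectors of cycle parameters. Effects on the active
# conformation are zero here, so the observable effect is minus the change
# of the inactive-average energy.
eps2_cycle <- function(Gj, Gk, daj, dak, dbj, dbk, rt) {
  g_ab <- lse2(Gj, Gk, rt)
  g_Ab <- lse2(Gj + daj, Gk + dak, rt)
  g_aB <- lse2(Gj + dbj, Gk + dbk, rt)
  g_AB <- lse2(Gj + daj + dbj, Gk + dak + dbk, rt)
  list(
    epsilon = -((g_AB - g_aB) - (g_Ab - g_ab)),
    a_in_ab = -(g_Ab - g_ab),
    a_in_aB = -(g_AB - g_aB),
    b_in_ab = -(g_aB - g_ab),
    b_in_Ab = -(g_AB - g_Ab)
  )
}

new_scan_grid <- function(df, x_name, y_name) {
  structure(
    df,
    x_name = x_name,
    y_name = y_name,
    class = c("scan_grid", class(df))
  )
}

#' Scan epistasis for two identical mutations over ensemble parameter space
#'
#' Maps ensemble epistasis for a pair of mutations with *identical* effects,
#' as a function of the baseline stability gap between the two inactive
#' conformations (`x = Gj - Gk`) and the differential mutational effect
#' (`y = dGj - dGk`). The j-side values are held fixed (`G_j`, `dG_j`) and the
#' k-side values are derived per cell as `Gk = G_j - x`, `dGk = dG_j - y`.
#' Epistasis requires both a mixed population (small `|x|`) and a
#' differential effect (`y != 0`): the `y = 0` row is identically zero and
#' epistasis decays as `|x|` grows and a single conformation dominates.
#'
#' @param x,y Numeric axis grids, kcal/mol. Defaults span +/-2 at 0.05
#'   resolution.
#' @param G_j Baseline energy of conformation j, kcal/mol.
#' @param dG_j Effect of each mutation on conformation j, kcal/mol (default
#'   -0.96, a mildly stabilising probe mutation).
#' @inheritParams boltzmann_weight
#' @inheritParams classify_epistasis
#' @return A long-form tibble of class `"scan_grid"` with columns `x`, `y`,
#'   `epsilon`, `eclass` (rows ordered y ascending then x ascending). Has an
#'   [autoplot()] method.
#' @examples
#' sg <- scan_identical_mutations(x = seq(-1, 1, 0.5), y = seq(-1, 1, 0.5))
#' sg[which.max(abs(sg$epsilon)), ]
#' @export
scan_identical_mutations <- function(x = seq(-2, 2, by = 0.05),
                                     y = seq(-2, 2, by = 0.05),
                                     G_j = 0, dG_j = -0.96,
                                     temperature = DEFAULT_TEMPERATURE,
                                     gas_constant = R_KCAL,
                                     cutoff = 0.6, sign_tol = 1e-6) {
  if (length(x) == 0 || length(y) == 0) {
    abort_invalid_input("axis ranges must be non-empty.")
  }
  check_temperature(temperature)
  rt <- temperature * gas_constant
  grid <- tidyr::expand_grid(y = as.numeric(y), x = as.numeric(x))
  Gk <- G_j - grid$x
  dGk <- dG_j - grid$y
  cyc <- eps2_cycle(G_j, Gk, dG_j, dGk, dG_j, dGk, rt)
  out <- tibble::tibble(
    x = grid$x, y = grid$y,
    epsilon = cyc$epsilon,
    eclass = classify_epistasis(
      cyc$epsilon, cyc$a_in_ab, cyc$a_in_aB, cyc$b_in_ab, cyc$b_in_Ab,
      cutoff = cutoff, sign_tol = sign_tol)
  )
  new_scan_grid(out, x_name = "Gj - Gk (kcal/mol)",
                y_name = "dGj - dGk (kcal/mol)")
}

#' Scan epistasis over the differential effects of two mutations
#'
#' Maps epistasis for a three-conformation ensemble whose two inactive
#' conformations start equally stable (`Gj = Gk = G`), as a function of each
#' mutation's *differential* effect on the inactive conformations:
#' `x = dGj - dGk` for mutation a and `y` likewise for mutation b. Effects
#' are split symmetrically (`dGj = +x/2`, `dGk = -x/2`); with an equal-energy
#' baseline epistasis depends only on the differentials. Same-sign quadrants
#' (`x*y > 0`, synergistic differentials) give positive epistasis (magnitude
#' regime); opposite-sign quadrants give negative epistasis (sign and
#' reciprocal-sign regimes); the axes are identically zero.
#'
#' @param x,y Differential-effect grids, kcal/mol.
#' @param G Common baseline energy of the two inactive conformations.
#' @inheritParams scan_identical_mutations
#' @return A `"scan_grid"` tibble as in [scan_identical_mutations()].
#' @examples
#' sg <- scan_mutation_pair(x = seq(-1, 1, 0.1), y = seq(-1, 1, 0.1))
#' sg[which.min(abs(sg$x - 0.7) + abs(sg$y + 0.7)), ]  # opposing pair
#' @export
scan_mutation_pair <- function(x = seq(-2, 2, by = 0.05),
                               y = seq(-2, 2, by = 0.05),
                               G = 0,
                               temperature = DEFAULT_TEMPERATURE,
                               gas_constant = R_KCAL,
                               cutoff = 0.6, sign_tol = 1e-6) {
  if (length(x) == 0 || length(y) == 0) {
    abort_invalid_input("axis ranges must be non-empty.")
  }
  check_temperature(temperature)
  rt <- temperature * gas_constant
  grid <- tidyr::expand_grid(y = as.numeric(y), x = as.numeric(x))
  cyc <- eps2_cycle(
    Gj = G, Gk = G,
    daj = grid$x / 2, dak = -grid$x / 2,
    dbj = grid$y / 2, dbk = -grid$y / 2,
    rt = rt
  )
  out <- tibble::tibble(
    x = grid$x, y = grid$y,
    epsilon = cyc$epsilon,
    eclass = classify_epistasis(
      cyc$epsilon, cyc$a_in_ab, cyc$a_in_aB, cyc$b_in_ab, cyc$b_in_Ab,
      cutoff = cutoff, sign_tol = sign_tol)
  )
  new_scan_grid(out, x_name = "dGj - dGk of a (kcal/mol)",
                y_name = "dGj - dGk of b (kcal/mol)")
}
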