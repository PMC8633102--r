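AA_ONE <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Standardised right-skewed deviate: a gamma(shape) variable shifted and
# scaled to mean 0, variance 1. Small shapes give a heavier destabilising
# tail once mapped onto dG.
rskew <- function(n, shape) {
  (rgamma(n, shape = shape, rate = 1) - shape) / sqrt(shape)
}

#' Simulate a per-conformation mutational effect table
#'
#' Emulates the kind of table produced by structure-based stability
#' calculations on several conformations of one protein: for every mutation,
#' one effect per conformation, with (i) a destabilising skew (most
#' mutations destabilise, a minority stabilise, with a heavy destabilising
#' tail) and (ii) a tunable correlation of effects across conformations.
#' Effects are drawn from a one-factor model,
#' `dG_c = location + scale * (sqrt(rho) * u + sqrt(1 - rho) * e_c)`,
#' with `u` and the `e_c` independent standardised skewed deviates. At
#' `rho = 1` every conformation receives the identical effect, which
#' provably abolishes ensemble epistasis; lowering `rho` dials in the
#' differential effects that generate it.
#'
#' @param n_sites Number of mutable sites (>= 2); sites are numbered 1..n.
#' @param alphabet Residue alphabet; each site gets one wild-type drawn from
#'   it and a mutation to every other letter. The 20 amino acids (19
#'   substitutions per site) by default.
#' @param conformations Conformation labels (default the S100A4 trio).
#' @param location,scale Location and scale of the effect distribution,
#'   kcal/mol. Defaults +1.0 and 1.5.
#' @param rho Cross-conformation effect correlation in `[0, 1]`.
#' @param skew_shape Gamma shape of the skewed deviates; smaller means a
#'   heavier destabilising tail. Default 2.
#' @param seed Integer seed; the table is bit-reproducible given the seed
#'   and the caller's RNG stream is left untouched.
#' @return A tidy ddG tibble (`site`, `wt`, `mut`, `conformation`, `dG`)
#'   that [validate_ddg_table()] accepts against `conformations`.
#' @examples
#' tbl <- simulate_ddg_table(n_sites = 3, alphabet = c("A", "V", "L"),
#'                           seed = 1)
#' head(tbl)
#' @export
simulate_ddg_table <- function(n_sites, alphabet = AA_ONE,
                               conformations = c("capep", "ca", "apo"),
                               location = 1.0, scale = 1.5, rho = 0.5,
                               skew_shape = 2, seed = NULL) {
  if (!is.numeric(n_sites) || length(n_sites) != 1 || n_sites < 2) {
    abort_invalid_parameter("`n_sites` must be an integer >= 2.")
  }
  if (length(alphabet) < 2 || anyDuplicated(alphabet) > 0) {
    abort_invalid_parameter("`alphabet` must hold >= 2 unique residues.")
  }
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho > 1) {
    abort_invalid_parameter("`rho` must lie in [0, 1].")
  }
  if (!is.numeric(scale) || scale <= 0) {
    abort_invalid_parameter("`scale` must be positive.")
  }
  if (!is.numeric(skew_shape) || skew_shape <= 0) {
    abort_invalid_parameter("`skew_shape` must be positive.")
  }
  if (length(conformations) < 1 || anyDuplicated(conformations) > 0) {
    abort_invalid_parameter("`conformations` must be unique labels.")
  }
  n_sites <- as.integer(n_sites)
  with_seed(seed, {
    wt <- sample(alphabet, n_sites, replace = TRUE)
    muts <- lapply(seq_len(n_sites), function(s) setdiff(alphabet, wt[s]))
    site <- rep(seq_len(n_sites), lengths(muts))
    mut <- unlist(muts)
    n_mut <- length(mut)
    n_conf <- length(conformations)
    u <- rskew(n_mut, skew_shape)
    e <- matrix(rskew(n_mut * n_conf, skew_shape), n_mut, n_conf)
    z <- sqrt(rho) * u + sqrt(1 - rho) * e
    dG <- location + scale * z
    wt_col <- wt[site]
    tibble::tibble(
      site = rep(site, times = n_conf),
      wt = rep(wt_col, times = n_conf),
      mut = rep(mut, times = n_conf),
      conformation = rep(conformations, each = n_mut),
      dG = as.numeric(dG)
    )
  })
}

#' Simulate within-conformation pair couplings
#'
#' Draws interaction energies `ddG` for a random subset of cross-site
#' mutation pairs, normally distributed per conformation. The default mean
#' and standard deviation (9.3 and 9.8 kcal/mol) match the statistics of
#' structure-based coupling calculations on S100A4 mutant pairs.
#'
#' @inheritParams validate_ddg_table
#' @param mean,sd Mean and standard deviation of `ddG`, kcal/mol.
#' @param fraction Fraction of cross-site pairs that receive a coupling.
#' @param conformations Conformations to couple; defaults to every
#'   conformation in the table.
#' @param seed Integer seed (reproducible; RNG stream untouched).
#' @return A coupling tibble (`site_a`, `wt_a`, `mut_a`, `site_b`, `wt_b`,
#'   `mut_b`, `conformation`, `ddG`) in the format [run_dms()] and
#'   [read_coupling_table()] use.
#' @export
simulate_couplings <- function(ddg_table, mean = 9.3, sd = 9.8,
                               fraction = 1, conformations = NULL,
                               seed = NULL) {
  validate_ddg_table(ddg_table)
  if (!is.numeric(sd) || sd < 0) {
    abort_invalid_parameter("`sd` must be non-negative.")
  }
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    abort_invalid_parameter("`fraction` must lie in [0, 1].")
  }
  conformations <- conformations %||% unique(ddg_table$conformation)
  prs <- enumerate_mutation_pairs(ddg_table)
  idx <- mutation_index(ddg_table)
  n_take <- round(fraction * nrow(prs))
  if (n_take == 0) {
    return(tibble::tibble(
      site_a = integer(), wt_a = character(), mut_a = character(),
      site_b = integer(), wt_b = character(), mut_b = character(),
      conformation = character(), ddG = numeric()
    ))
  }
  with_seed(seed, {
    take <- sort(sample.int(nrow(prs), n_take))
    sub <- prs[take, , drop = FALSE]
    n_conf <- length(conformations)
    wt_of <- setNames(idx$wt, idx$id)
    mut_of <- setNames(idx$mut, idx$id)
    tibble::tibble(
      site_a = rep(sub$site_a, each = n_conf),
      wt_a = rep(unname(wt_of[sub$mut_a]), each = n_conf),
      mut_a = rep(unname(mut_of[sub$mut_a]), each = n_conf),
      site_b = rep(sub$site_b, each = n_conf),
      wt_b = rep(unname(wt_of[sub$mut_b]), each = n_conf),
      mut_b = rep(unname(mut_of[sub$mut_b]), each = n_conf),
      conformation = rep(conformations, times = nrow(sub)),
      ddG = rnorm(nrow(sub) * n_conf, mean = mean, sd = sd)
    )
  })
}

#' Simulate a random ensemble with random mutational effects
#'
#' Fixture factory for property checks: a random ensemble with one active
#' conformation and `n_conformations - 1` inactive ones, with uniform
#' baseline energies, plus a set of mutations with uniform per-conformation
#' effects.
#'
#' @param n_conformations Total number of conformations (>= 2).
#' @param energy_range Range of baseline energies, kcal/mol.
#' @param n_mutations Number of mutations to draw effects for.
#' @param effect_range Range of per-conformation effects, kcal/mol.
#' @inheritParams define_ensemble
#' @param seed Integer seed.
#' @return List with elements `ensemble` (an `ens_def`) and `effects`
#'   (named list of per-conformation effect vectors `m1`, `m2`, ...).
#' @examples
#' fx <- simulate_random_ensemble(4, seed = 11)
#' mutant_cycle(fx$ensemble, fx$effects$m1, fx$effects$m2)$epsilon
#' @export
simulate_random_ensemble <- function(n_conformations,
                                     energy_range = c(-3, 3),
                                     n_mutations = 2,
                                     effect_range = c(-5, 5),
                                     temperature = DEFAULT_TEMPERATURE,
                                     seed = NULL) {
  if (!is.numeric(n_conformations) || length(n_conformations) != 1 ||
      n_conformations < 2) {
    abort_invalid_parameter("`n_conformations` must be an integer >= 2.")
  }
  n_conformations <- as.integer(n_conformations)
  with_seed(seed, {
    labs <- paste0("c", seq_len(n_conformations))
    ens <- define_ensemble(
      conformations = labs,
      G0 = runif(n_conformations, energy_range[1], energy_range[2]),
      active = labs[1],
      temperature = temperature
    )
    effects <- lapply(seq_len(n_mutations), function(m) {
      setNames(runif(n_conformations, effect_range[1], effect_range[2]),
               labs)
    })
    names(effects) <- paste0("m", seq_len(n_mutations))
    list(ensemble = ens, effects = effects)
  })
}
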