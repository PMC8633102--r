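# Independent brute-force oracle for the thermodynamic quantities, written
# directly from the defining formulas with no numerical stabilisation. Only
# valid on well-scaled energies, which is all the oracle comparisons use.

R_ORACLE <- 1.9872e-3

oracle_avg <- function(G, temperature = 298, R = R_ORACLE) {
  rt <- R * temperature
  -rt * log(sum(exp(-G / rt)))
}

oracle_dgobs <- function(active, inactive, temperature = 298) {
  oracle_avg(active, temperature) - oracle_avg(inactive, temperature)
}

# Four-genotype mutant-cycle epsilon straight from the double difference of
# observables. G0/effects are split into active and inactive parts.
oracle_epsilon <- function(G0_act, G0_inact, da_act, da_inact,
                           db_act, db_inact, temperature = 298) {
  dg <- function(sa, sb) {
    oracle_dgobs(G0_act + sa * da_act + sb * db_act,
                 G0_inact + sa * da_inact + sb * db_inact,
                 temperature)
  }
  (dg(1, 1) - dg(0, 1)) - (dg(1, 0) - dg(0, 0))
}

# Random mutant-cycle scenario on an n-conformation ensemble (one active),
# effects uniform in [-5, 5] kcal/mol.
random_cycle_case <- function(n_conf, effect_range = c(-5, 5)) {
  list(
    G0 = runif(n_conf, -3, 3),
    da = runif(n_conf, effect_range[1], effect_range[2]),
    db = runif(n_conf, effect_range[1], effect_range[2])
  )
}

# Package-side epsilon for the same scenario, through the generic
# object-based route.
package_cycle <- function(case, temperature = 298, ...) {
  n <- length(case$G0)
  labs <- paste0("c", seq_len(n))
  ens <- define_ensemble(labs, case$G0, active = labs[1],
                         temperature = temperature)
  mutant_cycle(ens,
               setNames(case$da, labs),
               setNames(case$db, labs), ...)
}
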