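#' Tidiers for mutant cycles, genotype cubes and DMS runs
#'
#' [tidy()] returns the genotype- or pair-level table of a fitted object;
#' [glance()] returns a one-row summary.
#'
#' @param x A `mutant_cycle`, `epistasis_cube`, `dms_result` or
#'   `dms_summary` object.
#' @param ... Ignored.
#' @return A tibble.
#' @name epiensemble-tidiers
NULL

#' @rdname epiensemble-tidiers
#' @export
tidy.mutant_cycle <- function(x, ...) {
  tibble::tibble(
    genotype = names(x$dg_obs),
    dg_obs = as.numeric(x$dg_obs)
  )
}

#' @rdname epiensemble-tidiers
#' @export
glance.mutant_cycle <- function(x, ...) {
  tibble::tibble(
    epsilon = x$epsilon,
    epsilon_reduced = x$epsilon_reduced,
    eclass = x$eclass,
    effect_a_in_ab = x$effects[["a_in_ab"]],
    effect_a_in_aB = x$effects[["a_in_aB"]],
    effect_b_in_ab = x$effects[["b_in_ab"]],
    effect_b_in_Ab = x$effects[["b_in_Ab"]],
    cutoff = x$cutoff,
    temperature = x$temperature
  )
}

#' @rdname epiensemble-tidiers
#' @export
tidy.epistasis_cube <- function(x, ...) {
  tibble::tibble(
    genotype = names(x$dg_obs),
    dg_obs = as.numeric(x$dg_obs)
  )
}

#' @rdname epiensemble-tidiers
#' @export
glance.epistasis_cube <- function(x, ...) {
  tibble::tibble(
    eps_ab_in_c = x$eps_ab_in_c,
    eps_ab_in_C = x$eps_ab_in_C,
    eps3 = x$eps3
  )
}

#' @rdname epiensemble-tidiers
#' @export
tidy.dms_result <- function(x, ...) {
  x$pairs
}

#' @rdname epiensemble-tidiers
#' @export
glance.dms_result <- function(x, ...) {
  s <- x$summary
  frac_at <- function(co) {
    i <- which(abs(s$fraction_ge$cutoff - co) < 1e-9)
    if (length(i) == 0) NA_real_ else s$fraction_ge$fraction[i[1]]
  }
  tibble::tibble(
    n_pairs = s$n_pairs,
    frac_ge_0.6 = frac_at(0.6),
    frac_ge_2.0 = frac_at(2.0),
    switch_fraction = s$switch_fraction,
    mean_abs_peak = mean(abs(x$pairs$epsilon_peak))
  )
}

#' @rdname epiensemble-tidiers
#' @export
tidy.dms_summary <- function(x, ...) {
  x$sweep
}

#' @rdname epiensemble-tidiers
#' @export
glance.dms_summary <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs,
    switch_cutoff = x$switch_cutoff,
    switch_fraction = x$switch_fraction
  )
}
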