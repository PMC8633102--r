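#' Validate a per-conformation mutational effect (ddG) table
#'
#' A ddG table is tidy: one row per mutation and conformation, with columns
#' `site` (1-based integer position), `wt` and `mut` (one-letter residues),
#' `conformation` and `dG` (kcal/mol). Checks: required columns, `wt != mut`,
#' a single consistent wild-type per site, no duplicated
#' (site, wt, mut, conformation) rows, and (optionally) that every mutation
#' covers a required conformation set.
#'
#' @param ddg_table Data frame to validate.
#' @param conformations Optional character vector every mutation must cover.
#' @return The table, invisibly, if valid; otherwise an error condition of
#'   class `epiensemble_error_*` describing the offenders.
#' @export
validate_ddg_table <- function(ddg_table, conformations = NULL) {
  need <- c("site", "wt", "mut", "conformation", "dG")
  if (!is.data.frame(ddg_table) || !all(need %in% names(ddg_table))) {
    abort_invalid_input(paste0(
      "a ddG table needs columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(ddg_table) == 0) {
    abort_invalid_input("ddG table is empty.")
  }
  if (!is.numeric(ddg_table$dG) || any(!is.finite(ddg_table$dG))) {
    abort_invalid_input("`dG` must be finite numeric (kcal/mol).")
  }
  if (any(ddg_table$wt == ddg_table$mut)) {
    abort_invalid_input("rows with wt == mut are not mutations.")
  }
  key <- paste(ddg_table$site, ddg_table$wt, ddg_table$mut,
               ddg_table$conformation, sep = "|")
  if (anyDuplicated(key) > 0) {
    dup <- unique(key[duplicated(key)])
    abort_invalid_input(paste0(
      "duplicated (site, wt, mut, conformation) rows, e.g.: ",
      paste(head(dup, 3), collapse = "; ")))
  }
  wt_per_site <- tapply(ddg_table$wt, ddg_table$site,
                        function(x) length(unique(x)))
  if (any(wt_per_site > 1)) {
    abort_invalid_input(paste0(
      "inconsistent wild-type residue at site(s): ",
      paste(head(names(wt_per_site)[wt_per_site > 1], 5), collapse = ", ")))
  }
  if (!is.null(conformations)) {
    id <- mutation_label(ddg_table$wt, ddg_table$site, ddg_table$mut)
    cover <- tapply(ddg_table$conformation, id,
                    function(x) all(conformations %in% x))
    if (any(!cover)) {
      abort_missing_data(paste0(
        "mutation(s) missing required conformations (",
        paste(conformations, collapse = ", "), "): ",
        paste(head(names(cover)[!cover], 5), collapse = ", ")))
    }
  }
  invisible(ddg_table)
}

# Unordered cross-site pair indices over a site vector, i < j in the given
# order. Same-site pairs (chemically impossible double mutants) are dropped.
pair_indices <- function(site) {
  n <- length(site)
  if (n < 2) {
    abort_invalid_input("need at least two mutations to form pairs.")
  }
  ia <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
  ib <- sequence(rev(seq_len(n - 1L)), from = seq_len(n)[-1L])
  keep <- site[ia] != site[ib]
  list(ia = ia[keep], ib = ib[keep])
}

# Mutation index of a ddG table: one row per mutation, sorted by site then
# mutant residue (the deterministic enumeration order used throughout).
mutation_index <- function(ddg_table) {
  idx <- unique(ddg_table[c("site", "wt", "mut")])
  idx <- idx[order(idx$site, idx$mut), , drop = FALSE]
  idx$id <- mutation_label(idx$wt, idx$site, idx$mut)
  tibble::as_tibble(idx)
}

#' Enumerate all cross-site mutation pairs of a ddG table
#'
#' All unordered pairs of mutations at distinct sites, in deterministic
#' order (by site, then mutant residue). Same-site pairs are excluded: two
#' substitutions cannot occupy one position.
#'
#' @inheritParams validate_ddg_table
#' @return Tibble with columns `mut_a`, `mut_b`, `site_a`, `site_b`.
#' @examples
#' tbl <- simulate_ddg_table(n_sites = 3, alphabet = c("A", "V"), seed = 1)
#' nrow(enumerate_mutation_pairs(tbl))
#' @export
enumerate_mutation_pairs <- function(ddg_table) {
  validate_ddg_table(ddg_table)
  idx <- mutation_index(ddg_table)
  if (length(unique(idx$site)) < 2) {
    abort_invalid_input("need mutations at >= 2 distinct sites to form pairs.")
  }
  p <- pair_indices(idx$site)
  tibble::tibble(
    mut_a = idx$id[p$ia], mut_b = idx$id[p$ib],
    site_a = idx$site[p$ia], site_b = idx$site[p$ib]
  )
}

# Boltzmann-average across the columns of an energy matrix, rowwise.
row_lse <- function(E, rt) {
  if (is.null(dim(E))) {
    return(E)
  }
  if (ncol(E) == 1L) {
    return(E[, 1L])
  }
  m <- E[, 1L]
  for (cc in 2:ncol(E)) m <- pmin(m, E[, cc])
  s <- exp(-(E[, 1L] - m) / rt)
  for (cc in 2:ncol(E)) s <- s + exp(-(E[, cc] - m) / rt)
  m - rt * log(s)
}

prepare_couplings <- function(couplings, idx, labs, active) {
  if (is.null(couplings) || nrow(couplings) == 0) {
    return(NULL)
  }
  need <- c("site_a", "wt_a", "mut_a", "site_b", "wt_b", "mut_b",
            "conformation", "ddG")
  if (!all(need %in% names(couplings))) {
    abort_invalid_input(paste0(
      "a coupling table needs columns: ", paste(need, collapse = ", ")))
  }
  la <- mutation_label(couplings$wt_a, couplings$site_a, couplings$mut_a)
  lb <- mutation_label(couplings$wt_b, couplings$site_b, couplings$mut_b)
  ka <- match(la, idx$id)
  kb <- match(lb, idx$id)
  known <- !is.na(ka) & !is.na(kb)
  if (any(!known)) {
    warn(sprintf(
      "dropping %d coupling row(s) referencing mutations absent from the ddG table",
      sum(!known)))
  }
  keep <- known & !(couplings$conformation %in% active)
  if (!any(keep)) {
    return(NULL)
  }
  n <- length(idx$id)
  lo <- pmin(ka[keep], kb[keep])
  hi <- pmax(ka[keep], kb[keep])
  list(
    pair_key = (lo - 1) * n + hi,
    conf = match(couplings$conformation[keep], labs),
    ddG = couplings$ddG[keep]
  )
}

#' Virtual deep mutational scan of pairwise ensemble epistasis
#'
#' For every cross-site pair of mutations in a per-conformation effect
#' table, titrates ensemble epistasis over a grid of effector chemical
#' potentials and records the peak, its class, and the number of
#' type switches along the titration. Within each conformation, effects are
#' treated as additive (plus optional pair couplings), so the epistasis
#' measured is the ensemble's own.
#'
#' Epistasis is computed on the reduced (inactive sub-ensemble) form, which
#' the active conformation provably cannot enter; classification, however,
#' uses each mutation's background-dependent effect on the full observable.
#' Coupling rows on active conformations are therefore inert and dropped.
#' The engine is vectorised over pairs and processes them in chunks, so
#' memory stays bounded in the number of pairs per chunk.
#'
#' @inheritParams validate_ddg_table
#' @inheritParams titrate_epistasis
#' @param cutoffs Cutoff sweep for the summary (kcal/mol); the default
#'   0..3 by 0.1 includes the thermal-fluctuation scale 0.6 and the strong
#'   threshold 2.0.
#' @param couplings Optional coupling table with columns `site_a`, `wt_a`,
#'   `mut_a`, `site_b`, `wt_b`, `mut_b`, `conformation`, `ddG` (see
#'   [read_coupling_table()]).
#' @param keep_curves If `TRUE`, retain the full per-pair epsilon curves
#'   (a pairs-by-grid matrix); off by default to bound memory on large runs.
#' @param chunk_size Number of pairs processed per vectorised block.
#' @return An object of class `"dms_result"`: list with `pairs` (tibble:
#'   `mut_a`, `mut_b`, `site_a`, `site_b`, `mu_peak`, `epsilon_peak`,
#'   `class_peak`, `class_raw`, `n_switches`), `summary` (a
#'   [summarize_dms()] result), and optionally `curves`. Has [tidy()] and
#'   [glance()] methods.
#' @examples
#' tbl <- simulate_ddg_table(n_sites = 4, alphabet = c("A", "V", "L"),
#'                           seed = 7)
#' res <- run_dms(tbl, mu_grid = seq(0, 5, by = 0.5))
#' glance(res)
#' @export
run_dms <- function(ddg_table, ensemble = s100a4_ensemble(), ligand = "ca",
                    mu_grid = seq(0, 5, by = 0.1), cutoff = 0.6,
                    cutoffs = seq(0, 3, by = 0.1), couplings = NULL,
                    mu_base = NULL, sign_tol = 1e-6,
                    require_effect_cutoff = FALSE, keep_curves = FALSE,
                    chunk_size = 200000L) {
  check_ensemble(ensemble)
  labs <- ensemble$conformation
  validate_ddg_table(ddg_table, conformations = labs)
  if (length(mu_grid) == 0) {
    abort_invalid_input("`mu_grid` must be non-empty.")
  }
  if (is.unsorted(mu_grid, strictly = TRUE)) {
    abort_invalid_input("`mu_grid` must be strictly increasing.")
  }
  rt <- ens_rt(ensemble)
  act <- which(ensemble$role == "active")
  inact <- which(ensemble$role == "inactive")

  idx <- mutation_index(ddg_table)
  if (length(unique(idx$site)) < 2) {
    abort_invalid_input("need mutations at >= 2 distinct sites.")
  }
  n_mut <- nrow(idx)
  M <- matrix(NA_real_, n_mut, length(labs),
              dimnames = list(idx$id, labs))
  rid <- match(mutation_label(ddg_table$wt, ddg_table$site, ddg_table$mut),
               idx$id)
  M[cbind(rid, match(ddg_table$conformation, labs))] <- ddg_table$dG

  pp <- pair_indices(idx$site)
  n_pairs <- length(pp$ia)
  cpl <- prepare_couplings(couplings, idx, labs, labs[act])

  # per-grid-point baselines
  n_grid <- length(mu_grid)
  baseL <- lapply(mu_grid, function(m) {
    mu <- c(setNames(m, ligand), mu_base[setdiff(names(mu_base), ligand)])
    baseline_energies(ensemble, mu)
  })

  best_abs <- rep(-1, n_pairs)
  best_eps <- numeric(n_pairs)
  best_mu <- numeric(n_pairs)
  best_raw <- character(n_pairs)
  n_switch <- integer(n_pairs)
  last_cls <- rep(NA_character_, n_pairs)
  curves <- if (keep_curves) matrix(NA_real_, n_pairs, n_grid) else NULL

  chunk_starts <- seq.int(1L, n_pairs, by = as.integer(chunk_size))
  for (cs in chunk_starts) {
    ce <- min(cs + chunk_size - 1L, n_pairs)
    sel <- cs:ce
    ia <- pp$ia[sel]
    ib <- pp$ib[sel]
    cadd <- NULL
    if (!is.null(cpl)) {
      key <- (pmin(ia, ib) - 1) * n_mut + pmax(ia, ib)
      hit <- match(cpl$pair_key, key)
      if (any(!is.na(hit))) {
        cadd <- matrix(0, length(sel), length(labs))
        ok <- !is.na(hit)
        cadd[cbind(hit[ok], cpl$conf[ok])] <-
          cadd[cbind(hit[ok], cpl$conf[ok])] + cpl$ddG[ok]
      }
    }
    ch_abs <- rep(-1, length(sel))
    ch_eps <- numeric(length(sel))
    ch_mu <- numeric(length(sel))
    ch_raw <- character(length(sel))
    ch_switch <- integer(length(sel))
    ch_last <- rep(NA_character_, length(sel))

    for (t in seq_len(n_grid)) {
      base <- baseL[[t]]
      EY1 <- M[, inact, drop = FALSE] +
        rep(base[inact], each = n_mut)
      gY1 <- row_lse(EY1, rt)
      EX1 <- M[, act, drop = FALSE] + rep(base[act], each = n_mut)
      gX1 <- row_lse(EX1, rt)
      dg1 <- gX1 - gY1
      gY0 <- ensemble_avg_energy(base[inact], 1, rt)
      gX0 <- ensemble_avg_energy(base[act], 1, rt)
      dg0 <- gX0 - gY0

      EY2 <- M[ia, inact, drop = FALSE] + M[ib, inact, drop = FALSE] +
        rep(base[inact], each = length(sel))
      if (!is.null(cadd)) {
        EY2 <- EY2 + cadd[, inact, drop = FALSE]
      }
      gY2 <- row_lse(EY2, rt)
      EX2 <- M[ia, act, drop = FALSE] + M[ib, act, drop = FALSE] +
        rep(base[act], each = length(sel))
      gX2 <- row_lse(EX2, rt)
      dg2 <- gX2 - gY2

      eps <- -((gY2 - gY1[ib]) - (gY1[ia] - gY0))
      # cutoff-free class; the stricter convention raises the minimum
      # effect magnitude for a sign call to the run cutoff
      raw <- classify_epistasis(
        eps,
        effect_a_in_ab = dg1[ia] - dg0,
        effect_a_in_aB = dg2 - dg1[ib],
        effect_b_in_ab = dg1[ib] - dg0,
        effect_b_in_Ab = dg2 - dg1[ia],
        cutoff = 0,
        sign_tol = if (require_effect_cutoff) max(sign_tol, cutoff)
                   else sign_tol,
        require_effect_cutoff = FALSE
      )
      if (keep_curves) {
        curves[sel, t] <- eps
      }

      imp <- abs(eps) > ch_abs
      if (any(imp)) {
        ch_abs[imp] <- abs(eps[imp])
        ch_eps[imp] <- eps[imp]
        ch_mu[imp] <- mu_grid[t]
        ch_raw[imp] <- raw[imp]
      }
      supra <- abs(eps) >= cutoff
      sw <- supra & !is.na(ch_last) & ch_last != raw
      ch_switch[sw] <- ch_switch[sw] + 1L
      ch_last[supra] <- raw[supra]
    }
    best_abs[sel] <- ch_abs
    best_eps[sel] <- ch_eps
    best_mu[sel] <- ch_mu
    best_raw[sel] <- ch_raw
    n_switch[sel] <- ch_switch
  }

  pairs <- tibble::tibble(
    mut_a = idx$id[pp$ia], mut_b = idx$id[pp$ib],
    site_a = idx$site[pp$ia], site_b = idx$site[pp$ib],
    mu_peak = best_mu,
    epsilon_peak = best_eps,
    class_peak = ifelse(abs(best_eps) >= cutoff, best_raw, "none"),
    class_raw = best_raw,
    n_switches = n_switch
  )
  out <- list(
    pairs = pairs,
    summary = summarize_dms(pairs, cutoffs = cutoffs,
                            switch_cutoff = cutoff),
    mu_grid = mu_grid,
    ligand = ligand,
    cutoff = cutoff
  )
  if (keep_curves) {
    out$curves <- curves
  }
  structure(out, class = "dms_result")
}

#' @export
print.dms_result <- function(x, ...) {
  cat(sprintf("# Virtual deep mutational scan: %d mutation pairs, %d-point grid\n",
              nrow(x$pairs), length(x$mu_grid)))
  print(x$summary)
  invisible(x)
}

#' Summarise a deep-mutational-scan run
#'
#' Aggregates per-pair peak epistasis into the standard summaries: the
#' fraction of pairs whose peak magnitude reaches each cutoff in a sweep,
#' the fractional contribution of each epistatic class as a function of that
#' cutoff (classes + non-epistatic always sum to 1), the fraction of
#' supra-cutoff pairs that switch type at least once along the titration,
#' and a histogram of the signed peak epistasis.
#'
#' @param pairs A per-pair results tibble (from [run_dms()], columns
#'   `epsilon_peak`, `class_raw`, `n_switches`).
#' @param cutoffs Numeric cutoff sweep, kcal/mol.
#' @param switch_cutoff Cutoff used for the switch fraction, kcal/mol.
#' @param hist_breaks Suggested number of histogram bins.
#' @return An object of class `"dms_summary"`: list with `n_pairs`,
#'   `sweep` (long tibble: `cutoff`, `eclass`, `fraction`), `fraction_ge`
#'   (tibble: `cutoff`, `fraction`), `switch_fraction`, `switch_cutoff` and
#'   `histogram` (tibble: `lower`, `upper`, `mid`, `count`).
#' @export
summarize_dms <- function(pairs, cutoffs = seq(0, 3, by = 0.1),
                          switch_cutoff = 0.6, hist_breaks = 40) {
  need <- c("epsilon_peak", "class_raw", "n_switches")
  if (!is.data.frame(pairs) || !all(need %in% names(pairs))) {
    abort_invalid_input(paste0(
      "`pairs` needs columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(pairs) == 0) {
    abort_invalid_input("`pairs` is empty.")
  }
  if (length(cutoffs) == 0 || any(cutoffs < 0)) {
    abort_invalid_parameter("`cutoffs` must be non-negative.")
  }
  a <- abs(pairs$epsilon_peak)
  cls <- pairs$class_raw
  sweep <- purrr::map_dfr(as.numeric(cutoffs), function(co) {
    supra <- a >= co
    tibble::tibble(
      cutoff = co,
      eclass = epistasis_classes(),
      fraction = c(
        mean(!supra),
        mean(supra & cls == "magnitude"),
        mean(supra & cls == "sign"),
        mean(supra & cls == "reciprocal_sign")
      )
    )
  })
  fraction_ge <- tibble::tibble(
    cutoff = as.numeric(cutoffs),
    fraction = vapply(cutoffs, function(co) mean(a >= co), numeric(1))
  )
  supra <- a >= switch_cutoff
  switch_fraction <- if (any(supra)) {
    mean(pairs$n_switches[supra] >= 1)
  } else {
    NA_real_
  }
  h <- graphics::hist(pairs$epsilon_peak, breaks = hist_breaks, plot = FALSE)
  histogram <- tibble::tibble(
    lower = h$breaks[-length(h$breaks)],
    upper = h$breaks[-1],
    mid = h$mids,
    count = h$counts
  )
  structure(
    list(
      n_pairs = nrow(pairs),
      sweep = sweep,
      fraction_ge = fraction_ge,
      switch_cutoff = switch_cutoff,
      switch_fraction = switch_fraction,
      histogram = histogram
    ),
    class = "dms_summary"
  )
}

#' @export
print.dms_summary <- function(x, ...) {
  at <- function(co) {
    s <- x$sweep[abs(x$sweep$cutoff - co) < 1e-9, ]
    if (nrow(s) == 0) return(NULL)
    cat(sprintf(
      "  at %.1f kcal/mol: %.1f%% epistatic (magnitude %.1f%%, sign %.1f%%, reciprocal sign %.1f%%)\n",
      co, 100 * (1 - s$fraction[s$eclass == "none"]),
      100 * s$fraction[s$eclass == "magnitude"],
      100 * s$fraction[s$eclass == "sign"],
      100 * s$fraction[s$eclass == "reciprocal_sign"]))
  }
  cat(sprintf("# DMS summary over %d pairs\n", x$n_pairs))
  at(0.6)
  at(2.0)
  if (!is.na(x$switch_fraction)) {
    cat(sprintf(
      "  %.1f%% of pairs above %.1f kcal/mol switch epistatic type with effector\n",
      100 * x$switch_fraction, x$switch_cutoff))
  }
  invisible(x)
}
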