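small_table <- function(seed = 101, n_sites = 4,
                        alphabet = c("A", "V", "L", "K")) {
  simulate_ddg_table(n_sites = n_sites, alphabet = alphabet, seed = seed)
}

test_that("ddG table validation catches duplicates, wt conflicts and gaps", {
  tbl <- small_table()
  expect_invisible(validate_ddg_table(tbl))
  expect_error(validate_ddg_table(rbind(tbl, tbl[1, ])),
               class = "epiensemble_error_invalid_input")
  bad <- tbl
  bad$wt[1] <- setdiff(c("A", "V", "L", "K"), bad$wt[1])[1]
  expect_error(validate_ddg_table(bad),
               class = "epiensemble_error_invalid_input")
  expect_error(validate_ddg_table(tbl[tbl$conformation != "apo", ],
                                  conformations = c("capep", "ca", "apo")),
               class = "epiensemble_error_missing_data")
  same <- tbl
  same$mut <- same$wt
  expect_error(validate_ddg_table(same),
               class = "epiensemble_error_invalid_input")
})

test_that("pair enumeration covers exactly the cross-site pairs in stable order", {
  # 2 sites x 1 mutation each -> 1 pair
  t1 <- tibble::tibble(
    site = rep(1:2, each = 1), wt = c("A", "G"), mut = c("V", "W"),
    conformation = "x", dG = 0)
  t1 <- tidyr::expand_grid(t1[, 1:3],
                           conformation = c("x", "y"))
  t1$dG <- 0
  expect_identical(nrow(enumerate_mutation_pairs(t1)), 1L)

  # 2 sites x 19 mutations -> 19^2 cross-site pairs
  t19 <- simulate_ddg_table(n_sites = 2, seed = 5)
  expect_identical(nrow(enumerate_mutation_pairs(t19)), 361L)

  # 3 sites x 2 mutations -> brute-force count
  t3 <- simulate_ddg_table(n_sites = 3, alphabet = c("A", "V", "L"),
                           seed = 6)
  prs <- enumerate_mutation_pairs(t3)
  idx <- unique(t3[c("site", "wt", "mut")])
  brute <- 0L
  for (i in seq_len(nrow(idx) - 1)) {
    for (j in (i + 1):nrow(idx)) {
      if (idx$site[i] != idx$site[j]) brute <- brute + 1L
    }
  }
  expect_identical(nrow(prs), brute)
  expect_identical(nrow(prs), 12L)
  # deterministic order: by site then mutant residue
  expect_true(!is.unsorted(prs$site_a))
  expect_true(all(prs$site_a < prs$site_b))

  single <- t3[t3$site == 1, ]
  expect_error(enumerate_mutation_pairs(single),
               class = "epiensemble_error_invalid_input")
})

test_that("run_dms matches the scalar titration oracle pair by pair", {
  tbl <- small_table(seed = 31)
  grid <- seq(0, 5, 0.25)
  res <- run_dms(tbl, mu_grid = grid, cutoff = 0.2)
  eff <- effect_list(tbl)
  ens <- s100a4_ensemble()
  set.seed(1)
  rows <- sample(nrow(res$pairs), 50)
  for (i in rows) {
    crv <- titrate_epistasis(ens, eff[[res$pairs$mut_a[i]]],
                             eff[[res$pairs$mut_b[i]]],
                             mu_grid = grid, cutoff = 0.2,
                             populations = FALSE)
    pk <- peak_epistasis(crv)
    expect_equal(res$pairs$epsilon_peak[i], pk$epsilon_peak,
                 tolerance = 1e-9)
    expect_equal(res$pairs$mu_peak[i], pk$mu_peak)
    expect_identical(res$pairs$class_peak[i], pk$class_peak)
    expect_identical(res$pairs$n_switches[i], count_type_switches(crv))
  }
})

test_that("run_dms honours both necessary conditions", {
  tbl <- small_table(seed = 41)
  # equalise the inactive-conformation effects: all epsilon exactly zero
  uni <- tbl
  uni$dG[uni$conformation == "apo"] <-
    uni$dG[uni$conformation == "ca"][match(
      mutation_label(uni$wt, uni$site, uni$mut)[uni$conformation == "apo"],
      mutation_label(uni$wt, uni$site, uni$mut)[uni$conformation == "ca"])]
  res <- run_dms(uni, mu_grid = seq(0, 5, 0.5))
  expect_true(all(abs(res$pairs$epsilon_peak) < 1e-12))
  expect_true(all(res$pairs$class_peak == "none"))
  sweep <- res$summary$sweep
  expect_equal(sweep$fraction[sweep$eclass == "none" & sweep$cutoff > 0],
               rep(1, sum(sweep$eclass == "none" & sweep$cutoff > 0)))

  # single inactive conformation in the ensemble: all epsilon zero
  two <- define_ensemble(c("on", "off"), c(8, 0), active = "on",
                         stoich = list(on = c(ca = 4)))
  tbl2 <- simulate_ddg_table(n_sites = 3, alphabet = c("A", "V", "L"),
                             conformations = c("on", "off"), seed = 43)
  res2 <- run_dms(tbl2, ensemble = two, mu_grid = seq(0, 4, 0.5))
  expect_true(all(abs(res2$pairs$epsilon_peak) < 1e-12))

  # conformation mismatch errors
  expect_error(run_dms(tbl2, mu_grid = seq(0, 4, 0.5)),
               class = "epiensemble_error_missing_data")
})

test_that("chunked and whole-run execution give identical results", {
  tbl <- small_table(seed = 51)
  grid <- seq(0, 5, 0.5)
  whole <- run_dms(tbl, mu_grid = grid)
  chunked <- run_dms(tbl, mu_grid = grid, chunk_size = 7L)
  expect_equal(chunked$pairs, whole$pairs)
  expect_equal(chunked$summary$sweep, whole$summary$sweep)
})

test_that("shifting the inactive baseline translates peaks without changing magnitude", {
  tbl <- small_table(seed = 61)
  grid <- seq(-2, 8, 0.1)
  r1 <- run_dms(tbl, ensemble = s100a4_ensemble(G_ca = 10), mu_grid = grid)
  r2 <- run_dms(tbl, ensemble = s100a4_ensemble(G_ca = 12), mu_grid = grid)
  expect_equal(abs(r2$pairs$epsilon_peak), abs(r1$pairs$epsilon_peak),
               tolerance = 1e-6)
  moved <- abs(r1$pairs$epsilon_peak) > 1e-6 &
    r1$pairs$mu_peak > min(grid) & r2$pairs$mu_peak < max(grid)
  expect_true(any(moved))
  expect_equal(r2$pairs$mu_peak[moved] - r1$pairs$mu_peak[moved],
               rep(0.5, sum(moved)), tolerance = 1e-9)
})

test_that("couplings on inactive conformations change epsilon; active ones are inert", {
  tbl <- small_table(seed = 71)
  grid <- seq(0, 5, 0.5)
  base <- run_dms(tbl, mu_grid = grid)
  cpl <- simulate_couplings(tbl, mean = 2, sd = 1, fraction = 0.5,
                            conformations = c("ca", "apo"), seed = 72)
  with_cpl <- run_dms(tbl, mu_grid = grid, couplings = cpl)
  expect_false(isTRUE(all.equal(with_cpl$pairs$epsilon_peak,
                                base$pairs$epsilon_peak)))
  cpl_act <- simulate_couplings(tbl, mean = 2, sd = 1, fraction = 0.5,
                                conformations = "capep", seed = 73)
  inert <- run_dms(tbl, mu_grid = grid, couplings = cpl_act)
  expect_equal(inert$pairs$epsilon_peak, base$pairs$epsilon_peak,
               tolerance = 1e-12)
  # coupling rows for unknown mutations warn and are dropped
  stray <- cpl[1, ]
  stray$site_a <- 999L
  expect_warning(run_dms(tbl, mu_grid = grid, couplings = stray),
                 "coupling")
})

test_that("summaries recount correctly and behave monotonically", {
  tbl <- small_table(seed = 81)
  res <- run_dms(tbl, mu_grid = seq(0, 5, 0.25), cutoff = 0.3)
  s <- res$summary
  expect_identical(s$n_pairs, nrow(res$pairs))

  # brute-force recount of every reported fraction
  a <- abs(res$pairs$epsilon_peak)
  for (co in c(0, 0.3, 0.6, 1.0)) {
    i <- which(abs(s$fraction_ge$cutoff - co) < 1e-9)
    expect_equal(s$fraction_ge$fraction[i], sum(a >= co) / length(a))
    for (cl in c("magnitude", "sign", "reciprocal_sign")) {
      j <- which(abs(s$sweep$cutoff - co) < 1e-9 & s$sweep$eclass == cl)
      expect_equal(s$sweep$fraction[j],
                   sum(a >= co & res$pairs$class_raw == cl) / length(a))
    }
  }
  # class fractions + none sum to one at every cutoff
  tot <- tapply(s$sweep$fraction, s$sweep$cutoff, sum)
  expect_equal(as.numeric(tot), rep(1, length(tot)), tolerance = 1e-12)
  # fraction >= cutoff is non-increasing; fraction at 0 is 1
  expect_true(all(diff(s$fraction_ge$fraction) <= 1e-12))
  expect_equal(s$fraction_ge$fraction[1], 1)
  # switch fraction recount
  supra <- a >= 0.3
  expect_equal(s$switch_fraction,
               mean(res$pairs$n_switches[supra] >= 1))
  # histogram covers every pair
  expect_identical(sum(s$histogram$count), nrow(res$pairs))
  expect_error(summarize_dms(res$pairs[0, ]),
               class = "epiensemble_error_invalid_input")
})

test_that("kept curves reproduce the reported peaks", {
  tbl <- small_table(seed = 91, n_sites = 3, alphabet = c("A", "V"))
  grid <- seq(0, 5, 0.5)
  res <- run_dms(tbl, mu_grid = grid, keep_curves = TRUE)
  expect_identical(dim(res$curves), c(nrow(res$pairs), length(grid)))
  best <- apply(abs(res$curves), 1, max)
  expect_equal(best, abs(res$pairs$epsilon_peak), tolerance = 1e-12)
})
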