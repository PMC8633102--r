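test_that("epistasis_full is the mutant-cycle double difference", {
  expect_equal(epistasis_full(c(ab = 0, Ab = 1, aB = 1, AB = 2)), 0)
  expect_equal(epistasis_full(c(ab = 0, Ab = 1, aB = -1, AB = 5)), 5)
  expect_equal(
    epistasis_full(c(ab = 0, Ab = 0.098044, aB = 0.098044, AB = 0)),
    -0.196088, tolerance = 1e-9)
  # symmetric in the two mutations: swapping Ab and aB changes nothing
  set.seed(3)
  for (rep in 1:20) {
    g <- setNames(runif(4, -3, 3), c("ab", "Ab", "aB", "AB"))
    swapped <- g[c("ab", "aB", "Ab", "AB")]
    names(swapped) <- c("ab", "Ab", "aB", "AB")
    expect_equal(epistasis_full(g), epistasis_full(swapped))
  }
  expect_error(epistasis_full(c(ab = 0, Ab = 1, aB = 1)),
               class = "epiensemble_error_invalid_input")
})

test_that("worked three-conformation scenarios: opposing, uniform, synergistic pairs", {
  ens <- three_state_ensemble()
  a <- c(i = 0, j = 0.35, k = -0.35)

  # opposing differential effects: negative epistasis, reciprocal sign
  cyc <- mutant_cycle(ens, a, c(i = 0, j = -0.35, k = 0.35), cutoff = 0.1)
  expect_equal(cyc$epsilon,
               oracle_epsilon(0, c(0, 0), 0, c(0.35, -0.35),
                              0, c(-0.35, 0.35)),
               tolerance = 1e-12)
  expect_equal(cyc$epsilon, -0.1958324, tolerance = 1e-6)
  expect_identical(cyc$eclass, "reciprocal_sign")

  # uniform second mutation: exactly additive
  cyc0 <- mutant_cycle(ens, a, c(i = 0, j = 0.35, k = 0.35), cutoff = 0.1)
  expect_equal(cyc0$epsilon, 0, tolerance = 1e-12)
  expect_identical(cyc0$eclass, "none")

  # synergistic differential effects: positive epistasis, magnitude
  cyc2 <- mutant_cycle(ens, a, a, cutoff = 0.1)
  expect_equal(cyc2$epsilon, 0.1469153, tolerance = 1e-6)
  expect_identical(cyc2$eclass, "magnitude")

  # single-mutant effects agree across the equivalent differences
  expect_equal(cyc$effects[["a_in_aB"]] - cyc$effects[["a_in_ab"]],
               cyc$epsilon, tolerance = 1e-12)
  expect_equal(cyc$effects[["b_in_Ab"]] - cyc$effects[["b_in_ab"]],
               cyc$epsilon, tolerance = 1e-12)
})

test_that("full-cycle and reduced-form epsilon agree for random ensembles (zero couplings)", {
  set.seed(11)
  for (rep in 1:300) {
    case <- random_cycle_case(sample(3:6, 1))
    cyc <- package_cycle(case)
    expect_equal(cyc$epsilon, cyc$epsilon_reduced, tolerance = 1e-9)
    expect_equal(cyc$epsilon,
                 oracle_epsilon(case$G0[1], case$G0[-1],
                                case$da[1], case$da[-1],
                                case$db[1], case$db[-1]),
                 tolerance = 1e-9)
  }
})

test_that("epsilon vanishes for a single inactive conformation and for uniform inactive effects", {
  set.seed(13)
  for (rep in 1:200) {
    # condition 1: two-state ensemble, any effects
    case <- random_cycle_case(2)
    expect_equal(package_cycle(case)$epsilon, 0, tolerance = 1e-12)

    # condition 2: effects uniform over the inactive sub-ensemble
    # (active-conformation effects arbitrary)
    n <- sample(3:6, 1)
    case <- random_cycle_case(n)
    case$da[-1] <- case$da[2]
    case$db[-1] <- case$db[2]
    expect_equal(package_cycle(case)$epsilon, 0, tolerance = 1e-12)
  }
})

test_that("epsilon is symmetric under mutation exchange and inactive-label permutation", {
  set.seed(17)
  for (rep in 1:50) {
    case <- random_cycle_case(sample(3:6, 1))
    eps <- package_cycle(case)$epsilon
    swapped <- case
    swapped$da <- case$db
    swapped$db <- case$da
    expect_equal(package_cycle(swapped)$epsilon, eps, tolerance = 1e-12)
    perm <- c(1, 1 + sample(length(case$G0) - 1))
    permuted <- list(G0 = case$G0[perm], da = case$da[perm],
                     db = case$db[perm])
    expect_equal(package_cycle(permuted)$epsilon, eps, tolerance = 1e-12)
  }
})

test_that("epsilon vanishes in both temperature limits", {
  set.seed(19)
  for (rep in 1:20) {
    case <- random_cycle_case(sample(3:6, 1))
    # high temperature: all weights equalise; epsilon decays like 1/RT
    hot <- abs(package_cycle(case, temperature = 1e6)$epsilon)
    warm <- abs(package_cycle(case, temperature = 1e4)$epsilon)
    expect_lt(hot, 1e-2)
    expect_lte(hot, warm + 1e-12)
    # low temperature with one conformation the global minimum across all
    # four genotypes: only the deepest well is populated
    case$G0[2] <- -50
    expect_equal(package_cycle(case, temperature = 0.01)$epsilon, 0,
                 tolerance = 1e-9)
  }
})

test_that("within-conformation couplings add epistasis on top of the ensemble part", {
  ens <- three_state_ensemble()
  a <- c(i = 0, j = 0.35, k = -0.35)
  b <- c(i = 0, j = -0.35, k = 0.35)
  base <- mutant_cycle(ens, a, b, cutoff = 0.1)
  cpl <- tibble::tibble(mut_a = "a", mut_b = "b",
                        conformation = c("j", "k"), ddG = c(1.0, 1.0))
  with_cpl <- mutant_cycle(ens, a, b, couplings = cpl, cutoff = 0.1)
  expect_false(isTRUE(all.equal(with_cpl$epsilon, base$epsilon)))
  # a coupling on the active conformation enters the full cycle linearly
  cpl_act <- tibble::tibble(mut_a = "a", mut_b = "b",
                            conformation = "i", ddG = 0.7)
  with_act <- mutant_cycle(ens, a, b, couplings = cpl_act, cutoff = 0.1)
  expect_equal(with_act$epsilon, base$epsilon + 0.7, tolerance = 1e-9)
  # ... and makes the full and reduced forms legitimately differ
  expect_equal(with_act$epsilon_reduced, base$epsilon, tolerance = 1e-9)
})

test_that("classification separates magnitude, sign and reciprocal-sign epistasis", {
  expect_error(classify_epistasis(1, 1, 1, 1, 1, cutoff = -0.1),
               class = "epiensemble_error_invalid_parameter")
  # below cutoff: none, regardless of effects
  expect_identical(
    classify_epistasis(0.05, 1, -1, 1, -1, cutoff = 0.1), "none")
  # both mutations flip sign: reciprocal
  expect_identical(
    classify_epistasis(-0.196, 0.098, -0.098, 0.098, -0.098, cutoff = 0.1),
    "reciprocal_sign")
  # one flips: sign
  expect_identical(
    classify_epistasis(-0.2, 0.098, -0.098, 0.30, 0.10, cutoff = 0.1),
    "sign")
  # none flips: magnitude
  expect_identical(
    classify_epistasis(0.5, 0.3, 0.8, 0.2, 0.7, cutoff = 0.1), "magnitude")
  # sub-tolerance effects cannot be called sign changes
  expect_identical(
    classify_epistasis(0.5, 1e-9, -1e-9, 0.2, 0.7, cutoff = 0.1,
                       sign_tol = 1e-6),
    "magnitude")
  # stricter convention: flips must also exceed the cutoff
  expect_identical(
    classify_epistasis(0.5, 0.05, -0.05, 0.3, 0.4, cutoff = 0.1,
                       require_effect_cutoff = TRUE),
    "magnitude")
  expect_identical(
    classify_epistasis(0.5, 0.05, -0.05, 0.3, 0.4, cutoff = 0.1),
    "sign")
  # vectorised
  out <- classify_epistasis(
    c(0.05, -0.196, 0.5), c(1, 0.098, 0.3), c(-1, -0.098, 0.8),
    c(1, 0.098, 0.2), c(-1, -0.098, 0.7), cutoff = 0.1)
  expect_identical(out, c("none", "reciprocal_sign", "magnitude"))
})

test_that("third-order epistasis vanishes on additive and pairwise surfaces", {
  # additive cube
  single <- c(a = 0.7, b = -0.4, c = 1.1)
  g <- c(abc = 0,
         Abc = single[["a"]], aBc = single[["b"]], abC = single[["c"]],
         ABc = single[["a"]] + single[["b"]],
         AbC = single[["a"]] + single[["c"]],
         aBC = single[["b"]] + single[["c"]],
         ABC = sum(single))
  expect_equal(high_order_epistasis(g), 0)
  # purely pairwise surface: add pair couplings, still no third order
  g2 <- g + c(abc = 0, Abc = 0, aBc = 0, abC = 0,
              ABc = 0.3, AbC = -0.2, aBC = 0.5, ABC = 0.3 - 0.2 + 0.5)
  expect_equal(high_order_epistasis(g2), 0)
  expect_error(high_order_epistasis(g[-1]),
               class = "epiensemble_error_invalid_input")
})

test_that("genotype cubes reproduce the brute-force background difference of pairwise epsilon", {
  ens <- three_state_ensemble()
  a <- c(i = 0, j = 0.9, k = -0.6)
  b <- c(i = 0, j = -0.7, k = 0.8)
  cc <- c(i = 0, j = 0.5, k = -1.0)
  cube <- epistasis_cube(ens, a, b, cc)

  # direct evaluation via the package's own four observables
  eps_c <- epistasis_full(c(ab = cube$dg_obs[["abc"]],
                            Ab = cube$dg_obs[["Abc"]],
                            aB = cube$dg_obs[["aBc"]],
                            AB = cube$dg_obs[["ABc"]]))
  eps_C <- epistasis_full(c(ab = cube$dg_obs[["abC"]],
                            Ab = cube$dg_obs[["AbC"]],
                            aB = cube$dg_obs[["aBC"]],
                            AB = cube$dg_obs[["ABC"]]))
  expect_equal(cube$eps3, eps_C - eps_c, tolerance = 1e-12)

  # independent oracle for the two faces
  oracle_c <- oracle_epsilon(0, c(0, 0), 0, c(0.9, -0.6), 0, c(-0.7, 0.8))
  oracle_C <- oracle_epsilon(0, c(0.5, -1.0), 0, c(0.9, -0.6),
                             0, c(-0.7, 0.8))
  expect_equal(cube$eps_ab_in_c, oracle_c, tolerance = 1e-10)
  expect_equal(cube$eps_ab_in_C, oracle_C, tolerance = 1e-10)
  expect_true(abs(cube$eps3) > 1e-3)  # genuinely third-order here

  # single inactive conformation: no third-order ensemble epistasis
  two <- define_ensemble(c("i", "j"), c(0, 0), active = "i")
  cube2 <- epistasis_cube(two,
                          c(i = 0.2, j = 0.9), c(i = -0.1, j = -0.7),
                          c(i = 0.4, j = 0.5))
  expect_equal(cube2$eps3, 0, tolerance = 1e-12)
})

test_that("tidy and glance methods return the documented shapes", {
  ens <- three_state_ensemble()
  cyc <- mutant_cycle(ens, c(i = 0, j = 0.35, k = -0.35),
                      c(i = 0, j = -0.35, k = 0.35), cutoff = 0.1)
  td <- tidy(cyc)
  expect_identical(td$genotype, c("ab", "Ab", "aB", "AB"))
  gl <- glance(cyc)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$eclass, "reciprocal_sign")
  expect_equal(gl$epsilon, cyc$epsilon)
})
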