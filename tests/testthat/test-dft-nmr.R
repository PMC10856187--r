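test_that("ensemble tables parse with unit handling and consistency checks", {
  ens <- toy_ensemble()
  path <- withr::local_tempfile(fileext = ".csv")
  write_scenario(list(ensembles = list(cand = ens)), dirname(path))
  got <- read_ensemble_table(file.path(dirname(path), "ensembles.csv"))$cand
  expect_equal(got$energies, c(0, 0.5))
  expect_equal(got$shieldings, ens$shieldings, ignore_attr = TRUE)

  # kJ/mol input: 4.184 kJ/mol is exactly 1 kcal/mol
  kj <- tibble::tibble(
    candidate_id = "x", conformer_id = rep(c("c1", "c2"), each = 1),
    rel_energy_kj = c(0, 4.184), nucleus_id = "C-1", element = "C",
    hybridization = "sp2", shielding_ppm = c(100, 101))
  p2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(kj, p2)
  expect_equal(read_ensemble_table(p2, energy_unit = "kJ")$x$energies,
               c(0, 1))

  # a nucleus present in one conformer but not another is a hard error
  bad <- tibble::tibble(
    candidate_id = "x", conformer_id = c("c1", "c1", "c2"),
    rel_energy_kcal = c(0, 0, 0.2),
    nucleus_id = c("C-1", "C-2", "C-1"), element = "C",
    hybridization = "sp2", shielding_ppm = c(100, 90, 101))
  p3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, p3)
  expect_error(read_ensemble_table(p3), "c2.*C-2")

  # a missing shielding cell names conformer and nucleus
  na_cell <- kj
  names(na_cell)[names(na_cell) == "rel_energy_kj"] <- "rel_energy_kcal"
  na_cell$shielding_ppm[2] <- NA
  p4 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(na_cell, p4)
  expect_error(read_ensemble_table(p4), "conformer c2.*C-1")
})

test_that("energy-window filtering is boundary-inclusive and matches brute force", {
  nuclei <- tibble::tibble(nucleus_id = "C-1", element = "C",
                           hybridization = "sp2",
                           equivalence_group = NA_character_)
  sh <- matrix(100, 4, 1, dimnames = list(NULL, "C-1"))
  ens <- conformer_ensemble("x", c(0, 2.9, 3.0, 3.1), sh, nuclei)
  kept <- filter_energy_window(ens, 3.0)
  expect_equal(kept$energies, c(0, 2.9, 3.0))

  single <- conformer_ensemble("y", 0, sh[1, , drop = FALSE], nuclei)
  expect_equal(filter_energy_window(single)$energies, 0)

  for (seed in 1:100) {
    e <- random_ensemble(8, 3, seed)
    w <- runif(1, 0.5, 6)
    got <- filter_energy_window(e, w)$energies
    expect_identical(got, e$energies[e$energies <= w])
  }
})

test_that("Boltzmann weights match the closed form and its invariances", {
  expect_equal(boltzmann_weights(5), 1)
  expect_equal(boltzmann_weights(c(1.3, 1.3)), c(0.5, 0.5))

  # closed-form two-state oracle at 1.0 kcal/mol, 298.15 K
  RT <- 1.9872041e-3 * 298.15
  w <- boltzmann_weights(c(0, 1.0))
  expect_equal(w[1], 1 / (1 + exp(-1 / RT)), tolerance = 1e-10)
  expect_equal(w[1], 0.844, tolerance = 1e-3)

  set.seed(31)
  for (i in 1:20) {
    e <- runif(6, 0, 8)
    w1 <- boltzmann_weights(e)
    expect_equal(sum(w1), 1, tolerance = 1e-12)
    expect_equal(w1, boltzmann_weights(e + runif(1, -50, 50)),
                 tolerance = 1e-12)
    expect_true(all(diff(w1[order(e)]) <= 1e-15))
  }
  expect_error(boltzmann_weights(numeric(0)), "empty")
  expect_error(boltzmann_weights(c(0, Inf)))
})

test_that("shielding averaging is the weighted mean, with group collapse", {
  ens <- toy_ensemble()
  avg <- average_shieldings(ens, c(0.75, 0.25))
  expect_equal(avg$shielding_ppm[avg$nucleus_id == "C-2"], 101)

  # identical shieldings across conformers: weights are irrelevant
  nuclei <- ens$nuclei
  sh <- matrix(rep(c(60, 100, 26), each = 3), 3,
               dimnames = list(NULL, nuclei$nucleus_id))
  same <- conformer_ensemble("s", c(0, 1, 2), sh, nuclei)
  for (w in list(c(1, 0, 0), c(0.2, 0.3, 0.5))) {
    expect_equal(average_shieldings(same, w)$shielding_ppm, c(60, 100, 26))
  }

  # brute-force oracle on a random 5-conformer ensemble
  e <- random_ensemble(5, 4, seed = 41)
  w <- boltzmann_weights(e$energies)
  avg2 <- average_shieldings(e, w)
  for (j in seq_len(4)) {
    expect_equal(avg2$shielding_ppm[j],
                 sum(w * e$shieldings[, j]), tolerance = 1e-12)
  }

  expect_error(average_shieldings(e, c(0.5, 0.5)), "length")

  # methyl protons declared equivalent collapse to one averaged entry
  nuc_me <- tibble::tibble(
    nucleus_id = c("H-7a", "H-7b", "H-7c", "C-7"),
    element = c("H", "H", "H", "C"),
    hybridization = "sp3",
    equivalence_group = c("H-7", "H-7", "H-7", NA))
  shm <- matrix(c(29.0, 29.4, 29.9, 150), 1,
                dimnames = list(NULL, nuc_me$nucleus_id))
  me <- conformer_ensemble("m", 0, shm, nuc_me)
  avg3 <- average_shieldings(me, 1)
  expect_equal(nrow(avg3), 2L)
  expect_equal(avg3$shielding_ppm[avg3$nucleus_id == "H-7"],
               mean(c(29.0, 29.4, 29.9)))
})

test_that("empirical scaling and unscaled shifts follow their conventions", {
  tbl <- tibble::tibble(nucleus_id = c("C-1", "C-2"), element = "C",
                        hybridization = "sp2",
                        shielding_ppm = c(186.5, 100))
  factors <- list(C = list(slope = -1.05, intercept = 186.5))
  out <- scale_shifts_global(tbl, factors)
  expect_equal(out$shift_ppm[1], 0)
  expect_equal(out$shift_ppm[2], (186.5 - 100) / 1.05, tolerance = 1e-12)

  # inverse identity: sigma = intercept + slope * delta, then scale back
  set.seed(51)
  delta <- runif(10, 0, 200)
  tbl2 <- tibble::tibble(nucleus_id = sprintf("C-%d", 1:10), element = "C",
                         hybridization = "sp2",
                         shielding_ppm = 186.5 + (-1.05) * delta)
  expect_equal(scale_shifts_global(tbl2, factors)$shift_ppm, delta,
               tolerance = 1e-10)

  expect_error(scale_shifts_global(
    tibble::tibble(nucleus_id = "H-1", element = "H",
                   hybridization = "sp3", shielding_ppm = 25),
    factors), "H")

  u <- unscaled_shifts(tibble::tibble(
    nucleus_id = c("C-1", "C-2"), element = "C", hybridization = "sp2",
    shielding_ppm = c(190, 60)), c(C = 190))
  expect_equal(u$shift_ppm, c(0, 130))
  # affine in the shielding with slope -1
  s <- runif(20, 0, 200)
  u2 <- unscaled_shifts(tibble::tibble(
    nucleus_id = sprintf("C-%d", 1:20), element = "C",
    hybridization = "sp2", shielding_ppm = s), c(C = 190))
  fit <- stats::lm(u2$shift_ppm ~ s)
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 1e-10)
  expect_error(unscaled_shifts(u2[0:1, ], c(H = 31)), "C")
})

test_that("per-candidate regression rescaling matches the normal equations", {
  exp <- shift_tbl(sprintf("C-%d", 1:10), "C", seq(10, 190, by = 20))
  calc_eq <- exp
  r1 <- regression_scale(calc_eq, exp)
  expect_equal(r1$fits$slope, 1, tolerance = 1e-10)
  expect_equal(r1$fits$intercept, 0, tolerance = 1e-8)
  expect_equal(r1$scaled$shift_ppm, exp$shift_ppm, tolerance = 1e-10)

  calc_lin <- exp
  calc_lin$shift_ppm <- 2 * exp$shift_ppm + 5
  r2 <- regression_scale(calc_lin, exp)
  expect_equal(r2$scaled$shift_ppm, exp$shift_ppm, tolerance = 1e-10)

  set.seed(61)
  calc_rand <- exp
  calc_rand$shift_ppm <- exp$shift_ppm + rnorm(10, 0, 3)
  r3 <- regression_scale(calc_rand, exp)
  # normal-equation oracle
  xb <- mean(exp$shift_ppm); yb <- mean(calc_rand$shift_ppm)
  m <- sum((exp$shift_ppm - xb) * (calc_rand$shift_ppm - yb)) /
    sum((exp$shift_ppm - xb)^2)
  b <- yb - m * xb
  expect_equal(r3$fits$slope, m, tolerance = 1e-10)
  expect_equal(r3$fits$intercept, b, tolerance = 1e-10)

  expect_error(regression_scale(calc_eq[1:2, ], exp[1:2, ]), ">= 3")
})

test_that("MAE and RMSD follow their definitions, with MAE <= RMSD always", {
  exp <- shift_tbl(c("C-1", "C-2", "C-3"), "C", c(100, 110, 120))
  calc <- exp
  st0 <- error_stats(calc, exp)
  expect_equal(st0$mae, 0)
  expect_equal(st0$rmsd, 0)

  calc$shift_ppm <- exp$shift_ppm + c(1, -2, 3)
  st <- error_stats(calc, exp, element = "C")
  expect_equal(st$mae, 2.0)
  expect_equal(st$rmsd, sqrt(14 / 3), tolerance = 1e-12)
  expect_equal(st$errors$error_ppm, c(1, -2, 3))

  set.seed(71)
  for (i in 1:1000) {
    e <- rnorm(sample(2:30, 1), 0, runif(1, 0.1, 5))
    expect_lte(mean(abs(e)), sqrt(mean(e^2)) + 1e-14)
  }

  h <- shift_tbl("H-1", "H", 7.2)
  expect_error(error_stats(calc, h), "no shared")
})
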