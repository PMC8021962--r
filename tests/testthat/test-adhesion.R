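test_that("molecule calibration is linear with 25,000 molecules per energy unit", {
  p <- adhesion_params()
  expect_identical(molecules_from_energy(1.0, p), 25000)
  expect_identical(molecules_from_energy(0, p), 0)
  expect_identical(molecules_from_energy(2.0, p), 50000)
  expect_error(molecules_from_energy(-1, p), class = "cadhesion_error_energy")
})

test_that("contact concentration follows the slab geometry of the cell-cell interface", {
  p <- adhesion_params()
  cc <- contact_concentration(25000, p)
  # independent hand geometry: sphere surface pi * (10 um)^2 = 314.159 um^2,
  # one of 12 contacts -> 26.18 um^2, x 12 nm slab -> 3.1416e-16 L;
  # 25000/12 * 0.5 = 1041.7 participating molecules -> 5.506 uM
  area_um2 <- pi * 10^2 / 12
  vol_l <- area_um2 * 1e-12 * 12e-9 * 1000
  expect_equal(cc$contact_volume, vol_l, tolerance = 1e-12)
  expect_equal(cc$c_total, (25000 / 12 * 0.5) / (6.022e23 * vol_l),
               tolerance = 1e-12)
  expect_equal(cc$c_total, 5.506e-6, tolerance = 1e-3)
  # zero molecules, linearity
  expect_equal(contact_concentration(0, p)$c_total, 0)
  expect_equal(contact_concentration(50000, p)$c_total, 2 * cc$c_total)
  # counting both membranes doubles C_T
  p2 <- adhesion_params(count_both_cells = TRUE)
  expect_equal(contact_concentration(25000, p2)$c_total, 2 * cc$c_total)
})

test_that("dimer equilibrium has the exact closed forms and conserves mass", {
  kd <- 25.8e-6
  # C_T = K_D gives C_M = K_D/2, C_D = K_D/4 exactly
  st <- solve_dimer_equilibrium(kd, kd)
  expect_equal(st$c_monomer, kd / 2, tolerance = 1e-14)
  expect_equal(st$c_dimer, kd / 4, tolerance = 1e-14)
  # C_T = 0 is fully dissociated
  st0 <- solve_dimer_equilibrium(0, kd)
  expect_equal(st0$c_monomer, 0)
  expect_equal(st0$c_dimer, 0)
  # frozen worked case: C_T = 5.52 uM, K_D = 25.8 uM
  st1 <- solve_dimer_equilibrium(5.52e-6, kd)
  expect_equal(st1$c_monomer, 4.1713e-6, tolerance = 1e-4)
  expect_equal(st1$c_dimer, 6.744e-7, tolerance = 1e-3)
  expect_error(solve_dimer_equilibrium(NaN, kd),
               class = "cadhesion_error_equilibrium")
  expect_error(solve_dimer_equilibrium(1e-6, 0),
               class = "cadhesion_error_equilibrium")
})

test_that("closed-form equilibrium matches the bisection oracle over eight decades", {
  kd <- 25.8e-6
  for (ratio in 10^seq(-4, 4, by = 0.5)) {
    ct <- kd * ratio
    st <- solve_dimer_equilibrium(ct, kd)
    oracle <- bisect_equilibrium(ct, kd)
    expect_equal(st$c_monomer, oracle$c_monomer, tolerance = 1e-9)
    expect_equal(st$c_dimer, oracle$c_dimer, tolerance = 1e-9)
    residual <- abs(st$c_monomer + 2 * st$c_dimer - ct)
    expect_lt(residual, 1e-12 * max(ct, kd))
  }
})

test_that("equilibrium approaches the dilute and saturated limits", {
  kd <- 25.8e-6
  # dilute: C_D -> C_T^2 / K_D within 1% at C_T/K_D = 1e-3
  ct <- kd * 1e-3
  st <- solve_dimer_equilibrium(ct, kd)
  expect_equal(st$c_dimer, ct^2 / kd, tolerance = 0.01)
  # saturated: C_D -> C_T / 2, deviation sqrt(K_D / (2 C_T)): about 2.2%
  # at C_T/K_D = 1e3, under 1% by 1e4, decreasing throughout
  errs <- vapply(10^(2:5), function(r) {
    ct <- kd * r
    abs(solve_dimer_equilibrium(ct, kd)$c_dimer - ct / 2) / (ct / 2)
  }, numeric(1))
  expect_equal(errs[2], sqrt(1 / (2 * 1e3)), tolerance = 0.05)
  expect_lt(errs[3], 0.01)
  expect_true(all(diff(errs) < 0))
  # dimer fraction increases monotonically with C_T
  fractions <- vapply(10^seq(-3, 3, by = 0.5), function(r) {
    s <- solve_dimer_equilibrium(kd * r, kd)
    2 * s$c_dimer / s$c_total
  }, numeric(1))
  expect_true(all(diff(fractions) > 0))
})

test_that("per-dimer free energy uses the 1 M reference state and is monotone in affinity", {
  p <- adhesion_params()
  expect_equal(free_energy_per_dimer(1.0, p), 0)
  # R*T = 1.987 * 310.15 = 616.27 cal/mol; ln(1/25.8e-6) = 10.565;
  # divided by Avogadro: 1.081e-20 cal per dimer
  expect_equal(free_energy_per_dimer(25.8e-6, p), 1.0812e-20,
               tolerance = 1e-3)
  expect_gt(free_energy_per_dimer(1e-6, p), free_energy_per_dimer(1e-5, p))
  expect_error(free_energy_per_dimer(0, p), class = "cadhesion_error_kd")
})

test_that("work of separation composes the model and normalizes to the reference", {
  p <- adhesion_params()
  ref <- adhesion_work(25000, 25.8e-6, p)
  expect_equal(ref$relative_adhesion, 1.0, tolerance = 1e-12)
  expect_equal(ref$work, ref$state$n_dimers * ref$delta_g)
  # the study's printed anchor: 2.4x the molecules -> 3.8x the work
  hi <- adhesion_work(2.4 * 25000, 25.8e-6, p)
  expect_equal(round(hi$relative_adhesion, 1), 3.8)
  # W is strictly increasing in molecule count
  works <- vapply(c(1e3, 1e4, 2.5e4, 1e5, 1e6), function(m) {
    adhesion_work(m, 25.8e-6, p)$work
  }, numeric(1))
  expect_true(all(diff(works) > 0))
  # for one cadherin the work ratio equals the dimer-count ratio (delta_g cancels)
  expect_equal(hi$work / ref$work, hi$state$n_dimers / ref$state$n_dimers,
               tolerance = 1e-12)
})

test_that("relative adhesion is invariant to temperature and contact fraction", {
  for (m in c(12000, 25000, 60000)) {
    r_cold <- adhesion_work(m, 25.8e-6,
                            adhesion_params(temperature = 298.15))
    r_warm <- adhesion_work(m, 25.8e-6,
                            adhesion_params(temperature = 310.15))
    expect_equal(r_cold$relative_adhesion, r_warm$relative_adhesion,
                 tolerance = 1e-12)
  }
  # the rounded 8% contact fraction agrees with the exact 1/12
  r_twelfth <- adhesion_work(60000, 25.8e-6,
                             adhesion_params(contact_fraction = 1 / 12))
  r_8pct <- adhesion_work(60000, 25.8e-6,
                          adhesion_params(contact_fraction = 0.08))
  expect_equal(round(r_twelfth$relative_adhesion, 1),
               round(r_8pct$relative_adhesion, 1))
})

test_that("the 2.4-fold amplification lies between linear and quadratic regimes", {
  p <- adhesion_params()
  # W(2.4m)/W(m) in (2.4, 5.76): quadratic (dilute) to linear (saturated)
  for (scale in 10^seq(-3, 3)) {
    m <- 25000 * scale
    ratio <- adhesion_work(2.4 * m, 25.8e-6, p)$work /
      adhesion_work(m, 25.8e-6, p)$work
    expect_gt(ratio, 2.4)
    expect_lt(ratio, 5.76)
  }
})

test_that("K_D table loads with valid specificity groups", {
  kd <- read_kd_table()
  expect_true(all(kd$kd_molar > 0))
  expect_equal(kd$kd_molar[kd$cadherin == "Cdh2"], 25.8e-6)
  expect_setequal(kd$cadherin[kd$specificity_group == "A"],
                  c("Cdh6", "Cdh9", "Cdh10"))
  expect_setequal(kd$cadherin[kd$specificity_group == "C"],
                  c("Cdh8", "Cdh11", "Cdh24"))
  # a wrong group assignment is rejected
  bad <- kd
  bad$specificity_group[bad$cadherin == "Cdh2"] <- "A"
  path <- tempfile(fileext = ".csv")
  names(bad)[names(bad) == "kd_molar"] <- "kd_molar"
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_kd_table(path), class = "cadhesion_error_kd")
})

test_that("adhesion profiles cover every (cadherin, structure) with a K_D entry", {
  m <- matrix(c(1.0, 2.4, 0.5, 1.5), 2, 2, byrow = TRUE,
              dimnames = list(c("Cdh2", "Nohit"), c("s1", "s2")))
  kd <- tibble::tibble(cadherin = "Cdh2", kd_molar = 25.8e-6,
                       cadherin_type = "type I",
                       specificity_group = "none", source = "test")
  expect_warning(prof <- adhesion_profile(m, kd), "Nohit")
  expect_equal(nrow(prof), 2L)
  expect_equal(prof$relative_adhesion[prof$structure_id == "s1"], 1.0,
               tolerance = 1e-12)
  ratio <- prof$relative_adhesion[prof$structure_id == "s2"] /
    prof$relative_adhesion[prof$structure_id == "s1"]
  expect_equal(round(ratio, 1), 3.8)
  # missing energies are skipped, empty gene intersection errors
  expect_error(
    suppressWarnings(adhesion_profile(
      matrix(1, 1, 1, dimnames = list("Nope", "s1")), kd)),
    class = "cadhesion_error_reference")
})

test_that("adjacent fold changes flag boundaries at the threshold", {
  fc <- adjacent_fold_changes(c(1, 4, 4))
  expect_equal(fc$fold, c(4, 1))
  expect_equal(fc$flagged, c(TRUE, FALSE))
  # constant profile has no boundary
  expect_false(any(adjacent_fold_changes(rep(2, 5))$flagged))
  # a zero next to a positive value is an infinite, flagged fold
  fc0 <- adjacent_fold_changes(c(0, 2))
  expect_true(is.infinite(fc0$fold))
  expect_true(fc0$flagged)
  # both sides zero is fold 1
  expect_equal(adjacent_fold_changes(c(0, 0))$fold, 1)
  expect_error(adjacent_fold_changes(1), class = "cadhesion_error_profile")
})
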