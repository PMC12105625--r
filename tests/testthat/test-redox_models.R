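test_that("pKa converts to deprotonation free energy as RT ln(10) pKa", {
  expect_equal(pka_to_deltaG(0), 0)
  expect_equal(pka_to_deltaG(1), 5.708, tolerance = 1e-4)
  expect_equal(pka_to_deltaG(-1), -pka_to_deltaG(1))
  expect_equal(pka_to_deltaG(3), 3 * pka_to_deltaG(1), tolerance = 1e-12)
})

test_that("Henderson-Hasselbalch mole fractions reproduce the titration footnotes", {
  mid <- mole_fractions(7, 7)
  expect_equal(mid$x_RH, 0.5)
  expect_equal(mid$x_Rminus, 0.5)
  # xanthine at pH 7 (pKa 7.5) and hypoxanthine at pH 9 (pKa 8.9)
  expect_equal(round_display(mole_fractions(7, 7.5)$x_RH), 0.76)
  expect_equal(round_display(mole_fractions(9, 8.9)$x_RH), 0.44)
})

test_that("x_RH falls with pH, rises with pKa, and the pair always sums to 1", {
  set.seed(41)
  for (i in 1:40) {
    pH <- stats::runif(1, 0, 14); pKa <- stats::runif(1, 0, 14)
    x <- mole_fractions(pH, pKa)
    expect_equal(x$x_RH + x$x_Rminus, 1, tolerance = 1e-12)
    expect_true(x$x_RH >= 0 && x$x_RH <= 1)
    expect_lt(mole_fractions(pH + 0.5, pKa)$x_RH, x$x_RH)
    expect_gt(mole_fractions(pH, pKa + 0.5)$x_RH, x$x_RH)
  }
})

test_that("M1 subtracts the reference electrode from the per-electron free energy", {
  expect_equal(m1_potential(5.721)$E, 1.44)
  expect_equal(m1_potential(4.281)$E, 0)
  sce <- redox_constants(reference = "SCE")
  expect_equal(m1_potential(5.679, sce)$E, 1.25)
  expect_equal(m1_potential(5.679, sce)$reference, "SCE")
})

test_that("M2 mixes the two pathways with Henderson-Hasselbalch fractions", {
  # xanthine: printed M1 pair (1.89, 0.92) V, pKa 7.5, pH 7 -> 1.66 V
  x_couple <- redox_couple(1.89 + 4.281, 0.92 + 4.281,
                           acid_base_spec(pKa_reduced = 7.5))
  expect_equal(m2_potential(x_couple, 7)$E, 1.66, tolerance = 0.01)
  # hypoxanthine at pH 9: printed M1 pair (2.05, 1.14) V, pKa 8.9 -> 1.54 V
  hx_couple <- redox_couple(2.05 + 4.281, 1.14 + 4.281,
                            acid_base_spec(pKa_reduced = 8.9))
  expect_equal(m2_potential(hx_couple, 9)$E, 1.54, tolerance = 0.01)

  # x_RH -> 1 limit: M2 collapses onto the neutral-pathway M1
  high_pka <- redox_couple(5.9, 5.0, acid_base_spec(pKa_reduced = 13.9))
  expect_equal(m2_potential(high_pka, 1)$E, m1_potential(5.9)$E,
               tolerance = 1e-10)

  # missing deprotonated pathway with non-negligible x_R- is an error
  lone <- redox_couple(5.9, acid_base = acid_base_spec(pKa_reduced = 7))
  expect_error(m2_potential(lone, 7), "deprotonated")
})

test_that("M2 lies between the deprotonated and neutral M1 potentials", {
  set.seed(43)
  for (i in 1:30) {
    dG_n <- stats::runif(1, 5.5, 6.5)
    dG_d <- dG_n - stats::runif(1, 0.1, 1)
    pKa <- stats::runif(1, 2, 12)
    cp <- redox_couple(dG_n, dG_d, acid_base_spec(pKa_reduced = pKa))
    E2 <- m2_potential(cp, stats::runif(1, 0, 14))$E
    expect_gte(E2, m1_potential(dG_d)$E - 1e-12)
    expect_lte(E2, m1_potential(dG_n)$E + 1e-12)
  }
})

test_that("the prototropic correction matches its worked value and sign rule", {
  # literal Ka(0)r = 0, Ka(+1)o = 1 at pH 7: -0.41 V
  expect_equal(prototropic_correction(0, 1, 7), -0.4141, tolerance = 1e-4)
  expect_equal(prototropic_correction(1e-9, 1e-9, 7), 0)
  # Ka(0)r > Ka(+1)o flips the sign positive; the standard ordering is negative
  set.seed(47)
  for (i in 1:40) {
    ka <- sort(10^stats::runif(2, -12, -2))
    expect_lt(prototropic_correction(ka[1], ka[2], 7), 0)
    expect_gt(prototropic_correction(ka[2], ka[1], 7), 0)
  }
  # pH deep enough that 10^-pH underflows to zero with both Ka zero
  expect_error(prototropic_correction(0, 0, 400), "positive")
})

test_that("M3 and M4 reduce to E-standard at Ka equality and match closed forms", {
  ab_eq <- acid_base_spec(Ka_oxidized = 1e-5, Ka_reduced = 1e-5)
  expect_equal(m3_potential(1.5, ab_eq, 7)$E, 1.5)
  expect_equal(m4_potential(1.5, ab_eq, 7)$E, 1.5)

  set.seed(53)
  for (i in 1:50) {
    E0 <- stats::runif(1, 0.5, 2.5)
    pKa_o <- stats::runif(1, 1, 7); pKa_r <- pKa_o + stats::runif(1, 0, 8)
    pH <- stats::runif(1, 0, 14)
    ab <- acid_base_spec(pKa_oxidized = pKa_o, pKa_reduced = pKa_r)
    expect_equal(m3_potential(E0, ab, pH)$E,
                 oracle_m3(E0, 10^-pKa_r, 10^-pKa_o, pH), tolerance = 1e-12)
    expect_equal(m4_potential(E0, ab, pH)$E,
                 oracle_m4(E0, 10^-pKa_r, 10^-pKa_o, pH), tolerance = 1e-12)
  }
  expect_error(m4_potential(1.5, acid_base_spec(Ka_reduced = 0,
                                                Ka_oxidized = 1), 7),
               "Ka\\(0\\)r > 0")
})

test_that("M4 - M3 equals the neutralization term plus one pH/Ka term", {
  set.seed(59)
  for (i in 1:50) {
    E0 <- stats::runif(1, 0, 2)
    ka_o <- 10^stats::runif(1, -7, -1); ka_r <- 10^stats::runif(1, -14, -8)
    pH <- stats::runif(1, 0, 14)
    ab <- acid_base_spec(Ka_oxidized = ka_o, Ka_reduced = ka_r)
    gap <- m4_potential(E0, ab, pH)$E - m3_potential(E0, ab, pH)$E
    expect_lt(abs(gap - (neutralization_term(ka_o, ka_r) +
                           prototropic_correction(ka_r, ka_o, pH))), 1e-12)
    expect_gt(neutralization_term(ka_o, ka_r), 0)
  }
  # one pKa unit of acidity difference is (RT/F) ln 10 ~ 59.2 mV
  expect_equal(neutralization_term(1e-4, 1e-5), oracle_rt_f() * log(10))
  expect_equal(round(neutralization_term(1e-4, 1e-5), 4), 0.0592)
  expect_equal(neutralization_term(1e-6, 1e-6), 0)
  expect_error(neutralization_term(0, 1e-5), "positive")
})

test_that("pathway selection follows the deprotonated mole fraction", {
  acidic <- acid_base_spec(pKa_oxidized = 1, pKa_reduced = 4.28)
  expect_equal(select_pathway(acidic, 7), "deprotonated")
  weak <- acid_base_spec(pKa_oxidized = 4.6, pKa_reduced = 12.2)
  expect_equal(select_pathway(weak, 7), "neutral")
  # tie at pH = pKa goes to neutral (strict inequality)
  expect_equal(select_pathway(acid_base_spec(pKa_reduced = 7), 7), "neutral")
  # non-acidic sentinel always keeps the neutral pathway
  expect_equal(select_pathway(acid_base_spec(), 7), "neutral")
})

test_that("speciation curves are monotone with the correct pH limits", {
  ab <- acid_base_spec(pKa_oxidized = 3, pKa_reduced = 9)
  cp <- redox_couple(5.9, 5.3, ab)
  E0 <- m1_potential(5.9)$E

  single <- speciation_curve(cp, "M3", pH_grid = 7.0)
  expect_equal(single$E_volts, m3_potential(E0, ab, 7)$E)
  expect_equal(nrow(single), 1)

  curve <- speciation_curve(cp, "M3")
  expect_equal(nrow(curve), length(seq(0, 14, by = 0.1)))
  expect_true(all(diff(curve$E_volts) <= 1e-12))
  # low-pH limit recovers E-standard; high-pH limit the Ka ratio plateau
  expect_equal(curve$E_volts[1], E0, tolerance = 1e-3)
  rt_f <- oracle_rt_f()
  expect_equal(curve$E_volts[nrow(curve)],
               E0 + rt_f * log(10^-9 / 10^-3), tolerance = 1e-3)

  m4curve <- speciation_curve(cp, "M4")
  expect_true(all(diff(m4curve$E_volts) <= 1e-12))
  expect_error(speciation_curve(cp, "M3", pH_grid = c(7, 6)), "ascending")
})

test_that("couple construction enforces the pathway energy ordering", {
  expect_error(redox_couple(5.5, 5.6, acid_base_spec(pKa_reduced = 7)),
               "below the neutral")
  ok <- redox_couple(5.6, 5.5, acid_base_spec(pKa_reduced = 7))
  expect_s3_class(ok, "redox_couple")
})

test_that("literal Ka entry and the non-acidic sentinel coexist with pKa entry", {
  lit <- acid_base_spec(Ka_oxidized = 1, Ka_reduced = 0)
  expect_equal(lit$Ka_oxidized, 1)
  expect_equal(lit$Ka_reduced, 0)
  expect_true(is.na(lit$pKa_reduced))
  via_pka <- acid_base_spec(pKa_oxidized = 4.2, pKa_reduced = 9.5)
  expect_equal(via_pka$Ka_oxidized, 10^-4.2)
  expect_equal(via_pka$pKa_reduced, 9.5)
})
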