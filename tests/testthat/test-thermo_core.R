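test_that("energy conversions use the defined constants and round-trip", {
  expect_equal(convert_energy(1, "hartree", "eV"), 27.2114)
  expect_equal(convert_energy(0, "eV", "kJ/mol"), 0)
  expect_equal(convert_energy(27.2114, "eV", "hartree"), 1)
  expect_equal(convert_energy(1, "hartree", "kJ/mol"), 2625.50)

  units <- c("hartree", "eV", "kJ/mol")
  set.seed(7)
  vals <- stats::runif(20, -500, 500)
  for (u in units) for (v in units) {
    back <- convert_energy(convert_energy(vals, u, v), v, u)
    expect_lt(max(abs(back - vals) / pmax(abs(vals), 1e-300)), 1e-12)
  }
  expect_error(convert_energy(1, "kcal/mol", "eV"), "supported units")
})

test_that("assemble_gsol sums converted gas terms, standard state and solvation", {
  consts <- redox_constants()
  zero_ss <- thermo_components(0, 0, 0, 0, apply_standard_state = TRUE)
  expect_equal(assemble_gsol(zero_ss, consts), 7.91)
  zero <- thermo_components(0, 0, 0, 0, apply_standard_state = FALSE)
  expect_equal(assemble_gsol(zero, consts), 0)

  # term-by-term summation oracle on random components
  set.seed(11)
  for (i in 1:50) {
    e <- stats::runif(1, -600, 0); z <- stats::runif(1, 0, 0.3)
    th <- stats::runif(1, -0.1, 0.1); sv <- stats::runif(1, -300, 50)
    got <- assemble_gsol(thermo_components(e, z, th, sv), consts)
    want <- e * 2625.50 + z * 2625.50 + th * 2625.50 + 7.91 + sv
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("assemble_gsol is additive in each hartree component", {
  consts <- redox_constants()
  base <- assemble_gsol(thermo_components(-100, 0.1, 0.01, -20), consts)
  bumped <- assemble_gsol(thermo_components(-100 + 0.002, 0.1, 0.01, -20), consts)
  expect_equal(bumped - base, convert_energy(0.002, "hartree", "kJ/mol"))
})

test_that("the recomputed standard-state correction is RT ln(24.46)", {
  lit <- redox_constants(standard_state = "literal")
  rec <- redox_constants(standard_state = "recomputed")
  expect_equal(lit$dG_1atm_to_1M, 7.91)
  expect_equal(rec$dG_1atm_to_1M, 8.31446 * 298.15 * log(24.46) / 1000)
  expect_gt(rec$dG_1atm_to_1M, 7.91) # ~7.93 at 298.15 K
})

test_that("solvation free energy is a same-unit phase difference", {
  expect_equal(solvation_free_energy(-100, -100), 0)
  expect_equal(solvation_free_energy(-100.010, -100.000), -0.010)
  set.seed(3)
  a <- stats::rnorm(10); b <- stats::rnorm(10)
  for (i in 1:10) expect_equal(solvation_free_energy(a[i], b[i]), a[i] - b[i])
  expect_error(solvation_free_energy(-1, -1, "hartree", "eV"), "unit mismatch")
})

test_that("adiabatic ionization energy converts the optimised-geometry gap to eV", {
  expect_equal(adiabatic_ionization_energy(-540.0, -539.712915),
               0.287085 * 27.2114)
  expect_equal(adiabatic_ionization_energy(-1, -1), 0)
  set.seed(5)
  for (i in 1:20) {
    n <- stats::runif(1, -900, -100); c <- n + stats::runif(1, 0, 0.5)
    expect_equal(adiabatic_ionization_energy(n, c),
                 convert_energy(c - n, "hartree", "eV"), tolerance = 1e-12)
  }
  expect_error(adiabatic_ionization_energy(-1, 0, phase = "solution"),
               "gas-phase")
})

test_that("solution oxidation free energy closes the thermodynamic cycle", {
  expect_equal(oxidation_free_energy_solution(7.81, -2.50, -0.30), 5.61)
  expect_equal(oxidation_free_energy_solution(7.81, -1.0, -1.0), 7.81)
  set.seed(9)
  for (i in 1:1000) {
    x <- stats::rnorm(3)
    expect_equal(oxidation_free_energy_solution(x[1], x[2], x[3]),
                 x[1] + x[2] - x[3], tolerance = 1e-10)
  }
})

test_that("two-point CBS extrapolation has the inverse-cubic form", {
  expect_equal(cbs_extrapolate(-100, -100), -100)
  expect_equal(cbs_extrapolate(-100.000, -100.037),
               (64 * (-100.037) - 27 * (-100.000)) / 37)
  # extrapolation continues past the larger basis in the TZ->QZ direction
  set.seed(13)
  for (i in 1:25) {
    tz <- stats::runif(1, -200, -100); qz <- tz + stats::rnorm(1, 0, 0.05)
    cbs <- cbs_extrapolate(tz, qz)
    expect_true(sign(cbs - qz) == sign(qz - tz) || cbs == qz)
  }
  expect_error(cbs_extrapolate(-1, -1, X = 3, Y = 3), "Y > X")
})
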