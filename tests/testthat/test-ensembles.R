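test_that("Boltzmann weights normalise, respect degeneracy and the exp(-dG/RT) form", {
  expect_equal(boltzmann_weights(-42), 1)
  expect_equal(boltzmann_weights(c(-10, -10)), c(0.5, 0.5))

  # a gap of RT ln(10) gives a 10:1 population ratio
  RT <- 8.31446 * 298.15 / 1000
  w <- boltzmann_weights(c(0, 5.708))
  expect_equal(w, exp(-c(0, 5.708) / RT) / sum(exp(-c(0, 5.708) / RT)))
  expect_equal(w, c(1 / 1.1, 0.1 / 1.1), tolerance = 1e-4)

  expect_error(boltzmann_weights(numeric(0)), "empty")
})

test_that("weights sum to one and are invariant under uniform shifts", {
  set.seed(21)
  for (i in 1:30) {
    G <- stats::rnorm(sample(2:12, 1), sd = 10)
    w <- boltzmann_weights(G)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(w, boltzmann_weights(G + stats::runif(1, -1e4, 1e4)),
                 tolerance = 1e-12)
  }
})

test_that("ensemble free energy honours both averaging conventions", {
  expect_equal(ensemble_gsol(-10, mode = "weighted_mean"), -10)
  expect_equal(ensemble_gsol(-10, mode = "partition_sum"), -10)
  RT <- 8.31446 * 298.15 / 1000
  expect_equal(ensemble_gsol(c(-10, -10), mode = "weighted_mean"), -10)
  expect_equal(ensemble_gsol(c(-10, -10), mode = "partition_sum"),
               -10 - RT * log(2))
  # dominance limit: a >= 30 kJ/mol spread pins the mean to the lowest record
  expect_equal(ensemble_gsol(c(-50, -20), mode = "weighted_mean"), -50,
               tolerance = 1e-2 / 50)

  set.seed(22)
  for (i in 1:20) {
    G <- stats::rnorm(6, sd = 4)
    expect_gte(ensemble_gsol(G, mode = "weighted_mean"), min(G))
    expect_lte(ensemble_gsol(G, mode = "weighted_mean"), max(G))
    expect_lte(ensemble_gsol(G, mode = "partition_sum"), min(G))
  }
})

test_that("deduplication applies the 1e-7 au energy criterion", {
  au <- convert_energy(1, "hartree", "kJ/mol")
  twin <- make_records(c(-10, -10 + 1e-8 * au),
                       descriptor = list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(nrow(deduplicate(twin)), 1)

  apart <- make_records(c(-10, -10 + 1e-6 * au),
                        descriptor = list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(nrow(deduplicate(apart)), 2)

  bare <- make_records(c(-10, -10))
  expect_equal(nrow(deduplicate(bare)), 1)
})

test_that("deduplication compares sorted descriptors and keeps the lowest-G member", {
  au <- convert_energy(1, "hartree", "kJ/mol")
  # same distance multiset in different atom order: still a duplicate
  perm <- make_records(c(-10, -10 + 1e-8 * au),
                       descriptor = list(c(1, 2, 3), c(3, 1, 2)))
  kept <- deduplicate(perm)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$G_sol, -10)
  expect_equal(kept$conformer_id, "c01")

  # isoenergetic but geometrically distinct conformers both survive
  diff_geo <- make_records(c(-10, -10), descriptor = list(c(1, 2, 3), c(1, 2, 9)))
  expect_equal(nrow(deduplicate(diff_geo)), 2)
})

test_that("deduplication is idempotent on random record sets", {
  set.seed(31)
  au <- convert_energy(1, "hartree", "kJ/mol")
  for (i in 1:15) {
    n <- sample(3:12, 1)
    G <- -10 + sample(0:3, n, replace = TRUE) * 5e-8 * au
    recs <- make_records(G, descriptor = replicate(n, c(1, 2, 3), simplify = FALSE))
    once <- deduplicate(recs)
    twice <- deduplicate(once)
    expect_equal(twice$conformer_id, once$conformer_id)
    expect_equal(twice$G_sol, once$G_sol)
  }
})

test_that("tautomer count is the binomial coefficient, matching enumeration", {
  expect_equal(tautomer_count(4, 2), 6)
  expect_equal(tautomer_count(6, 0), 1)
  expect_equal(tautomer_count(6, 3), 20)
  for (n in 1:10) for (k in 0:n) {
    enumerated <- if (k == 0) 1 else ncol(utils::combn(n, k))
    expect_equal(tautomer_count(n, k), enumerated)
  }
  expect_error(tautomer_count(3, 4), "exceeds")
})

test_that("the 2% contribution filter keeps major conformers and never empties", {
  RT <- 8.31446 * 298.15 / 1000
  # weights ~ (0.97, 0.03): both retained
  g2 <- c(0, RT * log(0.97 / 0.03))
  expect_equal(length(contribution_filter(g2)), 2)
  # weights ~ (0.99, 0.01): minor one dropped
  g3 <- c(0, RT * log(0.99 / 0.01))
  expect_equal(contribution_filter(g3), 0)
  # 100 degenerate records each at weight 0.01: lowest-G fallback keeps one
  u <- rep(-5, 100)
  expect_equal(boltzmann_weights(u), rep(0.01, 100))
  expect_equal(length(contribution_filter(u)), 1)
})

test_that("species ensembles validate their records and expose the average", {
  recs <- make_records(c(-12, -10, -8))
  e <- species_ensemble(recs, charge = 0, redox_state = "reduced")
  expect_s3_class(e, "species_ensemble")
  expect_equal(sum(e$weights), 1, tolerance = 1e-12)
  expect_equal(e$G_sol_ensemble, ensemble_gsol(recs))
  mixed <- rbind(recs, make_records(-1, species = "other"))
  expect_error(species_ensemble(mixed), "one species")
})
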