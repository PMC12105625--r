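# Shared helpers: small record tables and closed-form model evaluations
# used as independent oracles.

make_records <- function(G, species = "sp", descriptor = NULL) {
  conformer_records(species_id = species,
                    tautomer_id = "t1",
                    conformer_id = sprintf("c%02d", seq_along(G)),
                    G_sol = G, descriptor = descriptor)
}

# closed-form model potentials, written independently of the package's
# potential_result plumbing
oracle_rt_f <- function(T = 298.15) 8.31446 * T / 96485.3

oracle_m3 <- function(E0, Ka_r, Ka_o, pH, T = 298.15) {
  E0 + oracle_rt_f(T) * log((10^(-pH) + Ka_r) / (10^(-pH) + Ka_o))
}

oracle_m4 <- function(E0, Ka_r, Ka_o, pH, T = 298.15) {
  E0 + oracle_rt_f(T) * log(Ka_o / Ka_r) +
    2 * oracle_rt_f(T) * log((10^(-pH) + Ka_r) / (10^(-pH) + Ka_o))
}

# normal-equations least squares, independent of stats::lm
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r_squared = sxy^2 / (sxx * sum((y - mean(y))^2)))
}
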