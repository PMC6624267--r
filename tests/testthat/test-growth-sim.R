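test_that("monomers are conserved and trajectories are deterministic", {
  p <- kinetic_params(t_end = 120, n_samples = 61)
  tr <- simulate_polymerization(p, species_spec("WT", 400), rng_seed = 7)
  s <- tr$samples
  expect_true(all(s$free_WT + s$poly_WT == 400))
  expect_gt(tr$n_events, 0)
  tr2 <- simulate_polymerization(p, species_spec("WT", 400), rng_seed = 7)
  expect_identical(tr$samples, tr2$samples)
  expect_identical(tr$filaments, tr2$filaments)
  tr3 <- simulate_polymerization(p, species_spec("WT", 400), rng_seed = 8)
  expect_false(identical(tr$samples, tr3$samples))
})

test_that("degenerate inputs give the documented static behavior", {
  p <- kinetic_params(t_end = 50, n_samples = 11)
  # zero monomers, one seed: polymer mass constant
  tr <- simulate_polymerization(p, list(), seeds = list(list(length = 6)),
                                rng_seed = 1)
  expect_true(all(tr$samples$polymer_mass == 6))
  expect_equal(tr$n_events, 0L)
  # no nucleation, no seeds: supersaturated steady state, zero polymer
  p0 <- kinetic_params(k_nuc = 0, t_end = 50, n_samples = 11)
  tr0 <- expect_warning(
    simulate_polymerization(p0, species_spec("WT", 300), rng_seed = 1),
    "static")
  expect_true(all(tr0$samples$polymer_mass == 0))
  expect_error(simulate_polymerization(p, list()), "at least one")
})

test_that("pure elongation of a single seed matches the exponential-depletion mean", {
  # one uncapped seed, no nucleation: each free monomer joins independently
  # at rate k_on, so E[added by t] = A0 * (1 - exp(-k_on * t))
  k_on <- 1e-3; A0 <- 200; t_end <- 25
  p <- kinetic_params(k_nuc = 0, k_on = k_on, t_end = t_end, n_samples = 2)
  added <- vapply(1:200, function(r) {
    tr <- simulate_polymerization(p, species_spec("WT", A0),
                                  seeds = list(list(length = 4)),
                                  rng_seed = 1000 + r)
    tr$samples$polymer_mass[2] - 4
  }, numeric(1))
  mu <- A0 * (1 - exp(-k_on * t_end))
  se <- sd(added) / sqrt(length(added))
  expect_lt(abs(mean(added) - mu), 3 * se + 1e-9)
})

test_that("capped filaments never grow and b-ends are the only active ends", {
  p <- kinetic_params(t_end = 150, n_samples = 76)
  sp <- list(species_spec("WT", 300),
             species_spec("capper", 300, b_face_functional = FALSE))
  tr <- simulate_polymerization(p, sp, rng_seed = 11)
  s <- tr$samples
  # conservation per species
  expect_true(all(s$free_WT + s$poly_WT == 300))
  expect_true(all(s$free_capper + s$poly_capper == 300))
  # capped fraction is non-decreasing (capping is irreversible)
  expect_true(all(diff(s$capped_fraction * s$n_filaments) >= -1e-9))
  # every capped filament ends in a capper and never re-grows: final state
  # has capped filaments, and polymer mass of capped subset never decreased
  expect_gt(sum(tr$filaments$capped), 0)
  # a-dead monomers are never incorporated (they cannot bind the b-end)
  sp2 <- list(species_spec("WT", 300),
              species_spec("adead", 300, a_face_functional = FALSE))
  tr2 <- simulate_polymerization(p, sp2, rng_seed = 11)
  expect_true(all(tr2$samples$poly_adead == 0))
})

test_that("b-dead cappers suppress growth, a-dead mutants do not", {
  p <- kinetic_params(t_end = 120, n_samples = 25)
  cb <- capping_assay(p, 400, "b_dead", ratio = 1, n_replicates = 30,
                      base_seed = 100)
  expect_true(cb$significant)
  expect_lt(cb$effect$treated_mean, cb$effect$control_mean)
  expect_gt(mean(cb$endpoint$treated_capped_fraction), 0.5)
  ca <- capping_assay(p, 400, "a_dead", ratio = 1, n_replicates = 30,
                      base_seed = 100)
  expect_false(ca$significant)
  # ratio 0 is identical to control under matched seeds
  c0 <- capping_assay(p, 400, "b_dead", ratio = 0, n_replicates = 5,
                      base_seed = 3)
  expect_equal(c0$endpoint$control_wt_poly, c0$endpoint$treated_wt_poly)
})

test_that("seeding shortens the lag and lag shrinks with faster nucleation", {
  p <- kinetic_params(t_end = 250, n_samples = 126)
  sa <- seeded_nucleation_assay(p, seed_count = 10, monomer_count = 500,
                                n_replicates = 10, base_seed = 40)
  expect_lt(sa$median_seeded, sa$median_unseeded)
  # seed_count 0 reduces to the plain simulation
  sa0 <- seeded_nucleation_assay(p, seed_count = 0, monomer_count = 500,
                                 n_replicates = 3, base_seed = 40)
  expect_equal(sa0$lags$seeded, sa0$lags$unseeded)
  # median unseeded lag is monotone non-increasing in k_nuc
  lags <- vapply(c(5e-12, 2e-11, 1e-10), function(kn) {
    pp <- kinetic_params(k_nuc = kn, t_end = 400, n_samples = 201)
    seeded_nucleation_assay(pp, 0, 500, n_replicates = 6,
                            base_seed = 7)$median_unseeded
  }, numeric(1))
  expect_true(all(diff(lags) <= 0))
})
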