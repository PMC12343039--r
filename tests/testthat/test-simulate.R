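test_that("capture weights recover ambient proportions when non-selective", {
  amb <- ambient_assemblage("polar")
  m0 <- capture_model(strength = 0)
  w <- capture_weights(amb$pool$size_um, amb$pool$abundance, 22, m0)
  expect_equal(w, amb$pool$abundance, tolerance = 1e-12)
  # two particles, equal abundance, one inside the window, strength 1
  w2 <- capture_weights(c(9, 3.5), c(0.5, 0.5), 40, capture_model(strength = 1))
  expect_equal(w2, c(2 / 3, 1 / 3))
  expect_equal(sum(w2), 1)
  expect_error(capture_weights(c(5), 0, 20, m0), "degenerate")
})

test_that("in-window capture share is monotone in selectivity strength", {
  amb <- ambient_assemblage("temperate")
  D <- 40
  rel <- amb$pool$size_um / D
  inw <- rel >= 0.2 & rel <= 0.3
  shares <- vapply(c(0, 0.5, 1, 2, 5, 10), function(s) {
    w <- capture_weights(amb$pool$size_um, amb$pool$abundance, D,
                         capture_model(strength = s))
    sum(w[inw])
  }, numeric(1))
  expect_true(all(diff(shares) >= 0))
  expect_gt(shares[length(shares)], shares[1])
})

test_that("simulation is reproducible from the seed", {
  p <- simulation_params(30, seed = 123)
  a <- simulate_ledger(p)
  b <- simulate_ledger(p)
  expect_identical(a$loricae, b$loricae)
  expect_identical(a$observations, b$observations)
  p2 <- simulation_params(30, seed = 124)
  expect_false(identical(simulate_ledger(p2)$observations, a$observations))
  # the generator does not disturb the caller's RNG stream
  set.seed(77); before <- rnorm(3)
  set.seed(77); invisible(simulate_ledger(p)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("a single-taxon ambient yields single-taxon ledgers", {
  amb <- ambient_assemblage(data.frame(
    taxon = "Emiliania", particle_kind = "coccolith", abundance = 1))
  led <- simulate_ledger(simulation_params(25, seed = 4, ambient = amb))
  expect_true(all(led$observations$particle_taxon == "Emiliania"))
})

test_that("non-selective capture converges to the ambient composition", {
  amb <- ambient_assemblage("polar")
  p <- simulation_params(100, seed = 21, ambient = amb,
                         capture = capture_model(strength = 0,
                                                 particles_per_lorica = 100))
  led <- simulate_ledger(p)
  obs <- led$observations
  # recover particle counts (diatom quantities are count x unit biovolume)
  cnt <- obs$quantity
  dia <- obs$quantity_type == "biovolume_um3"
  cnt[dia] <- obs$quantity[dia] /
    loricaballast:::diatom_biovolume(obs$particle_taxon[dia],
                                     obs$particle_kind[dia], led$reference)
  freq <- tapply(cnt, obs$particle_taxon, sum)
  N <- sum(freq)
  pvec <- setNames(amb$pool$abundance, amb$pool$taxon)
  freq <- freq[names(pvec)] / N
  tv <- sum(abs(freq - pvec)) / 2
  expect_lt(tv, 3 * sqrt(sum(pvec * (1 - pvec)) / N))
})

test_that("coccolith scarcity shifts capture to diatom fragments", {
  amb0 <- ambient_assemblage("polar", coccolith_availability = 0)
  p <- simulation_params(500, seed = 31, ambient = amb0,
                         capture = capture_model(scarcity_threshold = 0.5))
  fit <- ballast(simulate_ledger(p))
  expect_equal(sum(fit$estimates$silica_pg) / sum(fit$estimates$total_pg), 1)
  # above the threshold the pool is untouched
  amb1 <- ambient_assemblage("polar", coccolith_availability = 0.9)
  expect_equal(loricaballast:::shifted_pool(amb1, capture_model())$abundance,
               amb1$pool$abundance)
})

test_that("the pipeline recovers the generator's analytic expectation", {
  # non-selective, single-taxon check against the closed form 100 x 4 pg
  amb <- ambient_assemblage(data.frame(
    taxon = "Emiliania", particle_kind = "coccolith", abundance = 1))
  p <- simulation_params(200, seed = 8, ambient = amb,
                         capture = capture_model(strength = 0,
                                                 particles_per_lorica = 100))
  r <- recovery_experiment(p)
  expect_equal(r$expected[r$quantity == "total_pg"], 400)
  expect_lt(abs(r$z[r$quantity == "total_pg"]), 3)
  # mixed ambient with selectivity
  p2 <- simulation_params(200, seed = 15,
                          ambient = ambient_assemblage("temperate"),
                          capture = capture_model(strength = 1))
  r2 <- recovery_experiment(p2)
  expect_true(all(abs(r2$z) < 3))
  # degenerate count distribution
  p0 <- simulation_params(100, seed = 2,
                          capture = capture_model(particles_per_lorica = 0))
  r0 <- recovery_experiment(p0)
  expect_equal(r0$expected, c(0, 0))
  expect_equal(r0$estimated, c(0, 0))
  expect_equal(r0$z, c(0, 0))
})

test_that("generated datasets always pass ledger validation", {
  for (seed in c(1, 2)) {
    for (region in c("polar", "temperate", "tropical")) {
      led <- simulate_ledger(simulation_params(
        10, seed = seed, ambient = ambient_assemblage(region),
        capture = capture_model(count_model = "nbinom")))
      expect_silent(validate_ledger(led))
    }
  }
})
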