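test_that("fixtures load with the documented group sizes", {
  t2 <- load_fixture("table2")
  expect_equal(nrow(t2$loricae), 11L)
  expect_equal(sum(t2$loricae$n_loricae), 11L)
  t4 <- load_fixture("table4")
  expect_equal(sum(t4$loricae$locality == "Tonga"), 9L)
  t3 <- load_fixture("table3_atlantic")
  expect_equal(sum(t3$loricae$n_loricae), 35L)
  expect_equal(sum(load_fixture("table3_sots")$loricae$n_loricae), 13L)
  t5 <- load_fixture("table5")
  expect_equal(sum(t5$loricae$n_loricae), 26L)
  expect_error(load_fixture("table9"), "unknown fixture")
})

test_that("ledgers round-trip through CSV", {
  for (led in list(load_fixture("table2"), load_fixture("table5"))) {
    d <- tempfile()
    write_ledger(led, d)
    back <- read_ledger(d)
    expect_equal(back$loricae, led$loricae)
    expect_equal(back$observations, led$observations)
    expect_equal(back$occurrences, led$occurrences)
  }
})

test_that("simulated ledgers round-trip through CSV (property)", {
  for (seed in c(3, 17)) {
    led <- simulate_ledger(simulation_params(20, seed = seed,
                                             ambient = ambient_assemblage("polar")))
    d <- tempfile()
    write_ledger(led, d, header = "provenance line")
    back <- read_ledger(d)
    expect_equal(back$loricae, led$loricae)
    expect_equal(back$observations, led$observations)
  }
})

test_that("single-file ledgers with a record_type column are accepted", {
  led <- toy_ledger()
  f <- tempfile(fileext = ".csv")
  lor <- led$loricae
  obs <- led$observations
  lor[setdiff(names(obs), names(lor))] <- NA
  obs[setdiff(names(lor), names(obs))] <- NA
  combined <- rbind(cbind(record_type = "lorica", lor[union(names(lor), names(obs))]),
                    cbind(record_type = "observation", obs[union(names(lor), names(obs))]))
  write.csv(combined, f, row.names = FALSE)
  back <- read_ledger(f)
  expect_equal(nrow(back$loricae), 2L)
  expect_equal(sort(back$observations$quantity), sort(obs$quantity))
})

test_that("an empty observations table is a valid ledger", {
  led <- lorica_ledger(
    data.frame(lorica_id = "L1", tintinnid_taxon = "T", locality = "X",
               region_class = "polar"),
    data.frame())
  expect_equal(nrow(led$observations), 0L)
  fit <- ballast(led)
  expect_equal(fit$estimates$total_pg, 0)
})

test_that("validation reports the offending row", {
  lor <- toy_ledger()$loricae
  obs <- toy_ledger()$observations
  bad <- obs; bad$quantity[2] <- -1
  expect_error(lorica_ledger(lor, bad), "row 2.*non-negative")
  bad <- lor; bad$lorica_id[2] <- "A"
  expect_error(lorica_ledger(bad, obs), "duplicate lorica_id")
  bad <- obs; bad$particle_taxon[3] <- "Mysterococcus"
  expect_error(lorica_ledger(lor, bad), "Mysterococcus")
  bad <- obs; bad$quantity_type[1] <- "biovolume_um3"
  expect_error(lorica_ledger(lor, bad), "coccoliths take")
  bad <- obs; bad$quantity[1] <- 10.5
  expect_error(lorica_ledger(lor, bad), "integer")
  bad <- obs; bad$lorica_id[1] <- "ZZ"
  expect_error(lorica_ledger(lor, bad), "unknown lorica_id")
  bad <- lor; bad$region_class[1] <- "abyssal"
  expect_error(lorica_ledger(bad, obs), "region_class")
})

test_that("known discrepancies table matches the shipped fixtures", {
  kd <- known_discrepancies()
  expect_true(all(kd$fixture %in% c("table2", "table3_atlantic", "table3_sots",
                                    "table4", "table5")))
  for (i in seq_len(nrow(kd))) {
    led <- load_fixture(kd$fixture[i])
    j <- match(kd$lorica_id[i], led$loricae$lorica_id)
    expect_false(is.na(j))
    expect_equal(led$loricae$printed_total_pg[j], kd$printed_total_pg[i])
  }
})
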