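test_that("summary rendering mirrors the published table layout", {
  s <- summarize_assemblage(ballast(load_fixture("table2")))
  md <- render_summary_table(s)
  expect_true(any(grepl("445 ± 461", md, fixed = TRUE)))
  expect_true(any(grepl("n = 11", md)))
  df <- render_summary_table(s, format = "csv")
  expect_equal(df[["Coscinodiscus"]], "6 of 11")
  expect_equal(df[["Eucampia"]], "2 of 11")
  # occurrence-only coccolith cells render as "x of n" too
  s5 <- summarize_assemblage(ballast(load_fixture("table5")),
                             group_by = "locality")
  df5 <- render_summary_table(s5, format = "csv")
  sots <- grepl("Southern Ocean", df5$group)
  expect_equal(df5[["Helicosphaera"]][sots], "10 of 18")
  # a single-lorica group has sd 0
  s1 <- summarize_assemblage(ballast(load_fixture("table3_sots")))
  expect_true(grepl("± 0", render_summary_table(s1, format = "csv")[["total pg/lorica"]]))
})

test_that("full analysis writes a deterministic, complete bundle", {
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  r1 <- suppressWarnings(run_full_analysis(
    run_config(fixture = "table2", out_dir = d1, seed = 7)))
  r2 <- suppressWarnings(run_full_analysis(
    run_config(fixture = "table2", out_dir = d2, seed = 7)))
  expect_setequal(names(r1$paths),
                  c("ballast", "summary", "matrix_occurrence", "matrix_share",
                    "report"))
  for (nm in names(r1$paths)) {
    expect_true(file.exists(r1$paths[nm]))
    expect_identical(readLines(r1$paths[nm]), readLines(r2$paths[nm]),
                     info = nm)
  }
  rep <- readLines(r1$paths["report"])
  expect_true(any(grepl("n = 11", rep)))
  expect_true(any(grepl("445 ± 461", rep, fixed = TRUE)))
})

test_that("table5 grouped by locality yields the three regional groups", {
  d <- file.path(tempdir(), "bundle5")
  r <- suppressWarnings(run_full_analysis(
    run_config(fixture = "table5", group_by = "locality", out_dir = d)))
  expect_equal(nrow(r$summary$groups), 3L)
  expect_setequal(r$summary$groups$group,
                  c("Southern Ocean Time Series", "Indian Ocean", "Tonga"))
})

test_that("run configuration demands exactly one input source", {
  expect_error(run_config(out_dir = tempdir()), "exactly one")
  expect_error(run_config(fixture = "table2", input = "x", out_dir = tempdir()),
               "exactly one")
})

test_that("the command-line wrapper runs end-to-end on a fixture", {
  skip_if_not_installed("optparse")
  cli <- system.file("cli", "ballast.R", package = "loricaballast")
  out <- file.path(tempdir(), "cli_out")
  libs <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  res <- system2("Rscript", c(cli, "report", "--fixture", "table2",
                              "--out", out, "--log-level", "quiet"),
                 stdout = TRUE, stderr = TRUE, env = libs)
  expect_equal(attr(res, "status") %||% 0L, 0L)
  expect_true(file.exists(file.path(out, "report.md")))
  bad <- suppressWarnings(
    system2("Rscript", c(cli, "compute"), stdout = TRUE, stderr = TRUE,
            env = libs))
  expect_false(is.null(attr(bad, "status")))
})
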