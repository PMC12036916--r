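test_that("the baseline scenario carries the stated numerical assignments", {
  sc <- baseline_scenario()
  p <- sc$params
  expect_equal(p$rho, 0.9)
  expect_equal(p$delta, 0.1)
  expect_equal(p$l, 1)
  expect_equal(p$betaS, 1.5)
  expect_equal(p$cS, 3)
  expect_equal(p$CI, 3)
  expect_equal(p$bI, 2.5)
  expect_equal(c(p$a1, p$a2), c(2, 2))
  expect_equal(p$aS, 1.2)
  expect_equal(p$CO, 10)
  expect_equal(c(p$x0_gov, p$x0_ent), c(1, 1))
  expect_equal(c(p$c1, p$c2), c(2, 2))
  expect_equal(sc$sweep$c_unit, c(2, 4))
  expect_equal(baseline_scenario(c_unit = 4)$params$c1, 4)
})

test_that("scenario generation is deterministic, validated, and annotated", {
  a <- generate_scenarios(25, seed = 123)
  b <- generate_scenarios(25, seed = 123)
  expect_identical(a, b)
  expect_length(a, 25L)
  for (sc in a) {
    expect_s3_class(validate_parameters(sc$params), "game_parameters")
    expect_identical(sc$bI_exceeds_CI, sc$params$bI >= sc$params$CI)
  }
  # a different seed gives a different batch
  expect_false(identical(generate_scenarios(25, seed = 124), a))
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- stats::runif(1)
  set.seed(99); invisible(generate_scenarios(3, seed = 5))
  expect_identical(stats::runif(1), before)
  # invalid ranges are rejected up front
  rng <- pestgame:::.default_ranges()
  rng$c1 <- c(0, 4)
  expect_error(generate_scenarios(5, seed = 1, ranges = rng),
               "positive lower bound")
  rng <- pestgame:::.default_ranges()
  rng$delta <- NULL
  expect_error(generate_scenarios(5, seed = 1, ranges = rng), "missing")
})

test_that("scenario JSON round-trips with a strict schema", {
  sc <- baseline_scenario()
  path <- withr::local_tempfile(fileext = ".json")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_identical(back$name, sc$name)
  expect_equal(unclass(back$params), unclass(sc$params))
  # unknown top-level keys are rejected
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$surprise <- 1
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw, path2, auto_unbox = TRUE, digits = NA)
  expect_error(read_scenario(path2), "unknown scenario key")
  # unknown parameter fields are rejected by validation
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$surprise <- NULL
  raw$params$bogus <- 1
  jsonlite::write_json(raw, path2, auto_unbox = TRUE, digits = NA)
  expect_error(read_scenario(path2), "unknown parameter field")
})

test_that("run_report writes a passing, reproducible bundle with embedded checks", {
  sc <- baseline_scenario()
  dir1 <- withr::local_tempdir()
  rep1 <- run_report(sc, dir1, b_grid = seq(0, 10, length.out = 11),
                     oracle_dt = 0.01)
  expect_true(rep1$passed)
  expect_setequal(
    list.files(dir1),
    c("equilibria.csv", "comparison_government.csv",
      "comparison_enterprise.csv", "summary.json"))
  # every embedded check carries residuals and the oracle error
  for (ch in rep1$checks) {
    expect_lt(abs(ch$slope_residual), 1e-10)
    expect_lt(abs(ch$const_residual), 1e-10)
    expect_lt(ch$oracle_rel_err, 1e-3)
    expect_true(ch$ok)
  }
  # the comparison table for cost 2 matches the decomposition directly
  tab <- utils::read.csv(file.path(dir1, "comparison_government.csv"))
  s <- solve_value(reduce_mode("A", "government", sc$params), b = 10,
                   x = 1, params = sc$params)
  expect_equal(tab$V_A[tab$b == 10], s$value, tolerance = 1e-9)
  # a second run is byte-identical (no timestamps in the content)
  dir2 <- withr::local_tempdir()
  run_report(sc, dir2, b_grid = seq(0, 10, length.out = 11),
             oracle_dt = 0.01)
  expect_identical(readLines(file.path(dir1, "summary.json")),
                   readLines(file.path(dir2, "summary.json")))
})

test_that("the CLI dispatches, overrides parameters, and signals failure codes", {
  expect_identical(pest_cli(character(0)), 0L)
  out <- capture.output(status <- suppressMessages(pest_cli("reproduce")),
                        type = "output")
  expect_identical(status, 0L)
  expect_true(any(grepl("match", out)))
  # --set override flows into the solve table
  out <- capture.output(
    status <- pest_cli(c("solve", "--set", "b1=3", "--c", "4")))
  expect_identical(status, 0L)
  expect_true(any(grepl("government", out)))
  # validation failure -> exit code 1
  expect_identical(suppressMessages(pest_cli(c("validate", "--set", "rho=0"))),
                   1L)
  expect_identical(suppressMessages(pest_cli("frobnicate")), 1L)
  # compare and regions run end to end
  dir <- withr::local_tempdir()
  out <- capture.output(
    status <- pest_cli(c("regions", "--player", "enterprise", "--out", dir)))
  expect_identical(status, 0L)
  expect_true(file.exists(file.path(dir, "regions_enterprise.csv")))
})
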