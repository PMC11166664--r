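test_that("an empty configuration file resolves to the full default scenario", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", f)
  cfg <- load_config(f)
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$scenario, "paper_rupture")
  expect_equal(cfg$geometry$length, 0.7)
  expect_equal(cfg$geometry$height, 0.09)
  expect_equal(cfg$flow$p_out, 13000)
  expect_equal(cfg$flow$p_rupture, 12990)
  expect_equal(cfg$thermal$T_inlet, 310)
  expect_equal(cfg$output$times, c(0, 0.4, 0.8, 1.2, 2.4))
})

test_that("unknown keys and inconsistent configurations are hard errors", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("flow:\n  v_zero: 0.1", f)
  expect_error(load_config(f), "unknown configuration key: flow\\$v_zero")
  writeLines("geometry:\n  mode: axisymmetric", f)
  expect_error(load_config(f), "axisymmetry")
  writeLines("output:\n  times: [0, 5.0]", f)
  expect_error(load_config(f), "t_end")
})

test_that("configurations round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("flow:\n  v0: 0.05\nmesh:\n  h_max: 0.02", f)
  cfg <- load_config(f)
  f2 <- withr::local_tempfile(fileext = ".yaml")
  dump_config(cfg, f2)
  cfg2 <- load_config(f2)
  cfg$scenario <- NULL; cfg2$scenario <- NULL
  expect_equal(unclass(cfg), unclass(cfg2))
})

test_that("the builtin registry carries the documented scenarios", {
  reg <- builtin_scenarios()
  expect_true(all(c("paper_rupture", "paper_rupture_no_particles",
                    "poiseuille_channel", "poiseuille_tube_axisym",
                    "uniform_thermal", "conduction_strip",
                    "mms_convergence") %in% names(reg)))
  a <- reg$paper_rupture; b <- reg$paper_rupture_no_particles
  # the two study scenarios differ only in the particle loading
  expect_false(isTRUE(all.equal(a, b)))
  a$materials$phi1 <- 0; a$materials$phi2 <- 0
  expect_equal(a, b)
})

test_that("transient scenarios are deterministic end to end", {
  ov <- function(dir) list(solver = list(t_end = 0.05),
                           mesh = list(h_max = 0.025),
                           output = list(times = c(0, 0.05), dir = dir))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_scenario("paper_rupture", overrides = ov(d1))
  r2 <- run_scenario("paper_rupture", overrides = ov(d2))
  f1 <- file.path(d1, "extremes.csv"); f2 <- file.path(d2, "extremes.csv")
  expect_identical(readLines(f1), readLines(f2))
  l1 <- file.path(d1, "run_log.csv"); l2 <- file.path(d2, "run_log.csv")
  expect_identical(readLines(l1), readLines(l2))
})

test_that("scenario stage errors are labelled with the failing stage", {
  expect_error(
    run_scenario("paper_rupture",
                 overrides = list(materials = list(phi1 = 0.9))),
    "below")
  expect_error(run_scenario("no_such_scenario"), "unknown scenario")
})

test_that("the convergence-study scenario emits observed orders", {
  r <- run_scenario("mms_convergence")
  expect_true(all(r$verdicts$pass))
  expect_s3_class(r$mms, "tbl_df")
  expect_true(all(c("order_u", "order_p") %in% names(r$mms)))
  expect_true(all(is.finite(r$mms$order_u[-1])))
})

test_that("run reports tidy into tables and glance into a one-row summary", {
  r <- run_scenario("conduction_strip")
  expect_true(all(r$verdicts$pass))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  g <- glance(r)
  expect_equal(nrow(g), 1L)
  expect_equal(g$scenario, "conduction_strip")
  expect_equal(g$checks_passed, g$checks_total)
})
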