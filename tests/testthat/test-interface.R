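test_that("measurement CSVs round-trip through write and read", {
  meas <- generate_measurements(tt_model(), 0.3, n_replicates = 2,
                                noise_cv = 0.05, seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_measurement_csv(meas, f, table_checksum = tt_model()$table_checksum)
  back <- read_measurement_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(meas), tolerance = 1e-12)
  expect_match(readLines(f, n = 2)[2], "transition_table_checksum")
})

test_that("malformed measurement files are rejected with the row cited", {
  write_csv_lines <- function(lines) {
    f <- tempfile(fileext = ".csv")
    writeLines(lines, f)
    f
  }
  f <- write_csv_lines(c(
    "replicate,metabolite,mass_shift,peak_area",
    "1,malate,0,100",
    "1,fumarate,0,50"
  ))
  expect_error(read_measurement_csv(f), "Row 2.*fumarate.*Allowed")
  f <- write_csv_lines(c(
    "replicate,metabolite,mass_shift,peak_area",
    "1,malate,0,-5"
  ))
  expect_error(read_measurement_csv(f), "Row 1.*negative")
  f <- write_csv_lines(c(
    "replicate,metabolite,mass_shift,peak_area",
    "1,malate,0,10",
    "1,malate,0,20"
  ))
  expect_error(read_measurement_csv(f), "Row 2.*duplicate")
  f <- write_csv_lines(c("replicate,metabolite,peak_area", "1,malate,10"))
  expect_error(read_measurement_csv(f), "mass_shift")
})

test_that("cli: predict at alpha 0 emits only unlabelled mass", {
  out <- withr::local_tempfile(fileext = ".csv")
  status <- suppressMessages(
    tca_cli(c("predict", "--alpha", "0", "--out", out))
  )
  expect_identical(status, 0L)
  d <- tcatrace:::read_stamped_csv(out)
  expect_true(all(d$proportion[d$mass_shift == 0] == 1))
  expect_true(all(d$proportion[d$mass_shift > 0] == 0))
})

test_that("cli: scan with step 0.25 yields 5 grid values per series", {
  out <- withr::local_tempfile(fileext = ".csv")
  status <- suppressMessages(
    tca_cli(c("scan", "--step", "0.25", "--out", out))
  )
  expect_identical(status, 0L)
  d <- tcatrace:::read_stamped_csv(out)
  expect_identical(length(unique(d$alpha)), 5L)
  counts <- table(d$metabolite, d$mass_shift)
  expect_true(all(counts[counts > 0] == 5))
})

test_that("cli: synth then fit recovers the generating alpha", {
  dir <- withr::local_tempdir()
  synth_csv <- file.path(dir, "synth.csv")
  report <- file.path(dir, "fit.json")
  status <- suppressMessages(tca_cli(c(
    "synth", "--alpha", "0.3", "--replicates", "2", "--noise-cv", "0",
    "--seed", "5", "--out", synth_csv
  )))
  expect_identical(status, 0L)
  status <- suppressMessages(suppressWarnings(tca_cli(c(
    "fit", "--input", synth_csv, "--labelled-fraction", "1",
    "--grid-step", "0.01", "--out", report
  ))))
  expect_identical(status, 0L)
  rep <- jsonlite::read_json(report, simplifyVector = TRUE)
  expect_equal(rep$summary$alpha_mean, 0.3, tolerance = 1e-5)
  expect_equal(rep$summary$contribution_percent, 30, tolerance = 1e-3)
  expect_identical(nrow(rep$per_replicate), 2L)
  expect_match(rep$transition_table_checksum, "^[0-9a-f]{32}$")
})

test_that("cli: enumerate exports the state space and logs the checksum", {
  out <- withr::local_tempfile(fileext = ".csv")
  msgs <- capture.output(
    status <- tca_cli(c("enumerate", "--out", out)),
    type = "message"
  )
  expect_identical(status, 0L)
  expect_true(any(grepl("checksum", msgs)))
  d <- tcatrace:::read_stamped_csv(out)
  expect_identical(nrow(d), nrow(tidy(tt_space())))
})

test_that("cli: outputs are byte-identical across repeat runs", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  suppressMessages(tca_cli(c(
    "simulate", "--alpha", "0.5", "--molecules", "1000",
    "--turns", "20", "--seed", "9", "--out", f1
  )))
  suppressMessages(tca_cli(c(
    "simulate", "--alpha", "0.5", "--molecules", "1000",
    "--turns", "20", "--seed", "9", "--out", f2
  )))
  expect_identical(readLines(f1), readLines(f2))
})

test_that("cli: bad invocations exit nonzero with a one-line diagnostic", {
  expect_identical(
    suppressMessages(tca_cli(c("frobnicate"))), 1L
  )
  expect_identical(suppressMessages(tca_cli(character(0))), 1L)
  expect_identical(
    suppressMessages(tca_cli(c("predict", "--alpha"))), 1L
  )
  msgs <- capture.output(
    status <- tca_cli(c("fit", "--input", "/no/such/file.csv",
                        "--out", tempfile())),
    type = "message"
  )
  expect_identical(status, 1L)
  expect_true(any(grepl("No such file", msgs)))
})

test_that("plot builders return ggplot objects without evaluation errors", {
  scan <- bifurcation_scan(tt_model(), grid_step = 0.1)
  p1 <- autoplot(scan)
  expect_s3_class(p1, "ggplot")
  meas <- generate_measurements(tt_model(), 0.3, n_replicates = 2,
                                noise_cv = 0.05, seed = 2)
  fit <- fit_alpha(meas, tt_model(), labelled_fraction = 1,
                   grid_predictions = tt_grid(0.01))
  p2 <- autoplot(fit, tt_model(), meas)
  expect_s3_class(p2, "ggplot")
  p3 <- plot_isotopologues(predict_isotopologues(tt_model(), 0.4))
  expect_s3_class(p3, "ggplot")
  # force evaluation of layer data
  expect_silent(invisible(ggplot2::ggplot_build(p1)))
  expect_silent(invisible(ggplot2::ggplot_build(p2)))
})
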