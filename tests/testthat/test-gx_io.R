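# Table ingest, unit handling, and report serialisation.

test_that("canonical CSV parses into ordered response curves", {
  path <- write_fixture_csv(tempfile(fileext = ".csv"))
  curves <- read_gas_exchange_table(path)
  expect_length(curves, 2)
  expect_equal(vapply(curves, function(cv) cv$replicate, character(1)),
               c("r1", "r2"))
  expect_equal(nrow(curves[[1]]$data), 3)
  # file row order preserved: Ca sequence as written
  expect_equal(curves[[1]]$data$Ca, c(400, 600, 800))
  # gsc derived from gsw by the 1.6 diffusivity ratio
  expect_equal(curves[[1]]$data$gsc, curves[[1]]$data$gsw / 1.6)
})

test_that("instrument headers map through the bundled LI-6400 map", {
  path <- write_fixture_csv(tempfile(fileext = ".csv"), headers = "li6400")
  curves <- read_gas_exchange_table(path, li6400_column_map())
  expect_length(curves, 1)
  df <- curves[[1]]$data
  expect_equal(df$An, c(10, 9, 8))
  expect_equal(df$hr, c(0.60, 0.62, 0.58))  # percent-scaled at ingest
  expect_equal(df$I, c(1000, 800, 600))
})

test_that("mandatory-column and parse errors are addressed precisely", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("species,replicate,protocol,I,Ca,Ci,An",
               "sp1,r1,light,1000,400,300,10"), path)
  expect_error(read_gas_exchange_table(path), "gsw or gsc")

  path2 <- tempfile(fileext = ".csv")
  writeLines(c("species,replicate,protocol,I,Ca,Ci,An,gsw",
               "sp1,r1,light,1000,400,300,10,0.3",
               "sp1,r1,light,800,400,300,oops,0.28",
               "sp1,r1,light,600,400,300,8,0.25"), path2)
  expect_error(read_gas_exchange_table(path2), "row 3")
})

test_that("undersized groups are skipped with a warning", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("species,replicate,protocol,I,Ca,Cs,Ci,An,gsw",
               "sp1,r1,light,1000,420,420,300,10,0.3",
               "sp1,r1,light,800,420,420,310,9,0.28",
               "sp1,r1,light,600,420,420,320,8,0.26",
               "sp2,r1,light,1000,420,420,300,11,0.31"), path)
  expect_warning(curves <- read_gas_exchange_table(path), "fewer than 3")
  expect_length(curves, 1)
  expect_equal(curves[[1]]$species, "sp1")
})

test_that("missing Cs falls back to Ca with a warning", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("species,replicate,protocol,I,Ca,Ci,An,gsw",
               "sp1,r1,light,1000,420,300,10,0.3",
               "sp1,r1,light,800,420,310,9,0.28",
               "sp1,r1,light,600,420,320,8,0.26"), path)
  expect_warning(curves <- read_gas_exchange_table(path), "Cs")
  expect_equal(curves[[1]]$data$Cs, rep(420, 3))
})

test_that("gsw/gsc conversion applies the 1.6 diffusivity ratio", {
  expect_equal(convert_gsw_to_gsc(0.32), 0.20)
  expect_equal(convert_gsw_to_gsc(0), 0)
  expect_equal(convert_gsw_to_gsc(1.6), 1.0)
  expect_error(convert_gsw_to_gsc(-0.1), "non-negative")
})

test_that("curves round-trip through the canonical CSV to 6 significant digits", {
  cfg <- simulation_config(
    "sp", gs_model_spec("bwb", g0 = 0.05, g1 = 4), demand_params(),
    protocol = list(kind = "light", levels = light_protocol(), Ca = 420),
    noise_sd_An = 0.2, noise_sd_gsc = 0.005, n_replicates = 2, seed = 9
  )
  curves <- simulate_response_curve(cfg)
  path <- tempfile(fileext = ".csv")
  write_gas_exchange_table(curves, path)
  back <- read_gas_exchange_table(path)
  expect_length(back, length(curves))
  for (i in seq_along(curves)) {
    for (col in c("I", "Ca", "Ci", "An", "gsc", "hr", "D")) {
      expect_equal(back[[i]]$data[[col]], curves[[i]]$data[[col]],
                   tolerance = 1e-7)
    }
  }
})

test_that("fit reports round-trip through CSV and JSON", {
  rows <- data.frame(
    species = rep(c("a", "b", "c"), each = 3),
    model = rep(c("bwb", "medlyn", "ye"), 3),
    g0_mean = runif(9, -0.3, 0.1), g0_se = runif(9, 0, 0.05),
    g0_letter = "a",
    g1_mean = runif(9, 0.5, 30), g1_se = runif(9, 0, 3),
    r2_adj = runif(9, 0.7, 1), aic = runif(9, 3, 30),
    n_replicates = 3L, stringsAsFactors = FALSE
  )
  for (fmt in c("csv", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_fit_report(rows, path, fmt)
    back <- read_fit_report(path, fmt)
    expect_equal(nrow(back), 9)
    for (col in c("g0_mean", "g1_mean", "r2_adj", "aic")) {
      expect_equal(back[[col]], rows[[col]], tolerance = 1e-7)
    }
  }
  # degenerate: empty table gives a header-only CSV
  empty <- rows[0, ]
  path <- tempfile(fileext = ".csv")
  write_fit_report(empty, path, "csv")
  expect_equal(nrow(read_fit_report(path, "csv")), 0)
  expect_length(readLines(path), 1)
})

test_that("record invariants are enforced at construction", {
  expect_error(
    response_curve("s", "r", "co2",
                   data.frame(I = 1000, Ca = c(400, 500, 600),
                              Ci = c(300, 380, 450), An = c(10, 12, 14),
                              gsw = c(0.3, 0.3, 0.3), gsc = c(0.2, 0.2, 0.2))),
    "gsw = 1.6 gsc")
  expect_error(
    response_curve("s", "r", "co2",
                   data.frame(I = 1000, Ca = c(400, 500, 600),
                              Ci = c(450, 380, 450), An = c(10, 12, 14),
                              gsw = c(0.32, 0.32, 0.32))),
    "Ci > Ca")
  expect_error(
    response_curve("s", "r", "light",
                   data.frame(I = c(0, 500, 1000), An = c(-1, 5, 8),
                              gsc = 0.2, hr = c(0.5, 0.6, 1.7))),
    "hr")
})

test_that("column maps load from YAML and JSON configs", {
  ypath <- tempfile(fileext = ".yaml")
  writeLines(c("columns:", "  An: Photo", "  gsw: Cond", "percent:", "  - hr"),
             ypath)
  cm <- read_column_map(ypath)
  expect_equal(unname(cm$columns["An"]), "Photo")
  expect_equal(cm$percent, "hr")
})
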