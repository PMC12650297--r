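# Parameter estimation: linear initialisation, nonlinear least squares,
# diagnostics, and replicate aggregation.

test_that("linearised initialisation recovers noise-free ye parameters", {
  spec <- gs_model_spec("ye", g0 = -0.002, g1 = 0.727)
  curve <- noise_free_design(spec, design_grid("ye"))
  init <- linearized_init(curve, "ye")
  expect_equal(unname(init["g0"]), -0.002, tolerance = 1e-8)
  expect_equal(unname(init["g1"]), 0.727, tolerance = 1e-8)
})

test_that("linearised ye solution matches a brute-force SSE grid", {
  spec <- gs_model_spec("ye", g0 = -0.05, g1 = 0.8)
  curve <- noise_free_design(spec, list(gsc = seq(0.1, 0.5, by = 0.1),
                                        dCa = seq(60, 140, by = 20)))
  df <- curve$data
  set.seed(11)
  df$An <- df$An + rnorm(5, 0, 0.4)
  noisy <- response_curve("sp", "r1", "design", df)
  init <- linearized_init(noisy, "ye")
  best <- grid_oracle("ye", noisy$data,
                      g0_range = init["g0"] + c(-0.02, 0.02),
                      g1_range = init["g1"] + c(-0.02, 0.02), step = 1e-3)
  expect_lt(abs(init["g0"] - best$g0), 1.5e-3)
  expect_lt(abs(init["g1"] - best$g1), 1.5e-3)
})

test_that("rank-deficient designs raise a collinearity error", {
  df <- data.frame(gsc = rep(0.2, 4), Ca = 420, Ci = 320,
                   An = rep(20, 4))
  curve <- response_curve("sp", "r1", "design", df)
  expect_error(linearized_init(curve, "ye"), "collinear")
})

test_that("noise-free fits recover generating parameters across all models", {
  # parameter ranges spanning the fitted-slope and intercept ranges that
  # comparison studies report for these models
  cases <- list(
    list(model = "bwb", g0 = 0.087, g1 = 3.446),
    list(model = "bwb", g0 = -0.28, g1 = 34.391),
    list(model = "medlyn", g0 = 0.018, g1 = 2.214),
    list(model = "medlyn", g0 = -0.586, g1 = 21.427),
    list(model = "ye", g0 = -0.002, g1 = 0.727),
    list(model = "ye", g0 = -0.264, g1 = 1.952)
  )
  set.seed(3)
  for (i in 1:6) {
    cases[[length(cases) + 1L]] <- list(
      model = sample(c("bwb", "medlyn", "ye"), 1),
      g0 = runif(1, -0.6, 0.1), g1 = runif(1, 0.2, 40)
    )
  }
  for (cs in cases) {
    spec <- gs_model_spec(cs$model, g0 = cs$g0, g1 = cs$g1)
    curve <- noise_free_design(spec, design_grid(cs$model))
    fit <- suppressWarnings(fit_gs_model(curve, cs$model))
    expect_lt(abs(fit$g0 - cs$g0), 1e-6)
    expect_lt(abs(fit$g1 - cs$g1), 1e-5)
    expect_equal(fit$r2, 1, tolerance = 1e-9)
    expect_true(is.na(fit$aic))  # perfect fit: AIC undefined
  }
})

test_that("medlyn sqrt variant round-trips through fitting", {
  spec <- gs_model_spec("medlyn", g0 = 0.01, g1 = 3.5,
                        medlyn_variant = "sqrt")
  curve <- noise_free_design(spec, design_grid("medlyn"))
  fit <- fit_gs_model(curve, "medlyn", medlyn_variant = "sqrt")
  expect_lt(abs(fit$g0 - 0.01), 1e-6)
  expect_lt(abs(fit$g1 - 3.5), 1e-5)
})

test_that("NLS optimum equals the closed-form An-space OLS for bwb and ye", {
  for (seed in 1:5) {
    for (model in c("bwb", "ye")) {
      spec <- gs_model_spec(model, g0 = 0.03, g1 = if (model == "bwb") 4 else 0.8)
      curve <- noise_free_design(spec, design_grid(model))
      df <- curve$data
      set.seed(seed)
      df$An <- df$An + rnorm(nrow(df), 0, 0.5)
      noisy <- response_curve("sp", "r1", "design", df)
      fit <- suppressWarnings(fit_gs_model(noisy, model))
      ols <- ols_an_space(model, noisy$data)
      expect_equal(fit$g0, unname(ols["g0"]), tolerance = 1e-8)
      expect_equal(fit$g1, unname(ols["g1"]), tolerance = 1e-8)
    }
  }
})

test_that("fitted SSE never exceeds the brute-force grid oracle's best", {
  for (model in c("bwb", "medlyn", "ye")) {
    spec <- gs_model_spec(model, g0 = 0.02,
                          g1 = if (model == "ye") 0.75 else 3)
    curve <- noise_free_design(spec, design_grid(model))
    df <- curve$data
    set.seed(19)
    df$An <- df$An + rnorm(nrow(df), 0, 0.5)
    noisy <- response_curve("sp", "r1", "design", df)
    fit <- suppressWarnings(fit_gs_model(noisy, model))
    best <- grid_oracle(model, noisy$data,
                        g0_range = fit$g0 + c(-0.05, 0.05),
                        g1_range = fit$g1 + c(-0.05, 0.05), step = 5e-3)
    expect_lte(fit$rss, best$sse + 1e-10)
  }
})

test_that("fits are invariant to record order within a curve", {
  spec <- gs_model_spec("ye", g0 = -0.01, g1 = 0.8)
  curve <- noise_free_design(spec, design_grid("ye"))
  df <- curve$data
  set.seed(5)
  df$An <- df$An + rnorm(nrow(df), 0, 0.3)
  a <- fit_gs_model(response_curve("s", "r", "design", df), "ye")
  b <- fit_gs_model(response_curve("s", "r", "design", df[sample(nrow(df)), ]),
                    "ye")
  expect_equal(a$g0, b$g0, tolerance = 1e-10)
  expect_equal(a$g1, b$g1, tolerance = 1e-10)
  expect_equal(a$rss, b$rss, tolerance = 1e-10)
})

test_that("noisy fits are consistent: mean recovered g1 near truth", {
  spec <- gs_model_spec("ye", g0 = -0.002, g1 = 0.75)
  curve <- noise_free_design(spec, design_grid("ye"))
  g1s <- vapply(1:100, function(s) {
    df <- curve$data
    set.seed(s)
    df$An <- df$An + rnorm(nrow(df), 0, 0.5)
    fit_gs_model(response_curve("s", "r", "design", df), "ye")$g1
  }, numeric(1))
  expect_lt(abs(mean(g1s) - 0.75) / 0.75, 0.02)
})

test_that("adjusted R2 follows its definition and domain", {
  expect_equal(adjusted_r2(1, n = 12, p = 2), 1)
  expect_equal(adjusted_r2(0.9, n = 12, p = 2), 0.87778, tolerance = 1e-5)
  expect_error(adjusted_r2(0.9, n = 3, p = 2), "undefined")
})

test_that("AIC convention n log(RSS/n) + 2k behaves as specified", {
  expect_equal(aic_from_rss(rss = 7, n = 7, k = 3), 6.0)
  expect_equal(aic_from_rss(rss = 20, n = 10, k = 3), 12.9315, tolerance = 1e-4)
  expect_error(aic_from_rss(rss = 0, n = 10), "degenerate")
})

test_that("replicate aggregation computes mean and SE over fits", {
  spec <- gs_model_spec("ye", g0 = 0, g1 = 1)
  base <- noise_free_design(spec, design_grid("ye"))
  mkfit <- function(g1) {
    f <- fit_gs_model(base, "ye")
    f$g1 <- g1
    f
  }
  agg <- aggregate_replicates(lapply(c(1, 2, 3), mkfit))
  expect_equal(agg$g1_mean, 2)
  expect_equal(agg$g1_se, 0.57735, tolerance = 1e-5)

  same <- aggregate_replicates(lapply(c(2, 2, 2), mkfit))
  expect_equal(same$g1_se, 0)

  single <- aggregate_replicates(list(mkfit(1)))
  expect_true(is.na(single$g1_se))

  other <- fit_gs_model(
    noise_free_design(gs_model_spec("bwb", g0 = 0.05, g1 = 3),
                      design_grid("bwb")), "bwb")
  expect_error(aggregate_replicates(list(mkfit(1), other)), "mixed")
})
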