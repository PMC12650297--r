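# Coupled demand/supply simulation and the noise-free design generators.

test_that("photosynthetic demand evaluates its three limitations", {
  p <- demand_params(Vm = 100, K = 300, Gamma = 40, Jmax = 160, I50 = 300,
                     Tp = 12, Rd = 1)
  # at the compensation point both CO2-limited rates vanish
  expect_equal(demand_an(40, 500, p), -1)
  expect_equal(demand_an(40, 2000, p), -1)
  # hand-evaluated electron-transport-limited case
  expect_equal(demand_an(340, 1200, p), 21.857, tolerance = 1e-3)
  # TPU cap at saturating CO2 and light
  expect_equal(demand_an(1e6, 1e6, p), 3 * 12 - 1, tolerance = 1e-3)
})

test_that("steady state matches the closed-form fixed-conductance solution", {
  # linear demand An = 0.1 (Ci - 50) against gsc = 0.2 at Ca = 400:
  # 0.1 (Ci - 50) = 0.2 (400 - Ci)  =>  Ci = 85/0.3
  ss <- steady_state_solve(Ca = 400, I = 1000, hr = 0.6, D = 1.5,
                           gs_spec = gs_model_spec("fick", gsc = 0.2),
                           demand = function(Ci, I) 0.1 * (Ci - 50))
  expect_equal(ss$Ci, 85 / 0.3, tolerance = 1e-6)
  expect_equal(ss$An, 0.1 * (85 / 0.3 - 50), tolerance = 1e-6)
  expect_equal(ss$An, ss$gsc * (400 - ss$Ci), tolerance = 1e-8)
})

test_that("solutions satisfy supply and demand to solver tolerance", {
  p <- demand_params()
  for (spec in list(gs_model_spec("bwb", g0 = 0.05, g1 = 4),
                    gs_model_spec("medlyn", g0 = 0.02, g1 = 2.5),
                    gs_model_spec("fick", gsc = 0.25))) {
    ss <- steady_state_solve(Ca = 420, I = 1200, hr = 0.6, D = 1.4,
                             gs_spec = spec, demand = p)
    expect_lt(abs(demand_an(ss$Ci, 1200, p) - ss$An), 1e-8)
    expect_lt(abs(ss$gsc * (420 - ss$Ci) - ss$An), 1e-8)
  }
})

test_that("the ye spec is admitted only in its Fick reduction", {
  p <- demand_params()
  ss <- steady_state_solve(Ca = 420, I = 1200, hr = 0.6, D = 1.4,
                           gs_spec = gs_model_spec("ye", g0 = 0, g1 = 1,
                                                   gsc = 0.25),
                           demand = p)
  expect_equal(ss$An, ss$gsc * (420 - ss$Ci), tolerance = 1e-8)
  expect_error(
    steady_state_solve(Ca = 420, I = 1200, hr = 0.6, D = 1.4,
                       gs_spec = gs_model_spec("ye", g0 = 0, g1 = 0.8),
                       demand = p),
    "no steady state")
})

test_that("CO2-free air yields respiration: An < 0 and Ci > Ca", {
  ss <- steady_state_solve(Ca = 0, I = 1000, hr = 0.6, D = 1.4,
                           gs_spec = gs_model_spec("fick", gsc = 0.15),
                           demand = demand_params())
  expect_lt(ss$An, 0)
  expect_gt(ss$Ci, 0)
})

test_that("simulated records are Fick-consistent before noise", {
  cfg <- simulation_config(
    "sp", gs_model_spec("bwb", g0 = 0.05, g1 = 4.5), demand_params(),
    protocol = list(kind = "co2", levels = co2_protocol(), I = 1000),
    noise_sd_An = 0, noise_sd_gsc = 0, n_replicates = 1
  )
  cv <- simulate_response_curve(cfg)[[1]]
  df <- cv$data
  expect_lt(max(abs(df$gsc * (df$Ca - df$Ci) - df$An)), 1e-6)
  # generating model holds exactly: refit recovers (g0, g1)
  fit <- fit_gs_model(cv, "bwb")
  expect_lt(abs(fit$g0 - 0.05), 1e-6)
  expect_lt(abs(fit$g1 - 4.5), 1e-6)
})

test_that("An rises with CO2 up to the TPU cap under hyperbolic light form", {
  cfg <- simulation_config(
    "sp", gs_model_spec("bwb", g0 = 0.05, g1 = 4.5), demand_params(),
    protocol = list(kind = "co2", levels = sort(co2_protocol()), I = 1200),
    noise_sd_An = 0, noise_sd_gsc = 0, n_replicates = 1
  )
  df <- simulate_response_curve(cfg)[[1]]$data
  below_cap <- df$An < 3 * 12 - 1 - 1e-6
  expect_true(all(diff(df$An[below_cap]) >= -1e-8))
})

test_that("simulation is deterministic in its seed", {
  cfg <- function(seed) simulation_config(
    "sp", gs_model_spec("bwb", g0 = 0.06, g1 = 4), demand_params(),
    protocol = list(kind = "light", levels = light_protocol(), Ca = 420),
    noise_sd_An = 0.3, noise_sd_gsc = 0.01, n_replicates = 2, seed = seed
  )
  a <- simulate_response_curve(cfg(99))
  b <- simulate_response_curve(cfg(99))
  c <- simulate_response_curve(cfg(100))
  expect_identical(a[[1]]$data, b[[1]]$data)
  expect_identical(a[[2]]$data, b[[2]]$data)
  expect_false(isTRUE(all.equal(a[[1]]$data$An, c[[1]]$data$An)))
  # a seed is required whenever noise is on
  expect_error(
    simulation_config("sp", gs_model_spec("bwb", g0 = 0.06, g1 = 4),
                      demand_params(),
                      noise_sd_An = 0.3, seed = NULL),
    "seed")
})

test_that("protocol sequences match the measurement design", {
  expect_length(light_protocol("L. perenne"), 15)
  expect_length(light_protocol("T. aestivum"), 15)
  expect_length(light_protocol("T. repens"), 13)
  expect_equal(max(light_protocol("T. repens")), 1600)
  expect_length(co2_protocol("L. perenne"), 12)
  expect_length(co2_protocol("T. aestivum"), 11)
  expect_false(1600 %in% co2_protocol("T. aestivum"))
  expect_equal(min(co2_protocol()), 0)
  # sequences run from high to low, as measured
  expect_true(all(diff(light_protocol()) < 0))
  expect_true(all(diff(co2_protocol()) < 0))
})

test_that("noise-free designs satisfy their generating model exactly", {
  spec <- gs_model_spec("ye", g0 = -0.002, g1 = 0.727)
  cv <- noise_free_design(spec, design_grid("ye"))
  expect_equal(nrow(cv$data), 12)
  expect_equal(gsc_forward(spec, cv$data), cv$data$gsc, tolerance = 1e-12)

  # constant gsc leaves (g0, g1) unidentifiable
  expect_error(
    noise_free_design(spec, list(gsc = rep(0.2, 12), dCa = seq(50, 160, 10))),
    "degenerate design")
  # constant D degenerates the medlyn design to a line
  expect_warning(
    noise_free_design(gs_model_spec("medlyn", g0 = 0.02, g1 = 2),
                      list(gsc = seq(0.05, 0.6, 0.05), D = 1.5, Cs = 400)),
    "constant D")
})
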