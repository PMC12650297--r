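# Synthetic gas-exchange generator: a reduced FvCB-style demand curve coupled
# to a stomatal conductance model through the Fick diffusion constraint,
# stepped through LI-6400-style measurement protocols with seeded noise;
# plus noise-free design-grid generators for parameter-recovery experiments.

#' Measurement protocol irradiance sequence
#'
#' The light-level sequence of an An-I protocol, in measurement order (high
#' to low): 15 levels from 2000 to 0 umol m-2 s-1 for the grasses, 13 levels
#' from 1600 to 0 for the clover (whose photosynthesis declines beyond
#' ~1200 umol m-2 s-1, making higher levels uninformative).
#'
#' @param species Species label; a label matching "repens" selects the
#'   13-level clover sequence.
#' @return Numeric vector of irradiance levels, umol photons m-2 s-1.
#' @export
light_protocol <- function(species = "L. perenne") {
  if (grepl("repens", species, ignore.case = TRUE)) {
    c(1600, 1400, 1200, 1000, 800, 600, 400, 200, 150, 100, 80, 50, 0)
  } else {
    c(2000, 1800, 1600, 1400, 1200, 1000, 800, 600, 400, 200, 150, 100, 80,
      50, 0)
  }
}

#' Measurement protocol CO2 sequence
#'
#' The ambient-CO2 sequence of an An-Ci protocol, in measurement order:
#' 12 levels from 1600 down to 0 umol mol-1 (11 for wheat, which omits the
#' 1600 step).
#'
#' @param species Species label; a label matching "aestivum" omits 1600.
#' @return Numeric vector of CO2 levels, umol mol-1.
#' @export
co2_protocol <- function(species = "L. perenne") {
  lv <- c(1600, 1400, 1200, 1000, 800, 600, 420, 300, 200, 100, 60, 0)
  if (grepl("aestivum", species, ignore.case = TRUE)) lv <- setdiff(lv, 1600)
  lv
}

#' Photosynthetic demand parameters
#'
#' Parameters of the reduced FvCB-style demand curve used by the simulator:
#' a three-way minimum of a carboxylation-limited rate (`Vm`, with effective
#' Michaelis constant `K` and CO2 compensation point `Gamma`), an
#' electron-transport-limited rate driven by irradiance (`Jmax` with
#' half-saturation `I50`, or a peaked irradiance response), and a
#' triose-phosphate-utilisation cap (`3 Tp`), minus day respiration `Rd`.
#' This is a deliberately reduced surrogate: it reproduces the qualitative
#' curve shapes (saturation, TPU plateau, optional post-peak light decline)
#' that the downstream conductance-model fitting assumes, not a full FvCB
#' parameterisation.
#'
#' @param Vm Maximum carboxylation-limited rate, umol m-2 s-1.
#' @param K Effective Michaelis constant, umol mol-1.
#' @param Gamma CO2 compensation point, umol mol-1.
#' @param Jmax Maximum electron-transport proxy, umol m-2 s-1.
#' @param I50 Half-saturation irradiance of the hyperbolic light response,
#'   umol photons m-2 s-1.
#' @param Tp Triose-phosphate proxy, umol m-2 s-1.
#' @param Rd Day respiration, umol m-2 s-1.
#' @param light_form `"hyperbolic"` (J saturating in I) or `"peaked"`
#'   (J declining beyond an optimum, via the light-response form with
#'   coefficients `light_beta`, `light_gamma`).
#' @param light_beta,light_gamma Peaked-form coefficients (used only when
#'   `light_form = "peaked"`).
#' @return An object of class `demand_params`.
#' @export
demand_params <- function(Vm = 100, K = 300, Gamma = 40, Jmax = 160,
                          I50 = 300, Tp = 12, Rd = 1,
                          light_form = c("hyperbolic", "peaked"),
                          light_beta = 5e-5, light_gamma = 2e-3) {
  light_form <- match.arg(light_form)
  vals <- c(Vm = Vm, K = K, Gamma = Gamma, Jmax = Jmax, I50 = I50, Tp = Tp,
            Rd = Rd)
  if (any(vals <= 0)) {
    stop("demand parameters must all be positive", call. = FALSE)
  }
  structure(list(Vm = Vm, K = K, Gamma = Gamma, Jmax = Jmax, I50 = I50,
                 Tp = Tp, Rd = Rd, light_form = light_form,
                 light_beta = light_beta, light_gamma = light_gamma),
            class = "demand_params")
}

#' Photosynthetic demand: An at a given intercellular CO2 and irradiance
#'
#' `An = min(Ac, Aj, Ap) - Rd` with
#' `Ac = Vm (Ci - Gamma) / (Ci + K)`,
#' `Aj = J(I)/4 * (Ci - Gamma) / (Ci + 2 Gamma)`, and `Ap = 3 Tp`.
#' `J(I) = Jmax I / (I + I50)` for the hyperbolic light form; the peaked
#' form scales the light-response shape `(1 - beta I) I / (1 + gamma I)` so
#' that its maximum equals `Jmax`.
#'
#' @param Ci Intercellular CO2, umol mol-1 (>= 0). Vectorised.
#' @param I Irradiance, umol photons m-2 s-1 (>= 0).
#' @param params A [demand_params()].
#' @return Net photosynthesis, umol m-2 s-1.
#' @export
demand_an <- function(Ci, I, params) {
  stopifnot(inherits(params, "demand_params"))
  if (any(Ci < 0) || any(I < 0)) {
    stop("Ci and I must be non-negative", call. = FALSE)
  }
  J <- if (params$light_form == "hyperbolic") {
    params$Jmax * I / (I + params$I50)
  } else {
    shape <- function(x) (1 - params$light_beta * x) * x / (1 + params$light_gamma * x)
    xmax <- saturating_irradiance(list(beta = params$light_beta,
                                       gamma = params$light_gamma))
    params$Jmax * shape(I) / shape(xmax)
  }
  Ac <- params$Vm * (Ci - params$Gamma) / (Ci + params$K)
  Aj <- (J / 4) * (Ci - params$Gamma) / (Ci + 2 * params$Gamma)
  Ap <- 3 * params$Tp
  pmin(Ac, Aj, Ap) - params$Rd
}

# conductance implied by a gs spec at a given An and environment, for the
# supply side of the steady-state problem
.supply_gsc <- function(gs_spec, An, env) {
  switch(gs_spec$model_id,
    bwb = {
      if (!is.finite(env$Cs) || env$Cs <= 0) {
        stop("degenerate supply: bwb requires Cs > 0", call. = FALSE)
      }
      gs_spec$g1 * An * env$hr / env$Cs + gs_spec$g0
    },
    medlyn = {
      if (!is.finite(env$Cs) || env$Cs <= 0) {
        stop("degenerate supply: medlyn requires Cs > 0", call. = FALSE)
      }
      gs_spec$g0 + .medlyn_slope_term(gs_spec, env$D) * An / env$Cs
    },
    ye = {
      if (!isTRUE(all.equal(gs_spec$g1, 1)) || gs_spec$g0 != 0) {
        stop("no steady state: the ye spec with g1 != 1 contradicts the ",
             "Fick mass balance (An = gsc (Ca - Ci) and ",
             "gsc = g1 An/(Ca - Ci) + g0 cannot both hold); use bwb, ",
             "medlyn, or a prescribed-conductance fick spec", call. = FALSE)
      }
      NA_real_  # resolved through the Fick identity below
    },
    fick = {
      if (is.null(gs_spec$gsc)) {
        stop("a fick supply spec needs a prescribed constant gsc", call. = FALSE)
      }
      gs_spec$gsc
    }
  )
}

#' Solve the coupled photosynthesis-diffusion steady state
#'
#' Finds the intercellular CO2 at which photosynthetic demand equals
#' diffusive supply: `demand(Ci, I) = gsc * (Ca - Ci)` with `gsc` given by
#' the stomatal model evaluated at that same An and environment. Solved by
#' root bracketing on Ci over `(0.01 * Gamma, 1.5 * Ca + 600)` (the bracket
#' extends above Ca to admit respiration states, e.g. the CO2-free protocol
#' step, where An < 0 and Ci > Ca).
#'
#' @param Ca Ambient CO2, umol mol-1 (> 0 allowed down to 0).
#' @param I Irradiance, umol photons m-2 s-1.
#' @param hr Relative humidity at the leaf surface, fraction.
#' @param D Leaf-to-air vapor pressure deficit, kPa.
#' @param gs_spec A [gs_model_spec()]: `"bwb"`, `"medlyn"`, a `"fick"` spec
#'   with prescribed constant `gsc`, or `"ye"` only in its Fick reduction
#'   (`g1 = 1, g0 = 0`); other ye parameterisations are algebraically
#'   incompatible with the mass-balance closure and raise an error.
#' @param demand A [demand_params()] or a function `f(Ci, I)` returning An.
#' @param Cs Leaf-surface CO2; defaults to `Ca`.
#' @return List with `An`, `Ci`, `gsc`, and `nonphysical` (TRUE when the
#'   solution has gsc <= 0).
#' @export
steady_state_solve <- function(Ca, I, hr, D, gs_spec, demand, Cs = Ca) {
  stopifnot(inherits(gs_spec, "gs_model_spec"))
  env <- list(hr = hr, D = D, Cs = Cs)
  if (gs_spec$model_id == "ye") {
    .supply_gsc(gs_spec, 0, env)  # errors unless the spec is the Fick reduction
    # the Fick reduction leaves gsc free (its supply equation is the mass
    # balance itself); it needs a prescribed conductance to close the system
    if (is.null(gs_spec$gsc)) {
      stop("the ye spec in its Fick reduction leaves gsc undetermined; ",
           "prescribe a conductance via gs_model_spec('fick', gsc = ...)",
           call. = FALSE)
    }
    gs_spec <- gs_model_spec("fick", gsc = gs_spec$gsc)
  }
  dem <- if (is.function(demand)) {
    function(Ci) demand(Ci, I)
  } else {
    function(Ci) demand_an(Ci, I, demand)
  }
  gsc_at <- function(An) {
    if (gs_spec$model_id == "fick") gs_spec$gsc
    else .supply_gsc(gs_spec, An, env)
  }
  resid <- function(Ci) {
    An <- dem(Ci)
    An - gsc_at(An) * (Ca - Ci)
  }

  Gamma <- if (is.function(demand)) NULL else demand$Gamma
  lo <- if (is.null(Gamma)) 1e-3 else 0.01 * Gamma
  hi <- 1.5 * Ca + 600
  # the residual can cross zero more than once (a spurious branch where the
  # stomatal model extrapolates to negative conductance at strongly negative
  # An): scan the bracket and prefer the sign change on the physical
  # (gsc > 0) branch
  grid <- seq(lo, hi, length.out = 201L)
  fg <- vapply(grid, resid, numeric(1L))
  gg <- vapply(grid, function(Ci) gsc_at(dem(Ci)), numeric(1L))
  ok <- is.finite(fg)
  flips <- which(ok[-length(ok)] & ok[-1L] &
                   sign(fg[-length(fg)]) * sign(fg[-1L]) <= 0 &
                   (fg[-length(fg)] != 0 | fg[-1L] != 0))
  physical <- flips[gg[flips] > 0 | gg[flips + 1L] > 0]
  pick <- if (length(physical) > 0L) physical[1L] else flips[1L]
  if (is.na(pick) || length(flips) == 0L) {
    stop(sprintf(
      "no steady state on Ci bracket (%.3g, %.3g): residuals %.4g and %.4g",
      lo, hi, fg[1L], fg[length(fg)]), call. = FALSE)
  }
  root <- uniroot(resid, grid[c(pick, pick + 1L)], tol = 1e-12)
  Ci <- root$root
  An <- dem(Ci)
  gsc <- gsc_at(An)
  list(An = An, Ci = Ci, gsc = gsc, nonphysical = !is.finite(gsc) || gsc <= 0)
}

#' Simulation configuration for synthetic response curves
#'
#' @param species_label Label carried into the generated curves.
#' @param gs_spec Generating stomatal model spec (see
#'   [steady_state_solve()] for the admissible forms).
#' @param demand A [demand_params()].
#' @param protocol List with `kind` (`"light"` or `"co2"`), `levels`
#'   (protocol sequence in measurement order), and the fixed condition:
#'   `Ca` for light protocols, `I` for CO2 protocols.
#' @param hr_band Uniform band the per-record leaf-surface relative
#'   humidity is drawn from (the chamber controls humidity within a band,
#'   not at a point).
#' @param D Leaf-to-air vapor pressure deficit, kPa (constant by default).
#' @param D_jitter Half-width of optional uniform jitter on D, kPa.
#' @param Tleaf Leaf temperature, degrees C.
#' @param noise_sd_An,noise_sd_gsc Additive Gaussian noise SDs on An
#'   (umol m-2 s-1) and gsc (mol m-2 s-1) applied after the steady-state
#'   solve.
#' @param n_replicates Number of replicate curves.
#' @param seed RNG seed; mandatory when either noise SD is positive.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(species_label, gs_spec, demand,
                              protocol = list(kind = "light",
                                              levels = light_protocol(),
                                              Ca = 420),
                              hr_band = c(0.45, 0.75), D = 1.5,
                              D_jitter = 0, Tleaf = 30,
                              noise_sd_An = 0.3, noise_sd_gsc = 0.01,
                              n_replicates = 3L, seed = NULL) {
  stopifnot(inherits(gs_spec, "gs_model_spec"),
            protocol$kind %in% c("light", "co2"),
            length(protocol$levels) > 0L,
            noise_sd_An >= 0, noise_sd_gsc >= 0, n_replicates >= 1L)
  if ((noise_sd_An > 0 || noise_sd_gsc > 0) && is.null(seed)) {
    stop("a seed is mandatory when noise is enabled", call. = FALSE)
  }
  structure(
    list(species_label = species_label, gs_spec = gs_spec, demand = demand,
         protocol = protocol, hr_band = hr_band, D = D, D_jitter = D_jitter,
         Tleaf = Tleaf, noise_sd_An = noise_sd_An,
         noise_sd_gsc = noise_sd_gsc, n_replicates = as.integer(n_replicates),
         seed = seed),
    class = "simulation_config"
  )
}

#' Simulate replicate response curves under a measurement protocol
#'
#' Steps the coupled steady-state leaf through the configured protocol, one
#' curve per replicate. Per protocol step: relative humidity is drawn
#' uniformly from `hr_band`, the steady state is solved, then seeded
#' additive Gaussian noise is applied to An and gsc and `gsw = 1.6 gsc` is
#' recomputed. Output is deterministic given the seed. Protocol steps where
#' no steady state exists (e.g. the Ca = 0 step under a model that divides
#' by Cs) are dropped from the curve and annotated in the curve's
#' `dropped` attribute rather than aborting the simulation; noisy
#' conductance is floored at zero (a measured conductance cannot be
#' negative).
#'
#' @param config A [simulation_config()].
#' @return List of [response_curve()] objects, one per replicate, each with
#'   attributes `seed` and `dropped` (character log of dropped steps).
#' @export
simulate_response_curve <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(config$seed)
  }
  proto <- config$protocol
  curves <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    rows <- list()
    dropped <- character(0)
    for (lev in proto$levels) {
      if (proto$kind == "light") {
        I <- lev; Ca <- proto$Ca
      } else {
        I <- proto$I; Ca <- lev
      }
      hr <- runif(1L, config$hr_band[1L], config$hr_band[2L])
      D <- config$D + if (config$D_jitter > 0) {
        runif(1L, -config$D_jitter, config$D_jitter)
      } else 0
      ss <- tryCatch(
        steady_state_solve(Ca = Ca, I = I, hr = hr, D = D,
                           gs_spec = config$gs_spec, demand = config$demand),
        error = function(e) e
      )
      if (inherits(ss, "error")) {
        dropped <- c(dropped, sprintf("%s level %g: %s", proto$kind, lev,
                                      conditionMessage(ss)))
        next
      }
      if (ss$nonphysical) {
        dropped <- c(dropped, sprintf("%s level %g: non-physical gsc %.4g",
                                      proto$kind, lev, ss$gsc))
        next
      }
      An <- ss$An + if (config$noise_sd_An > 0) rnorm(1L, 0, config$noise_sd_An) else 0
      gsc <- ss$gsc + if (config$noise_sd_gsc > 0) rnorm(1L, 0, config$noise_sd_gsc) else 0
      gsc <- max(gsc, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        I = I, Ca = Ca, Cs = Ca, Ci = ss$Ci, An = An, gsw = 1.6 * gsc,
        gsc = gsc, hr = hr, D = D, Tleaf = config$Tleaf
      )
    }
    df <- do.call(rbind, rows)
    # a respiration step can leave Ci > Ca while noise pushes An above 0;
    # nudge such records back to the invariant by the noise magnitude
    if (!is.null(df)) {
      bump <- df$Ci > df$Ca + 1e-9 & df$An >= 0
      df$An[bump] <- -1e-6
    }
    cv <- response_curve(config$species_label, paste0("r", r), proto$kind,
                         df,
                         ambient = if (proto$kind == "light") {
                           list(Ca = proto$Ca)
                         } else list(I = proto$I))
    attr(cv, "seed") <- config$seed
    attr(cv, "dropped") <- dropped
    curves[[r]] <- cv
  }
  curves
}

#' Noise-free design-grid generator for recovery experiments
#'
#' Builds a response curve whose records satisfy a generating stomatal model
#' exactly: conductance and environmental drivers are laid out on grids and
#' net photosynthesis is computed from the model's An-inverse form. No
#' steady-state solver and no noise, so refitting the generating model must
#' recover its parameters to solver precision.
#'
#' @param gs_spec Generating [gs_model_spec()] (`"bwb"`, `"medlyn"`, or
#'   `"ye"`).
#' @param design Named list of grids, recycled to a common length (>= 3):
#'   `gsc` always; plus `dCa` (the gradient Ca - Ci, with optional `Ca`,
#'   default 420) for `ye`; `hr` and `Cs` for `bwb`; `D` and `Cs` for
#'   `medlyn`.
#' @return A [response_curve()] with `protocol_kind = "design"`.
#' @export
noise_free_design <- function(gs_spec, design) {
  stopifnot(inherits(gs_spec, "gs_model_spec"))
  model_id <- gs_spec$model_id
  if (!model_id %in% c("bwb", "medlyn", "ye")) {
    stop("noise_free_design supports bwb, medlyn, ye", call. = FALSE)
  }
  gsc <- design$gsc
  if (is.null(gsc) || length(unique(gsc)) < 3L) {
    stop("degenerate design: need a gsc grid with at least 3 distinct points",
         call. = FALSE)
  }
  n <- length(gsc)
  rec <- function(x, nm) {
    if (is.null(x)) stop("design lacks grid '", nm, "'", call. = FALSE)
    rep_len(x, n)
  }
  if (model_id == "ye") {
    dCa <- rec(design$dCa, "dCa")
    Ca <- rep_len(design$Ca %||% 420, n)
    df <- data.frame(gsc = gsc, Ca = Ca, Ci = Ca - dCa)
  } else if (model_id == "bwb") {
    df <- data.frame(gsc = gsc, hr = rec(design$hr, "hr"),
                     Cs = rec(design$Cs, "Cs"))
  } else {
    D <- rec(design$D, "D")
    if (length(unique(D)) == 1L) {
      warning("constant D: the medlyn design degenerates to a bwb-like ",
              "line; g0 and g1 are only weakly identified", call. = FALSE)
    }
    df <- data.frame(gsc = gsc, D = D, Cs = rec(design$Cs, "Cs"))
  }
  df$An <- an_inverse(gs_spec, df)
  # negative An with Ci < Ca would violate the record invariants only in the
  # ye case where Ci > Ca encodes respiration; designs here keep An free
  curve <- response_curve("synthetic", "design", "design", df)
  curve
}
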