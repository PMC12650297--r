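# Stomatal conductance model equations, in both the gsc-forward form the
# models are usually written in and the An-inverse form used for fitting.

GS_MODEL_IDS <- c("bwb", "medlyn", "ye", "fick")

#' Create a stomatal conductance model specification
#'
#' Bundles a model identity with its parameters. `g1` is dimensionless for
#' `"bwb"` and `"ye"` and has units of kPa^-1 for `"medlyn"` in its as-printed
#' form. `"fick"` is Fick's first law of diffusion, `An = gsc (Ca - Ci)`,
#' which has no free parameters (it is the `"ye"` model with `g1 = 1`,
#' `g0 = 0`).
#'
#' @param model_id One of `"bwb"`, `"medlyn"`, `"ye"`, `"fick"`.
#' @param g0 Conductance offset, mol m-2 s-1. Treated as an unconstrained
#'   fitting constant: negative values are permitted (fitted intercepts in
#'   this family of models are frequently negative and are best read as
#'   fitting constants, not residual conductances).
#' @param g1 Slope parameter; must be supplied for all models except
#'   `"fick"`. A warning (not an error) is raised when `g1 <= 0`, since
#'   fitted slopes can land there on degenerate data.
#' @param medlyn_variant `"printed"` for the `(1 + g1 D)` slope term,
#'   `"sqrt"` for the literature form `(1 + g1/sqrt(D))`. Ignored for other
#'   models.
#' @param gsc Optional prescribed constant conductance (mol m-2 s-1), used
#'   only by [steady_state_solve()] when a `"fick"` spec is employed as a
#'   fixed-conductance supply.
#' @return An object of class `gs_model_spec`.
#' @export
gs_model_spec <- function(model_id, g0 = 0, g1 = NULL,
                          medlyn_variant = c("printed", "sqrt"),
                          gsc = NULL) {
  model_id <- match.arg(model_id, GS_MODEL_IDS)
  medlyn_variant <- match.arg(medlyn_variant)
  if (model_id == "fick") {
    g0 <- 0
    g1 <- 1
  } else {
    if (is.null(g1)) {
      stop("g1 must be supplied for model '", model_id, "'", call. = FALSE)
    }
    if (is.finite(g1) && g1 <= 0) {
      warning("non-physical slope: g1 <= 0 for model '", model_id, "'",
              call. = FALSE)
    }
  }
  stopifnot(is.numeric(g0), length(g0) == 1L,
            is.numeric(g1), length(g1) == 1L)
  structure(
    list(model_id = model_id, g0 = g0, g1 = g1,
         medlyn_variant = medlyn_variant, gsc = gsc),
    class = "gs_model_spec"
  )
}

#' @export
print.gs_model_spec <- function(x, ...) {
  cat(sprintf("<gs_model_spec> %s%s: g0 = %g, g1 = %g\n",
              x$model_id,
              if (x$model_id == "medlyn") paste0(" (", x$medlyn_variant, ")") else "",
              x$g0, x$g1))
  invisible(x)
}

# require record columns, all finite
.require_fields <- function(df, cols, model_id) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop("model '", model_id, "' requires record field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(!complete.cases(df[cols]))
  if (length(bad) > 0L) {
    stop("model '", model_id, "' has missing values in record(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

.check_denominator <- function(x, what, tol = 1e-9) {
  bad <- which(!is.finite(x) | abs(x) < tol)
  if (length(bad) > 0L) {
    stop("degenerate record(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         ": ", what, " too close to zero", call. = FALSE)
  }
  invisible(x)
}

.records_df <- function(records) {
  if (inherits(records, "response_curve")) records$data else as.data.frame(records)
}

.medlyn_slope_term <- function(spec, D) {
  if (spec$medlyn_variant == "sqrt") 1 + spec$g1 / sqrt(D) else 1 + spec$g1 * D
}

#' Evaluate a stomatal conductance model in its gsc-forward form
#'
#' Computes modelled stomatal conductance to CO2 from net photosynthesis and
#' the environmental drivers each model uses: `bwb` gives
#' `g1 * An * hr / Cs + g0`, `medlyn` gives `g0 + (1 + g1 D) * An / Cs`
#' (or `1 + g1/sqrt(D)` under the `"sqrt"` variant), `ye` gives
#' `g1 * An / (Ca - Ci) + g0`, and `fick` gives `An / (Ca - Ci)`.
#'
#' @param spec A [gs_model_spec()].
#' @param records A data frame of gas-exchange records (or a
#'   `response_curve`), with the fields the model requires.
#' @return Numeric vector of gsc, mol m-2 s-1.
#' @export
gsc_forward <- function(spec, records) {
  stopifnot(inherits(spec, "gs_model_spec"))
  df <- .records_df(records)
  switch(spec$model_id,
    bwb = {
      .require_fields(df, c("An", "hr", "Cs"), "bwb")
      .check_denominator(df$Cs, "Cs")
      spec$g1 * df$An * df$hr / df$Cs + spec$g0
    },
    medlyn = {
      .require_fields(df, c("An", "D", "Cs"), "medlyn")
      .check_denominator(df$Cs, "Cs")
      .check_denominator(df$D, "D")
      spec$g0 + .medlyn_slope_term(spec, df$D) * df$An / df$Cs
    },
    ye = {
      .require_fields(df, c("An", "Ca", "Ci"), "ye")
      .check_denominator(df$Ca - df$Ci, "Ca - Ci")
      spec$g1 * df$An / (df$Ca - df$Ci) + spec$g0
    },
    fick = {
      .require_fields(df, c("An", "Ca", "Ci"), "fick")
      .check_denominator(df$Ca - df$Ci, "Ca - Ci")
      df$An / (df$Ca - df$Ci)
    }
  )
}

#' Evaluate a stomatal conductance model in its An-inverse form
#'
#' The exact algebraic inverse of [gsc_forward()] for a fixed spec and
#' environment, with net photosynthesis on the left-hand side: `bwb` gives
#' `(gsc - g0) * Cs / (g1 * hr)`, `medlyn` gives
#' `Cs * (gsc - g0) / (1 + g1 D)`, `ye` gives
#' `(gsc - g0) * (Ca - Ci) / g1`, and `fick` gives `gsc * (Ca - Ci)`.
#' This form is the one fitted: it avoids the sensitivity of the ratio of two
#' large, noisy numbers that the gsc-forward form suffers from.
#'
#' @inheritParams gsc_forward
#' @return Numeric vector of An, umol m-2 s-1.
#' @export
an_inverse <- function(spec, records) {
  stopifnot(inherits(spec, "gs_model_spec"))
  df <- .records_df(records)
  if (spec$model_id != "fick" && (!is.finite(spec$g1) || spec$g1 == 0)) {
    stop("an_inverse requires g1 != 0", call. = FALSE)
  }
  switch(spec$model_id,
    bwb = {
      .require_fields(df, c("gsc", "hr", "Cs"), "bwb")
      if (any(df$hr <= 0)) stop("an_inverse for bwb requires hr > 0", call. = FALSE)
      (df$gsc - spec$g0) * df$Cs / (spec$g1 * df$hr)
    },
    medlyn = {
      .require_fields(df, c("gsc", "D", "Cs"), "medlyn")
      .check_denominator(df$D, "D")
      df$Cs * (df$gsc - spec$g0) / .medlyn_slope_term(spec, df$D)
    },
    ye = {
      .require_fields(df, c("gsc", "Ca", "Ci"), "ye")
      (df$gsc - spec$g0) * (df$Ca - df$Ci) / spec$g1
    },
    fick = {
      .require_fields(df, c("gsc", "Ca", "Ci"), "fick")
      df$gsc * (df$Ca - df$Ci)
    }
  )
}

#' Net photosynthesis from Fick's first law of diffusion
#'
#' At steady state the CO2 flux into the leaf equals conductance times the
#' CO2 gradient across the stomata: `An = gsc * (Ca - Ci)`. Negative when
#' `Ci > Ca` (net efflux, e.g. respiration in CO2-free air).
#'
#' @param gsc Stomatal conductance to CO2, mol m-2 s-1 (>= 0).
#' @param Ca Ambient CO2 mole fraction, umol mol-1.
#' @param Ci Intercellular CO2 mole fraction, umol mol-1.
#' @return Net photosynthesis, umol m-2 s-1.
#' @export
fick_an <- function(gsc, Ca, Ci) {
  if (any(gsc < 0)) stop("gsc must be non-negative", call. = FALSE)
  gsc * (Ca - Ci)
}
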