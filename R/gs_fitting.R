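# Per-curve (g0, g1) estimation by least squares in An-space, with
# closed-form linear initialisation, plus fit diagnostics and replicate
# aggregation.
#
# The objective is always the sum of squared An residuals (models in their
# An-inverse form), never gsc residuals: the gsc-forward forms divide by
# large, noisy quantities (Cs or Ca - Ci) and are numerically fragile.

#' Closed-form linear initialisation of (g0, g1)
#'
#' All three models admit a linear reformulation whose ordinary-least-squares
#' solution either equals the An-space optimum (bwb, ye: the An-inverse form
#' is linear in transformed coefficients) or provides a good starting point
#' for it (medlyn, where g1 enters nonlinearly):
#' \itemize{
#'   \item ye: `An = b1 * gsc (Ca - Ci) + b2 * (Ca - Ci)`, then `g1 = 1/b1`,
#'     `g0 = -b2/b1`;
#'   \item bwb: `An hr / Cs = b1 * gsc + b2`, then `g1 = 1/b1`,
#'     `g0 = -b2/b1`;
#'   \item medlyn (printed): `An - Cs gsc = -g1 (D An) - g0 Cs`, solved by
#'     OLS in the two predictors (for the `"sqrt"` variant the first
#'     predictor is `An / sqrt(D)`).
#' }
#'
#' @param curve A [response_curve()].
#' @param model_id `"bwb"`, `"medlyn"`, or `"ye"`.
#' @param medlyn_variant `"printed"` or `"sqrt"`.
#' @return Named numeric `c(g0, g1)`. A non-physical slope (`g1 <= 0`) is
#'   returned with a warning; a rank-deficient design is an error.
#' @export
linearized_init <- function(curve, model_id = c("bwb", "medlyn", "ye"),
                            medlyn_variant = c("printed", "sqrt")) {
  model_id <- match.arg(model_id)
  medlyn_variant <- match.arg(medlyn_variant)
  df <- .records_df(curve)
  if (nrow(df) < 3L) stop("need at least 3 records", call. = FALSE)

  ols2 <- function(y, X) {
    qx <- qr(X)
    if (qx$rank < 2L) {
      stop("collinear design: (g0, g1) not separable for model '",
           model_id, "'", call. = FALSE)
    }
    drop(qr.coef(qx, y))
  }

  if (model_id == "ye") {
    .require_fields(df, c("An", "gsc", "Ca", "Ci"), "ye")
    d <- df$Ca - df$Ci
    b <- ols2(df$An, cbind(b1 = df$gsc * d, b2 = d))
    g1 <- 1 / b[["b1"]]; g0 <- -b[["b2"]] / b[["b1"]]
    if (!is.finite(g1) || b[["b1"]] <= 0) {
      warning("non-physical slope from linearisation (b1 <= 0)", call. = FALSE)
    }
  } else if (model_id == "bwb") {
    .require_fields(df, c("An", "gsc", "hr", "Cs"), "bwb")
    y <- df$An * df$hr / df$Cs
    b <- ols2(y, cbind(b1 = df$gsc, b2 = rep(1, nrow(df))))
    g1 <- 1 / b[["b1"]]; g0 <- -b[["b2"]] / b[["b1"]]
    if (!is.finite(g1) || b[["b1"]] <= 0) {
      warning("non-physical slope from linearisation (b1 <= 0)", call. = FALSE)
    }
  } else {
    .require_fields(df, c("An", "gsc", "D", "Cs"), "medlyn")
    x1 <- if (medlyn_variant == "sqrt") df$An / sqrt(df$D) else df$D * df$An
    b <- ols2(df$An - df$Cs * df$gsc, cbind(c1 = x1, c2 = df$Cs))
    g1 <- -b[["c1"]]; g0 <- -b[["c2"]]
    if (g1 <= 0) {
      warning("non-physical slope from linearisation (g1 <= 0)", call. = FALSE)
    }
  }
  c(g0 = unname(g0), g1 = unname(g1))
}

#' Fit a stomatal conductance model to one response curve
#'
#' Minimises the sum of squared An residuals,
#' `sum((An_obs - an_inverse(spec, record))^2)`, over `(g0, g1)` by
#' Levenberg--Marquardt least squares ([minpack.lm::nlsLM()]), initialised
#' from [linearized_init()]. For `bwb` and `ye` the An-space objective is
#' linear in transformed coefficients, so the optimum coincides with the
#' closed-form OLS solution to solver tolerance; for `medlyn` the slope
#' enters nonlinearly and iteration is required. Convergence is declared at
#' relative RSS change below 1e-10, capped at 200 iterations.
#'
#' Parameters are unbounded: negative fitted `g0` is reported as-is (a
#' fitting constant, not a residual conductance), and `g1 <= 0` at the
#' optimum raises a warning.
#'
#' @param curve A [response_curve()] with at least 3 records carrying the
#'   fields the model needs.
#' @param model_id `"bwb"`, `"medlyn"`, or `"ye"`.
#' @param medlyn_variant `"printed"` or `"sqrt"`.
#' @return An object of class `gs_fit`: the fitted [gs_model_spec()], `g0`,
#'   `g1`, asymptotic standard errors `se_g0`/`se_g1` (from the Jacobian at
#'   the optimum), `n`, `rss`, `r2`, `r2_adj`, `aic` (NA for a numerically
#'   perfect fit, whose AIC is undefined under the RSS convention),
#'   `converged`, `residuals`, `fitted`, and the curve labels.
#' @export
fit_gs_model <- function(curve, model_id = c("bwb", "medlyn", "ye"),
                         medlyn_variant = c("printed", "sqrt")) {
  model_id <- match.arg(model_id)
  medlyn_variant <- match.arg(medlyn_variant)
  df <- .records_df(curve)
  if (nrow(df) < 3L) {
    stop("need at least 3 records to fit, got ", nrow(df), call. = FALSE)
  }
  start <- linearized_init(curve, model_id, medlyn_variant)
  if (!all(is.finite(start))) start <- c(g0 = 0, g1 = 1)

  form <- switch(model_id,
    bwb    = An ~ (gsc - g0) * Cs / (g1 * hr),
    medlyn = if (medlyn_variant == "sqrt") {
      An ~ Cs * (gsc - g0) / (1 + g1 / sqrt(D))
    } else {
      An ~ Cs * (gsc - g0) / (1 + g1 * D)
    },
    ye     = An ~ (gsc - g0) * (Ca - Ci) / g1
  )

  converged <- TRUE
  fit <- tryCatch(
    minpack.lm::nlsLM(
      form, data = df, start = as.list(start),
      control = minpack.lm::nls.lm.control(maxiter = 200L, ftol = 1e-10,
                                           ptol = 1e-12)
    ),
    error = function(e) {
      converged <<- FALSE
      NULL
    }
  )

  if (is.null(fit)) {
    est <- start
    ses <- c(g0 = NA_real_, g1 = NA_real_)
    pred <- an_inverse(gs_model_spec(model_id, g0 = est[["g0"]],
                                     g1 = est[["g1"]],
                                     medlyn_variant = medlyn_variant), df)
  } else {
    est <- coef(fit)
    converged <- isTRUE(fit$convInfo$isConv) || fit$convInfo$finIter < 200L
    sm <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
    ses <- if (is.null(sm)) c(g0 = NA_real_, g1 = NA_real_) else
      c(g0 = sm["g0", "Std. Error"], g1 = sm["g1", "Std. Error"])
    pred <- predict(fit)
  }
  if (is.finite(est[["g1"]]) && est[["g1"]] <= 0) {
    warning("fitted slope g1 <= 0 for model '", model_id, "'", call. = FALSE)
  }

  res <- df$An - pred
  rss <- sum(res^2)
  tss <- sum((df$An - mean(df$An))^2)
  n <- nrow(df)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  r2a <- if (is.finite(r2) && n > 3L) adjusted_r2(r2, n, p = 2L) else NA_real_
  aic <- if (rss > n * 1e-20) aic_from_rss(rss, n, k = 3L) else NA_real_

  spec <- suppressWarnings(
    gs_model_spec(model_id, g0 = est[["g0"]], g1 = est[["g1"]],
                  medlyn_variant = medlyn_variant)
  )
  structure(
    list(spec = spec, model_id = model_id, g0 = est[["g0"]], g1 = est[["g1"]],
         se_g0 = unname(ses[["g0"]]), se_g1 = unname(ses[["g1"]]),
         n = n, rss = rss, r2 = r2, r2_adj = r2a, aic = aic,
         converged = converged, residuals = res, fitted = pred,
         species = if (inherits(curve, "response_curve")) curve$species else NA_character_,
         replicate = if (inherits(curve, "response_curve")) curve$replicate else NA_character_,
         protocol_kind = if (inherits(curve, "response_curve")) curve$protocol_kind else NA_character_),
    class = "gs_fit"
  )
}

#' @export
print.gs_fit <- function(x, ...) {
  cat(sprintf(
    "<gs_fit> %s (%s/%s): g0 = %.4f (SE %.4f), g1 = %.4f (SE %.4f)\n  n = %d, RSS = %.4g, adj. R2 = %s, AIC = %s%s\n",
    x$model_id, x$species, x$replicate, x$g0, x$se_g0, x$g1, x$se_g1,
    x$n, x$rss,
    ifelse(is.na(x$r2_adj), "NA", sprintf("%.4f", x$r2_adj)),
    ifelse(is.na(x$aic), "NA (perfect fit)", sprintf("%.3f", x$aic)),
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - r2) (n - 1) / (n - p - 1)`, penalising R-squared for the number
#' of predictors. The conductance models here use `p = 2` (g0 and g1).
#'
#' @param r2 Coefficient of determination.
#' @param n Number of observations; must exceed `p + 1`.
#' @param p Number of predictors.
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, p = 2L) {
  if (n <= p + 1L) {
    stop("adjusted R2 undefined for n <= p + 1 (n = ", n, ", p = ", p, ")",
         call. = FALSE)
  }
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' AIC from a residual sum of squares
#'
#' The least-squares convention `n log(RSS/n) + 2k`, with `k = 3` for the
#' conductance models (g0, g1, and the error variance). Only differences
#' within one dataset are meaningful: the convention drops additive
#' constants, so values are not comparable across datasets or across AIC
#' conventions.
#'
#' @param rss Residual sum of squares (> 0; a perfect fit has undefined AIC
#'   under this convention).
#' @param n Number of observations (>= 1).
#' @param k Number of estimated parameters including the error variance.
#' @return AIC value.
#' @export
aic_from_rss <- function(rss, n, k = 3L) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (!is.finite(rss) || rss <= 0) {
    stop("degenerate fit: AIC undefined for RSS <= 0", call. = FALSE)
  }
  n * log(rss / n) + 2 * k
}

#' Aggregate replicate fits into a parameter summary
#'
#' Arithmetic mean and standard error (sample SD / sqrt(n)) of g0 and g1
#' over replicate curves, with pooled (mean) adjusted R-squared and AIC, as
#' comparison tables report them.
#'
#' @param fits List of `gs_fit` objects, all for the same model.
#' @return An object of class `parameter_summary` with fields `model_id`,
#'   `g0_mean`, `g0_se`, `g1_mean`, `g1_se`, `r2_adj_pooled`, `aic_pooled`,
#'   `n_replicates`, and `g0_values`/`g1_values` (the per-replicate
#'   estimates, kept for downstream ANOVA). SEs are `NA` for a single
#'   replicate.
#' @export
aggregate_replicates <- function(fits) {
  if (length(fits) < 1L) stop("need at least one fit", call. = FALSE)
  ids <- vapply(fits, function(f) f$model_id, character(1L))
  if (length(unique(ids)) != 1L) {
    stop("mixed model_ids in replicate set: ",
         paste(unique(ids), collapse = ", "), call. = FALSE)
  }
  g0 <- vapply(fits, function(f) f$g0, numeric(1L))
  g1 <- vapply(fits, function(f) f$g1, numeric(1L))
  n <- length(fits)
  se <- function(x) if (n >= 2L) sd(x) / sqrt(n) else NA_real_
  structure(
    list(model_id = ids[[1L]],
         g0_mean = mean(g0), g0_se = se(g0),
         g1_mean = mean(g1), g1_se = se(g1),
         r2_adj_pooled = mean(vapply(fits, function(f) f$r2_adj, numeric(1L))),
         aic_pooled = mean(vapply(fits, function(f) f$aic, numeric(1L))),
         n_replicates = n, g0_values = g0, g1_values = g1),
    class = "parameter_summary"
  )
}
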