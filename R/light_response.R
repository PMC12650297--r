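# Light-response (An-I) curve fitting and saturating-irradiance
# determination. Isat sets the irradiance at which CO2-response curves are
# measured (and half of it for the low-light condition).

#' Evaluate the light-response model of net photosynthesis
#'
#' A nonrectangular saturating form with an optional post-peak decline:
#' `An = alpha * (1 - beta I) / (1 + gamma I) * I - Rd`. `alpha` is the
#' initial quantum slope (umol CO2 per umol photons), `gamma` controls
#' saturation, `beta >= 0` produces the decline beyond the optimum seen in
#' photoinhibition-prone leaves, and `Rd` is dark respiration, so
#' `An(0) = -Rd`. With `beta = 0` the curve rises monotonically to the
#' asymptote `alpha/gamma - Rd`; with `beta > 0` it has a finite maximum at
#' the saturating irradiance given by [saturating_irradiance()].
#'
#' @param params List (or `light_response_fit`) with `alpha`, `beta`,
#'   `gamma`, `Rd`.
#' @param I Irradiance, umol photons m-2 s-1 (>= 0). Vectorised.
#' @return Net photosynthesis, umol m-2 s-1.
#' @export
an_light_model <- function(params, I) {
  if (any(I < 0)) stop("irradiance must be non-negative", call. = FALSE)
  params$alpha * (1 - params$beta * I) / (1 + params$gamma * I) * I - params$Rd
}

#' Saturating irradiance of the light-response model
#'
#' Closed-form argmax of [an_light_model()] for `beta > 0`:
#' `Isat = (sqrt((beta + gamma)/beta) - 1) / gamma`. For `beta = 0` the
#' model has no finite maximum and an error is raised; callers may instead
#' use the 95%-of-asymptote fallback built into [fit_light_response()].
#'
#' @param params List with `beta` and `gamma` (both from a light-response
#'   fit).
#' @return Saturating irradiance, umol photons m-2 s-1.
#' @export
saturating_irradiance <- function(params) {
  beta <- params$beta
  gamma <- params$gamma
  if (!is.finite(beta) || beta <= 0) {
    stop("no finite maximum: saturating irradiance undefined for beta <= 0",
         call. = FALSE)
  }
  (sqrt((beta + gamma) / beta) - 1) / gamma
}

#' Fit the light-response model to an An-I curve
#'
#' Least-squares estimation of `(alpha, beta, gamma, Rd)` by
#' Levenberg--Marquardt ([minpack.lm::nlsLM()]) with `beta` bounded below at
#' 0. Initialisation: `Rd` from the dark record (`-An` at `I = 0`), `alpha`
#' from the slope of the three lowest-irradiance points, `gamma` from the
#' observed maximum (`alpha / (Amax + Rd)`), `beta = 1e-5`.
#'
#' The saturating irradiance `Isat` is the fitted curve's argmax when
#' `beta > 0` (closed form); when the fit collapses to `beta = 0` (a
#' monotone curve) the fallback is the smallest irradiance reaching
#' `isat_threshold` of the asymptote `alpha/gamma - Rd`. `Amax` is the model
#' value at `Isat`.
#'
#' @param curve A [response_curve()] with `protocol_kind = "light"` and at
#'   least 5 records spanning irradiance from 0 to the protocol maximum.
#' @param isat_threshold Fraction of the asymptote defining the fallback
#'   Isat for monotone fits (default 0.95).
#' @return An object of class `light_response_fit`: `alpha`, `beta`,
#'   `gamma`, `Rd`, `Isat`, `Amax`, `isat_method` (`"argmax"` or
#'   `"threshold"`), `n`, `rss`, `r2_adj`, `converged`.
#' @export
fit_light_response <- function(curve, isat_threshold = 0.95) {
  df <- .records_df(curve)
  if (inherits(curve, "response_curve") && curve$protocol_kind != "light") {
    stop("light-response fitting needs a light-protocol curve", call. = FALSE)
  }
  .require_fields(df, c("I", "An"), "light response")
  if (nrow(df) < 5L) {
    stop("need at least 5 records for a light-response fit, got ", nrow(df),
         call. = FALSE)
  }
  degenerate <- function() {
    structure(list(alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
                   Rd = NA_real_, Isat = NA_real_, Amax = NA_real_,
                   isat_method = NA_character_, n = nrow(df), rss = NA_real_,
                   r2_adj = NA_real_, converged = FALSE),
              class = "light_response_fit")
  }
  if (var(df$An) == 0) return(degenerate())  # no curvature information

  ord <- order(df$I)
  Rd0 <- if (any(df$I == 0)) -mean(df$An[df$I == 0]) else 1
  low3 <- df[ord, ][seq_len(3L), ]
  alpha0 <- tryCatch(unname(coef(lm(An ~ I, data = low3))[2L]),
                     error = function(e) NA_real_)
  if (!is.finite(alpha0) || alpha0 <= 0) alpha0 <- 0.02
  Amax0 <- max(df$An)
  gamma0 <- alpha0 / max(Amax0 + Rd0, 1e-3)

  converged <- TRUE
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200L, ftol = 1e-12,
                                     ptol = 1e-12)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      An ~ alpha * (1 - beta * I) / (1 + gamma * I) * I - Rd,
      data = df,
      start = list(alpha = alpha0, beta = 1e-5, gamma = gamma0, Rd = Rd0),
      control = ctrl
    ),
    error = function(e) NULL
  )
  # beta is meaningful only as a decline; when the free fit drifts negative
  # or numerically to zero (a monotone curve) refit the 3-parameter
  # saturating form with beta = 0
  if (!is.null(fit) && coef(fit)[["beta"]] < 1e-7) fit <- NULL
  if (is.null(fit)) {
    fit3 <- tryCatch(
      minpack.lm::nlsLM(
        An ~ alpha * I / (1 + gamma * I) - Rd, data = df,
        start = list(alpha = alpha0, gamma = gamma0, Rd = Rd0),
        control = ctrl
      ),
      error = function(e) NULL
    )
    if (is.null(fit3)) return(degenerate())
    est <- as.list(coef(fit3))
    est$beta <- 0
    est <- est[c("alpha", "beta", "gamma", "Rd")]
    fit <- fit3
  } else {
    est <- as.list(coef(fit))
  }
  res <- df$An - predict(fit)
  rss <- sum(res^2)
  tss <- sum((df$An - mean(df$An))^2)
  r2 <- 1 - rss / tss
  r2a <- if (nrow(df) > 5L) adjusted_r2(r2, nrow(df), p = 4L) else NA_real_

  if (est$beta > 1e-12) {
    Isat <- saturating_irradiance(est)
    method <- "argmax"
  } else {
    asym <- est$alpha / est$gamma - est$Rd
    target <- isat_threshold * asym
    # smallest I with An >= target; monotone so a single root
    f <- function(I) est$alpha * I / (1 + est$gamma * I) - est$Rd - target
    hi <- 1e3 / est$gamma
    Isat <- if (f(hi) < 0) hi else uniroot(f, c(0, hi), tol = 1e-8)$root
    method <- "threshold"
  }
  Amax <- an_light_model(est, Isat)

  structure(
    c(est,
      list(Isat = Isat, Amax = Amax, isat_method = method, n = nrow(df),
           rss = rss, r2_adj = r2a, converged = converged)),
    class = "light_response_fit"
  )
}

#' @export
print.light_response_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<light_response_fit> NOT CONVERGED (degenerate curve)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<light_response_fit> alpha = %.4g, beta = %.4g, gamma = %.4g, Rd = %.3f\n  Isat = %.1f umol m-2 s-1 (%s), Amax = %.2f, n = %d, RSS = %.4g\n",
    x$alpha, x$beta, x$gamma, x$Rd, x$Isat, x$isat_method, x$Amax, x$n, x$rss))
  invisible(x)
}
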