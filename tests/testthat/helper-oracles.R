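# Independent oracles and fixture builders. These deliberately re-derive
# model predictions from the printed equations rather than calling the
# package's evaluation paths, so that tests compare two independent routes.

# An predicted by each model, written out directly from the equations
oracle_an <- function(model_id, g0, g1, df, variant = "printed") {
  switch(model_id,
    bwb    = (df$gsc - g0) * df$Cs / (g1 * df$hr),
    medlyn = if (variant == "sqrt") {
      df$Cs * (df$gsc - g0) / (1 + g1 / sqrt(df$D))
    } else {
      df$Cs * (df$gsc - g0) / (1 + g1 * df$D)
    },
    ye     = (df$gsc - g0) * (df$Ca - df$Ci) / g1
  )
}

oracle_sse <- function(model_id, g0, g1, df, variant = "printed") {
  sum((df$An - oracle_an(model_id, g0, g1, df, variant))^2)
}

# brute-force grid search for the An-space SSE minimiser
grid_oracle <- function(model_id, df, g0_range, g1_range, step = 1e-3,
                        variant = "printed") {
  g0s <- seq(g0_range[1], g0_range[2], by = step)
  g1s <- seq(g1_range[1], g1_range[2], by = step)
  best <- list(sse = Inf)
  for (g1 in g1s) {
    sse <- vapply(g0s, function(g0) oracle_sse(model_id, g0, g1, df, variant),
                  numeric(1))
    i <- which.min(sse)
    if (sse[i] < best$sse) best <- list(g0 = g0s[i], g1 = g1, sse = sse[i])
  }
  best
}

# closed-form An-space OLS solution for the models whose An-inverse form is
# linear in transformed coefficients (bwb, ye)
ols_an_space <- function(model_id, df) {
  if (model_id == "ye") {
    d <- df$Ca - df$Ci
    b <- coef(lm(df$An ~ 0 + I(df$gsc * d) + I(d)))
  } else if (model_id == "bwb") {
    b <- coef(lm(df$An ~ 0 + I(df$gsc * df$Cs / df$hr) + I(df$Cs / df$hr)))
  } else {
    stop("no closed form for ", model_id)
  }
  c(g0 = unname(-b[2] / b[1]), g1 = unname(1 / b[1]))
}

# n replicate values with exactly the requested mean and standard error
replicates_from_mean_se <- function(mean, se, n = 3) {
  offsets <- seq_len(n) - (n + 1) / 2          # symmetric, mean zero
  offsets <- offsets / sd(offsets)             # unit sample SD
  mean + offsets * se * sqrt(n)
}

# fuzzed gas-exchange records with all fields populated and Fick-consistent
# An (so they satisfy every record invariant)
random_records <- function(n, seed = 1) {
  set.seed(seed)
  gsc <- runif(n, 0.02, 0.6)
  Ca <- runif(n, 100, 1500)
  Ci <- Ca - runif(n, 20, 90)
  data.frame(
    I = runif(n, 0, 2000), Ca = Ca, Cs = Ca, Ci = Ci,
    An = gsc * (Ca - Ci), gsc = gsc, gsw = 1.6 * gsc,
    hr = runif(n, 0.45, 0.75), D = runif(n, 0.8, 2.5), Tleaf = 30
  )
}

# standard design grids used throughout the recovery experiments
design_grid <- function(model_id) {
  gsc <- seq(0.05, 0.60, by = 0.05)
  switch(model_id,
    ye     = list(gsc = gsc, dCa = seq(50, 160, by = 10)),
    bwb    = list(gsc = gsc, hr = seq(0.45, 0.75, length.out = 12), Cs = 400),
    medlyn = list(gsc = gsc, D = seq(1.0, 2.0, length.out = 12), Cs = 400)
  )
}

# small canonical gas-exchange CSV written to a temp file
write_fixture_csv <- function(path, headers = "canonical") {
  if (headers == "canonical") {
    lines <- c(
      "species,replicate,protocol,I,Ca,Cs,Ci,An,gsw,hr,D",
      "sp1,r1,co2,1000,400,400,300,10,0.24,0.6,1.5",
      "sp1,r1,co2,1000,600,600,460,14,0.224,0.6,1.5",
      "sp1,r1,co2,1000,800,800,620,18,0.208,0.6,1.5",
      "sp1,r2,co2,1000,400,400,310,9,0.224,0.6,1.5",
      "sp1,r2,co2,1000,600,600,470,13,0.208,0.6,1.5",
      "sp1,r2,co2,1000,800,800,630,17,0.192,0.6,1.5"
    )
  } else {
    lines <- c(
      "species,replicate,protocol,PARi,CO2R,CO2S,Ci,Photo,Cond,RH_S,VpdL",
      "sp1,r1,light,1000,420,420,300,10,0.24,60,1.5",
      "sp1,r1,light,800,420,420,310,9,0.224,62,1.5",
      "sp1,r1,light,600,420,420,320,8,0.208,58,1.5"
    )
  }
  writeLines(lines, path)
  path
}
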