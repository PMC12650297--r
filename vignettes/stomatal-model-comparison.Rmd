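---
title: "Comparing stomatal conductance models on gas-exchange response curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing stomatal conductance models on gas-exchange response curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gscompare)
```

## The models and what is being compared

Stomatal conductance to CO2, $g_{sc}$ (mol m$^{-2}$ s$^{-1}$), couples a
leaf's carbon gain to its water loss. Three single-slope models of $g_{sc}$
as a function of net photosynthesis $A_n$ and the leaf environment are
compared here:

* **Ball–Woodrow–Berry (BWB)**, empirical:
  $g_{sc} = g_1 \, A_n h_r / C_s + g_0$, with $h_r$ the relative humidity at
  the leaf surface (fraction) and $C_s$ the CO2 mole fraction at the leaf
  surface (µmol mol$^{-1}$).
* **Medlyn**, derived from stomatal optimisation theory. This package's
  default form is $g_{sc} = g_0 + (1 + g_1 D)\,A_n / C_s$ with $D$ the
  leaf-to-air vapor pressure deficit, which makes $g_1$ carry units of
  kPa$^{-1}$. The more common literature form,
  $g_{sc} = g_0 + (1 + g_1/\sqrt{D})\,A_n/C_s$, is available as
  `medlyn_variant = "sqrt"`. Both are implemented because published work
  uses both slope terms, and slopes fitted under one form are not
  comparable with the other; the default follows the form the comparison
  methodology was defined with, and every fitting function takes the
  variant as an argument.
* **Ye (Fick-law based)**: $g_{sc} = g_1 A_n / (C_a - C_i) + g_0$, a
  parameterised extension of Fick's first law of diffusion. With $g_1 = 1$
  and $g_0 = 0$ it reduces exactly to the mass balance
  $A_n = g_{sc}(C_a - C_i)$; fitted $g_1 < 1$ measures how far the leaf
  falls short of the ideal-diffusion prediction (mesophyll and biochemical
  limitations), which gives the slope a physical reading the other two
  models lack.

All three have exactly two free parameters. $g_0$ is treated throughout as
an unconstrained *fitting constant*, not as a "residual conductance":
negative fitted intercepts are commonplace for these models on real curves
and are reported as-is, never clamped.

## Fitting: why An-space, and how

Each model is fitted per replicate curve by minimising the sum of squared
residuals of **net photosynthesis**, using the model's algebraically
inverted form (e.g. $A_n = (g_{sc} - g_0)\,C_s/(g_1 h_r)$ for BWB). Fitting
the conductance-forward form instead would divide a noisy numerator by a
noisy, large denominator ($C_s$, or $C_a - C_i$), and the ratio of two
large numbers is highly sensitive to small denominator errors. Both forms
are available for evaluation (`gsc_forward()`, `an_inverse()`); only the
An-form is ever fitted.

Estimation is Levenberg–Marquardt least squares (`minpack.lm::nlsLM`),
initialised from a closed-form linearisation (`linearized_init()`):

* BWB and Ye are linear in transformed coefficients, so their An-space
  optimum *equals* the ordinary-least-squares solution; the iterative fit
  just confirms it (the test suite checks agreement to 1e-8).
* Medlyn's slope enters nonlinearly through $1/(1 + g_1 D)$; its
  initialiser is OLS on the exact rearrangement
  $A_n - C_s g_{sc} = -g_1 (D A_n) - g_0 C_s$.

Convergence is declared at a relative RSS change below 1e-10, capped at 200
iterations, and a fit reports `converged = FALSE` rather than failing.
Standard errors come from the Jacobian at the optimum. A fitted $g_1 \le 0$
raises a warning (non-physical slope), and a rank-deficient design (e.g.
constant conductance) is a hard error: the parameters are not separable.

```{r recovery}
spec <- gs_model_spec("ye", g0 = -0.002, g1 = 0.727)
curve <- noise_free_design(spec, list(gsc = seq(0.05, 0.60, by = 0.05),
                                      dCa = seq(50, 160, by = 10)))
fit_gs_model(curve, "ye")
```

### Diagnostics and their conventions

* **Adjusted $R^2$** uses $p = 2$ predictors:
  $1 - (1 - R^2)(n-1)/(n-p-1)$.
* **AIC** uses the least-squares convention $n \ln(\mathrm{RSS}/n) + 2k$
  with $k = 3$ ($g_0$, $g_1$, error variance). This convention drops
  additive constants, so AIC values are **only comparable between models
  fitted to the same records** — which is the only use made of them. A
  numerically perfect fit (RSS $\approx 0$, as on noise-free synthetic
  data) has no finite AIC under this convention and is reported as `NA`.
* Parameters are fitted **per replicate curve and then aggregated** as mean
  ± SE over replicates (`aggregate_replicates()`), with $R^2$ and AIC
  pooled as replicate means. Comparison tables of this kind report
  mean ± SE over $n = 3$ replicates, which implies replicate-wise
  estimation; whether published pooled diagnostics were computed this way
  is not stated anywhere we know of, so the choice is documented here
  rather than asserted as *the* published procedure.

## Light-response curves and saturating irradiance

CO2-response protocols are run at each species' saturating irradiance
$I_{sat}$ and at half of it, so $I_{sat}$ must first be estimated from the
An–I curve. The light-response form used is

$$A_n(I) = \alpha\,\frac{(1 - \beta I)}{(1 + \gamma I)}\,I - R_d,$$

chosen because (a) with $\beta > 0$ it has a finite, closed-form optimum
$I_{sat} = (\sqrt{(\beta+\gamma)/\beta} - 1)/\gamma$, matching how a
saturating irradiance is extracted in practice, and (b) it reproduces the
post-peak decline (photoinhibition / dynamic down-regulation) that clover
shows above ~1200 µmol m$^{-2}$ s$^{-1}$. This is a stand-in with the
right qualitative behaviour, not a claim about the exact equation inside
any particular fitting software; numerical equality with other tools'
$I_{sat}$ values is therefore not claimed, and exact reproduction of any
particular study's $I_{sat}$ triplet is out of scope.

When the fitted curve is monotone ($\beta = 0$ within 1e-7, refitted with
$\beta$ fixed at 0), there is no finite argmax and $I_{sat}$ falls back to
the smallest irradiance reaching 95% of the asymptote (threshold
configurable). For a slowly saturating rectangular-hyperbola response this
threshold lands at high irradiance (several thousand µmol m$^{-2}$
s$^{-1}$ in the default grass-like simulations); that is a property of the
definition, flagged in the fit as `isat_method = "threshold"`.

## The synthetic-leaf generator

No raw measurements ship with this package, so the generator provides data
with the structure the analysis assumes, at the study's own conditions:

* **Protocols**: light sequences of 15 levels (2000 → 0, grasses) or 13
  levels (1600 → 0, clover) at $C_a$ = 420 µmol mol$^{-1}$; CO2 sequences
  of 12 levels (1600 → 0; 11 for the wheat-like species, which omits
  1600), measured high-to-low as `light_protocol()` / `co2_protocol()`
  return them. Chamber humidity is drawn per record from the controlled
  45–75% band; leaf temperature is 30 °C; $D$ defaults to a constant
  1.5 kPa (see "Open choices" below).
* **Demand**: a deliberately reduced FvCB-style surrogate,
  $A_n = \min(A_c, A_j, A_p) - R_d$ with carboxylation
  ($V_m, K, \Gamma$), electron-transport ($J(I)/4$ with hyperbolic or
  peaked $J$), and a TPU cap ($3T_p$). No photosynthesis model is ever
  *fitted* to CO2 curves in this package, so the generator only needs the
  qualitative shapes — CO2 saturation, the TPU plateau, and the optional
  post-peak light decline. The clover-like default uses the peaked form
  with its optimum near 1200 µmol m$^{-2}$ s$^{-1}$, emulating that
  species' observed decline.
* **Supply and closure**: for each protocol step the generator solves
  $\mathrm{demand}(C_i, I) = g_{sc}\,(C_a - C_i)$ with $g_{sc}$ given by
  the generating stomatal model at the same $A_n$, by root bracketing on
  $C_i$ over $(0.01\Gamma,\ 1.5 C_a + 600)$ — the bracket extends above
  $C_a$ so the CO2-free step resolves to a respiration state
  ($A_n < 0$, $C_i > C_a$). The residual can cross zero on a spurious
  branch where the stomatal model extrapolates to negative conductance, so
  the solver scans the bracket and roots on the physical ($g_{sc} > 0$)
  branch. Every pre-noise record satisfies the Fick identity to 1e-6.
* **An algebraic caveat**: the Ye model with $g_1 \ne 1$ cannot serve as
  the *generating* model of a coupled steady state — combined with the
  mass balance it forces $A_n = g_0 (C_a - C_i)/(1 - g_1)$ regardless of
  demand, so the solver rejects it with an explanatory error. The
  generating defaults therefore use BWB (with slopes/intercepts in the
  range reported for these species), and Ye-model recovery experiments use
  `noise_free_design()`, which lays conductance and gradients on grids and
  computes $A_n$ from the model directly.
* **Noise**: additive, independent Gaussian on $A_n$ (SD 0.3 µmol m$^{-2}$
  s$^{-1}$) and $g_{sc}$ (SD 0.01 mol m$^{-2}$ s$^{-1}$), the order of
  typical replicate SE bars on such curves; the true error structure and
  replicate variance of field measurements are unknowable from summary
  tables, so these defaults are placeholders and labelled as such. Noise
  requires an explicit seed; the same seed reproduces curves exactly, and
  protocol steps whose steady state fails are dropped and logged on the
  curve (`attr(curve, "dropped")`), never silently imputed — under the
  BWB generator the $C_a = 0$ step is always in this category, since the
  model divides by $C_s$.

What passing tests on these data do **not** show: robustness to
instrument drift, leaks, non-Gaussian or autocorrelated noise,
boundary-layer or mesophyll-conductance structure, or temperature
responses. They show that the estimation machinery is correct when the
model assumptions hold.

## Statistics

* **Paired t** (`paired_t_observed_vs_predicted()`): observed vs
  model-predicted $A_n$, two-sided, with explicit degenerate handling
  (identical series → $t = 0, p = 1$; constant nonzero difference →
  infinite-$t$ flag). The pipeline reports it both per replicate curve and
  pooled across a species' records, since either pairing is defensible.
* **One-way ANOVA + letters** (`oneway_anova_letters()`): parameter
  estimates compared across models within one species. The post hoc
  procedure behind the letters is Tukey's HSD at $\alpha = 0.05$ by
  default — comparison tables of this kind print letters without naming
  their post hoc test, so the choice is explicit and configurable
  (pairwise pooled-SD t with Holm correction as the alternative). Letters
  are built by insert-and-absorb on the non-significance relation,
  assigned "a", "b", … in descending group-mean order; groups share a
  letter iff no pairwise comparison separates them. Letters are attached
  to $g_0$ always (it shares units across models); $g_1$ letters are
  opt-in, because $g_1$'s dimension differs between models and an ANOVA
  across them compares incommensurable quantities.

## Open choices, made once and documented

* **Units of $D$**: kPa (instrument convention for vapour-pressure-deficit
  columns). The Medlyn slope's numerical value depends on this choice;
  slopes in mol mol$^{-1}$-based studies differ by a constant factor.
* **$h_r$** is stored as a fraction in $[0, 1]$; percent-logged columns
  (e.g. LI-6400 `RH_S`) are divided by 100 at ingest, driven by the
  column map's `percent` flag. It is read as leaf-surface humidity.
* **$g_{sw} \to g_{sc}$** conversion uses the binary diffusivity ratio
  1.6 of water vapor to CO2 in air.
* **Missing $C_s$** falls back to $C_a$ with a warning (leaf-surface CO2
  approximated by ambient).
* **Medlyn slope term**: implemented as printed in the defining form
  ($1 + g_1 D$, no 1.6 factor, no square root); the `sqrt` variant covers
  the original formulation. No attempt is made to guess which was
  intended where they disagree.

## Problem sizes

The test suite and the analysis scripts run at desk scale by design:
recovery experiments use 12-record design grids; property suites fuzz
10^4 records for algebraic identities and 200 seeded replicates for
stochastic consistency (median relative error of $\hat g_1$ under
$\sigma_{A_n} = 0.5$ noise is required below 5%, halving $\sigma$ must
shrink it); the full synthetic pipeline is 3 species × 3 replicates ×
(1 light + 2 CO2 conditions), about 350 solved steady states and 90 model
fits, a few seconds end to end.

## Known limitations

* The generator's demand surrogate is not a fittable FvCB model and its
  parameters should not be interpreted against published $V_{cmax}$ or
  $J_{max}$ values.
* AIC values are convention-bound (see above); only within-dataset
  rankings are meaningful.
* The coupled simulator supports generating models that are compatible
  with the Fick closure (BWB, Medlyn, prescribed conductance); this is an
  algebraic property of the model family, not an implementation limit.
* Significance letters from $n = 3$ replicates have little power; they
  reproduce the published patterns on matched means/SEs but should not be
  over-read on real data.
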