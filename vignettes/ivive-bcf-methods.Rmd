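---
title: "From hepatocyte depletion assays to BCF predictions: models and assumptions"
author: "fishbcf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From hepatocyte depletion assays to BCF predictions: models and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishbcf)
```

`fishbcf` chains four models: a first-order substrate-depletion fit, an
in vitro–in vivo extrapolation (IVIVE) of the resulting intrinsic
clearance to a whole-body biotransformation rate constant $k_B$, a kinetic
mass-balance prediction of the steady-state bioconcentration factor (BCF),
and an OECD TG 305 study evaluation that back-calculates the in vivo
$k_B$.  This vignette documents the equations, the defaults and why they
were chosen, the numerical decisions, and what the synthetic-data tests do
and do not demonstrate.

## In vitro clearance

Substrate depletion in a hepatocyte suspension at concentrations well
below saturation follows first-order kinetics,
$C(t) = C_0 e^{-kt}$.  The package fits ordinary least squares to
$\log_{10} C$ vs $t$ and reports $k = -\ln(10)\,\hat\beta_1$ (1/h).  The
factor is the exact $\ln 10 = 2.302585$; the conventional "$-2.3 \times$
slope" is its two-digit print (the difference is < 0.2 %).  Unweighted OLS
in log space — rather than nonlinear exponential least squares — mirrors
standard assay evaluation practice and makes $k$ invariant to the
concentration unit and to normalization, so normalizing a curve to its
first sampling point (`normalize_to_first()`) is purely presentational.

Intrinsic clearance divides by the nominal viable-cell density
(default $2\times10^6$ cells/mL):
$CL_{in\,vitro,int} = k / [\text{cells}]$ in mL/h/10⁶ cells.

**Window policy.** Cryopreserved cells can lose activity late in a 4 h
incubation, flattening the tail.  Because no canonical criterion exists
for "the linear portion of the curve", the package makes the rule explicit
and configurable: refit without the final point and drop it when its
standardized residual exceeds 2.0, at most once by default (`max_drop`),
never below 3 points.  Two numerical guards matter: an absolute residual
floor of $10^{-8}$ log₁₀ units prevents machine-precision scatter on a
perfectly log-linear series from triggering a drop, and a drop that would
leave fewer than 3 points raises an error rather than silently fitting a
2-point line.  Concentrations at or below a user-set LOQ are excluded, not
substituted, since substitution biases the slope.

**QC.** Abiotic loss in heat-inactivated controls must not exceed 5 % of
the live-cell rate (`qc_inactivated()`, boundary inclusive).  When the
live rate is not positive the ratio is undefined and the QC flag is `NA`
rather than an error, so batch processing can continue.

## IVIVE

$$CL_{in\,vivo,int} = CL_{in\,vitro,int} \cdot H \cdot f_{liver} \cdot 24
\quad \text{(L/d/kg fish)}$$

with hepatocellularity $H = 510\times10^6$ cells/g liver for both species
and fractional liver weights 0.015 (trout) and 0.0174 (carp), interpreted
as unitless g liver per g fish for dimensional consistency.  Hepatic
clearance uses the well-stirred liver model

$$CL_H = \frac{Q_H\, f_u\, CL_{in\,vivo,int}}{Q_H + f_u\, CL_{in\,vivo,int}},$$

which is intrinsic-clearance-limited for slowly metabolized chemicals and
saturates at liver blood flow $Q_H$ for rapidly metabolized ones.  The
binding correction is $f_u = f_{u,blood}/f_{u,inc}$ with defaults

$$P_{BW} = 0.16\cdot10^{0.73 \log K_{OW}} + 0.84,\qquad
f_{u,blood} = 1/P_{BW},$$
$$f_{u,inc} = \left(1 + 125\,VR\cdot
 10^{0.072\log K_{OW}^2 + 0.067\log K_{OW} - 1.126}\right)^{-1},$$

$VR = 0.005$ mL cells per mL incubation at the nominal cell density.  Note
that with these defaults $f_u$ is *not* monotone in hydrophobicity: it
falls steeply up to $\log K_{OW}\approx 5$ (blood binding grows fastest),
then rises slightly as incubation binding catches up — the package's tests
pin down exactly this shape.  $f_u$ can exceed 1 for unusual coefficient
choices; a warning is emitted and the value is not clamped, because
clamping would hide configuration errors.  `binding_model("unity")` gives
the conventional $f_u = 1$ variant.

Hepatic blood flow comes from the cardiac-output correlation
$Q_C = (0.23\,T - 0.78)(W_g/500)^{-0.1}$ L/h/kg with a hepatic fraction of
0.259; the relation is only accepted on 0–35 °C and errors when it turns
non-positive.  Finally

$$V_D = \frac{f_{lipid}\cdot K_{OW}}{P_{BW}}, \qquad k_B = CL_H / V_D
\quad (1/d),$$

treating whole-body storage as lipid-dominated octanol-like partitioning
referenced to blood.  The published IVIVE frameworks do not reprint these
sub-models in one place; the package therefore fixes one concrete,
internally consistent default suite and exposes **every** coefficient
(`binding_model()`, `hepatic_blood_flow()` arguments,
`rate_constant_suite()`), so alternative binding QSARs or blood-flow
relations can be swapped without code changes.  Reproduction of published
prediction tables with the defaults is consequently expected only within
the tolerances quoted below, not digit-for-digit.

## Mass-balance BCF

For a one-compartment fish at steady state,

$$BCF = \frac{k_1}{k_2 + k_E + k_G + k_B} \quad \text{(L/kg ww)}.$$

Defaults (all in `rate_constant_suite()`):

| quantity | relation | default coefficients |
|---|---|---|
| gill uptake efficiency | $E_W = (a + b/K_{OW})^{-1}$ | $a=1.85$, $b=155$ |
| ventilation | $G_V = 1400\,W^{0.65}/C_{OX}$ L/d | $C_{sat}(T) = 468/(31.6+T)$ mg/L |
| uptake | $k_1 = E_W G_V / W$ | — |
| respiratory loss | $k_2 = k_1 / K_{FW}$ | $K_{FW} = f_{lipid} K_{OW}$ (lipid-only) |
| feeding | $G_D = 0.022\,W^{0.85} e^{0.06T}$ kg/d | dietary efficiency $E_D = (3\times10^{-7} K_{OW} + 2)^{-1}$ |
| egestion | $k_E = 0.125\, E_D G_D / W$ | — |
| growth dilution | $k_G = c\,W^{-0.2}$ | $c = 5\times10^{-4}$ (cold) / $2.51\times10^{-3}$ (warm) |

$k_2 = k_1/K_{FW}$ is a thermodynamic-consistency closure: with no other
losses the steady state recovers equilibrium partitioning.  The lipid-only
$K_{FW}$ is the simplest defensible choice; a non-lipid organic-matter
term (proportionality 0.035) can be enabled.  Trout takes the cold-water
growth coefficient and carp the warm-water one; a measured growth rate
(from study fish weights) can override the modeled $k_G$.

One suite serves both forward BCF prediction and in vivo $k_B$
back-calculation ($k_B = k_T - (k_2+k_E+k_G)$), although published
assessments have used two separately derived models for these roles;
coherence and testability won that trade-off here.  A negative
back-calculated $k_B$ is returned flagged as not distinguishable from
zero, never truncated.

Uncertainty factors for in vivo $k_B$ estimates are consumed as numeric
inputs; `kb_uncertainty(kb, uf)` returns the multiplicative 95 % range
$(k_B/uf,\; k_B\,uf)$.

## TG 305 evaluation

The time-weighted average water concentration is the trapezoidal mean of
the sampled series (exact for piecewise-linear water concentrations and
invariant under grid refinement).  $BCF_{SS}$ divides the mean of all
individual fish concentrations on the plateau days by the TWA.  Because
study reports rarely state which days defined "steady state", plateau days
are user-specified or auto-detected as the longest trailing run (≥ 3
sampling days) whose per-fish log concentrations show no significant
log-linear trend ($\alpha = 0.05$).  The depuration fit is OLS on
$\ln C_f$ vs days since transfer — the log-linear form of
$C_f = C_{f,0}e^{-k_T t}$ — with individual fish treated as independent
observations rather than pooled day means; non-positive concentrations are
excluded with a warning.  Days are real-valued from phase start and the
depuration clock restarts at transfer; the measured growth rate therefore
uses uptake-phase weights only.  BCFs are reported on a wet-weight basis
without lipid normalization.

## Synthetic data: what it emulates and what it does not

`simulate_depletion()` draws
$C = C_0 e^{-k_{true}t}\,\varepsilon$ on the standard 8-point grid
(5–240 min) with multiplicative lognormal noise of mean 1 — the
analytical-chemistry error model implied by reported %CVs — plus a
constant-rate abiotic-loss control.  `simulate_tg305()` generates a 35 d
uptake / 35 d depuration study (fish sampled on days 0, 7, 14, 21, 28, 31,
35 and 4, 10, 21, 35; 4 fish per occasion; water sampled every 2 days)
from the one-compartment solution, with lognormal water variability,
per-fish noise and exponential weight growth.  A master seed fans out to
fixed per-replicate substreams, so adding replicates never perturbs
existing draws.

The generators deliberately omit features of real assays: time-varying
dead-cell kinetics, metabolite formation, saturation (Michaelis–Menten)
kinetics, inter-laboratory effects, temperature drift and below-LOQ
censoring mechanisms.  Passing recovery tests therefore demonstrates that
the estimators invert the stated generating model — exactly at zero noise,
and with small bias under realistic noise — not that field data satisfy
that model.

## Problem sizes and numerical tolerances

The test suite checks exact recovery to at least 10 significant digits on
noiseless data, and Monte-Carlo calibration on ~1000 triplicate depletion
runs (10 % CV, $k_{true}\in\{0.1, 0.5, 1.0\}$ 1/h; median relative bias
below 3 %) and 500 simulated TG 305 studies (15 % fish noise, 4 fish/day;
median $\hat k_T$ bias below 5 %).  These sizes give stable medians while
keeping the default suite fast.

Reproduction of the bundled reference predictions uses: within ±15 % for
the methoxychlor BCFs and within a factor of 2 for all four scenarios
(the benzo[a]pyrene gap reflects the $K_{OW}$-driven terms of the default
suite), a factor of 2 for the IVIVE $k_B$ extremes (binding sub-model
ambiguity), and a 2–3.5-fold biotransformation-driven BCF reduction
compared at the one-decimal precision of that bound — the reference
scenarios themselves include a fold of 1.99 that rounds to 2.0.

## Known limitations

* Single liver-only biotransformation site; extrahepatic (gill, gut)
  metabolism is not represented, which is one reason IVIVE $k_B$ values
  tend to undershoot in vivo back-calculated ones.
* One-compartment whole-fish kinetics; no PBTK tissue resolution.
* The default sub-model suite is parameterized from trout physiology; the
  carp adaptation changes liver fraction, temperature, mass, lipid and the
  growth regime but reuses the trout binding and blood-flow algorithms.
* Dietary (feeding-study) biomagnification, sediment exposure and
  time-variable temperature are out of scope.
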