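---
title: "Methods: models, generator design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generator design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coastspray)
```

# Scientific setting

When a sewage-impacted river discharges into the coastal ocean, dissolved
pollutants can return to land through sea spray aerosol (SSA): breaking
waves entrain bubbles, bubbles scavenge dissolved and surface-active
material, and bursting bubbles at the surface eject that material into the
marine boundary layer. `coastspray` implements the quantitative chain used
to study this pathway:

1. rain drives river flow, which drives coastal-water pollutant
   concentrations;
2. wind (and sea surface temperature) drive the SSA mass flux;
3. the product of water concentration and SSA flux, modulated by each
   compound's air–water partitioning, drives aerosol concentrations;
4. rain simultaneously removes aerosol by wet scavenging, so
   concentrations rebuild over a multi-day post-rain accumulation period.

Because real campaign data are not redistributable, the package pairs the
analysis functions with a fully seeded synthetic campaign generator whose
construction embeds the same causal structure; every statistical claim the
package makes is tested by recovering the generator's known parameters.

# SSA source functions

Two independent parameterizations of the SSA mass flux are implemented
(`ssa_flux_surfzone()`, `ssa_flux_wind_sst()`); their coefficients live in
the `ssa_constants()` registry together with units and an
assumption flag.

**Surf-zone model.** Number flux per unit surf-zone area,
$dF/dD_{80} = 1.1\times10^{5}\,e^{0.23\,U_{10}}\,D_{80}^{-1.65}$ for drop
diameters at 80% relative humidity $D_{80} \in [1.6, 20]\ \mu m$. The
size integral of the implied dry mass ($r_{dry} = r_{80}/2$, sea-salt
density 2160 kg m^-3^) has a closed form, so this model is evaluated
analytically. The wind dependence is a pure exponential: flux ratios over
a wind increment $\Delta u$ equal $e^{0.23\,\Delta u}$ regardless of the
base wind, a property the tests exploit.

**Wind/SST model.** Open-ocean whitecap parameterization
$dF/dr_{80} = 1.373\,u^{3.41}\,r^{-A}(1 + 0.057 r^{3.45})\,
10^{1.607 e^{-B^2}}$ with
$A = 4.7(1+30r)^{-0.017 r^{-1.44}}$ and
$B = (0.433 - \log_{10} r)/0.433$, scaled by the cubic SST factor
$0.3 + 0.1T - 0.0076T^2 + 0.00021T^3$ (valid 0–30 °C; out-of-range SST is
clamped with a warning and flagged). The mass integral over
$r_{80} \in [0.8, 10]\ \mu m$ has no closed form and is evaluated by a
2000-point trapezoidal rule on a log-spaced grid.

**Areal comparability.** The surf-zone model is per m^2^ of a narrow
wave-breaking strip; the wind/SST model is per m^2^ of open ocean. To
compare them (or feed either into the same aerosol budget) the surf-zone
flux is averaged over an air-mass footprint: a 50 m wide surf strip
diluted across a 54 km fetch (about 3 h of travel at 5 m/s). These two
widths are registry assumptions, chosen at design time, not fitted. Under
this convention the two models agree within a factor of 10 (maximum
absolute log~10~ ratio ≈ 0.88) for winds of 2–10 m/s and SST 15–20 °C —
the package's order-of-magnitude cross-validation of its own flux scale.

Fluxes are reported canonically in pg m^-2^ day^-1^.
`integrate_flux()` integrates a flux series over a time window by the
trapezoidal rule, interpolating the window endpoints so that integrals
are exactly additive over adjacent windows.

# Quantification and QA/QC

`fit_calibration()` fits an ordinary least squares response curve to
external standards (default levels 1.37, 13.7, 137 ng per sample) and
defines LOD = 3·SE(intercept)/sensitivity and LOQ = (10/3)·LOD.
`quantify()` inverts the curve and divides by sample volume; 1.37–137 ng
in a 1 L water sample spans 1.37–137 ng/L (parts per trillion), and in a
70.5 m^3^ air sample (50 L/min for 23.5 h) about 0.019–1.94 ng m^-3^.
Back-calculated masses below the LOD (including negative ones) are
censored: reported at the LOD with flag `lt_lod`, never as zero or
negative.

`blank_filter()` applies the contamination rule: a compound is discarded
if and only if it is detected (> 300 ion counts) in strictly more than
50% of field blanks. The rule is idempotent and order-independent.

# Synthetic campaign generator

`campaign_config()` + `simulate_campaign()` produce a 50-day hourly
campaign with five rain events, one river site, four coastal sites, and
twelve compounds spanning seven orders of magnitude in octanol–water
partitioning ($\log K_{ow}$ from −1.3 to 5.8).

**Flow.** River flow is baseline plus a gain times the discrete
exponential-kernel convolution of hourly rain (recursion
$a_{t} = a_{t-1} e^{-1/\tau} + r_t$, decay 24 h). This is linear in rain,
so doubling the rain exactly doubles the flow anomaly — a property used
as a generator oracle.

**Water.** Each compound's river concentration scales its median by
relative flow; coastal sites see the river signal attenuated by
$e^{-|d|/15\ km}$ plus a small uniform background, with lognormal
multiplicative noise of unit mean. Noise-free water at a coastal site is
therefore exactly affine in daily mean flow, which the tests verify with
$R^2 = 1$.

**Aerosol.** A per-site, per-compound daily pool: each day the pool first
decays by wet scavenging ($e^{-k\,\text{wet hours}}$), photochemical loss
($e^{-1/\tau_{photo}}$) and dry deposition ($e^{-1/\tau_{dep}}$), then
gains an increment equal to (transfer weight) × (daily SSA flux) ×
(same-day water concentration), where the transfer weight is
$s\,10^{\gamma(\log K_{ow} - 2)}$ with designed exponent γ = 0.5.
Area (non-marine) sources add a constant on top for compounds like
dibenzylamine. The `aerosol_coupling = "constant"` mode freezes the water
factor so that analytic tests can demand exactly linear flux response.

**Measurement.** Per-compound LODs are set at a configurable quantile of
the truth distribution (LOQ = 10/3 LOD), lognormal measurement noise is
applied, and values below the LOD are censored at the LOD — mirroring the
quantification conventions above.

**Determinism.** All randomness derives from the single config seed via
fixed per-stage offsets; `.Random.seed` is saved and restored, so
simulation never perturbs the caller's RNG state and two runs on the same
config are byte-identical.

**Realism and limits.** The generator is a causal-structure testbed, not
a geophysical model: it has no tides, no alongshore advection, no aerosol
size resolution, and its noise is purely multiplicative lognormal. Wind
and rain are independent apart from a storm-wind kernel; air-mass
direction is a simple diurnal sea-breeze pattern. These simplifications
are deliberate — they make the mapping from designed parameters to
recoverable statistics exact enough to test, while retaining the features
the analysis must survive: censoring, event overlap, site gradients,
surface-active outliers, and area-source confounders.

# Event statistics

`detect_events()` finds maximal wet runs (≥ 0.1 mm/h) and merges runs
separated by dry gaps shorter than 12 h; each event carries a 2-day dry
pre-window, the wet window, and a 3-day accumulation window.
`event_deltas()` computes window-mean differences with standard
deviations propagated in quadrature.

`regress()` provides free-intercept OLS and forced-zero fits. Forced-zero
slopes use the closed form $\sum xy / \sum x^2$. There is no unique
$R^2$ for a through-origin fit; the default reported value is the squared
Pearson correlation between observed and fitted values (the quantity most
readers interpret), with the uncentered definition
$1 - RSS/\sum y^2$ available by flag. The definition used is recorded in
the result.

`site_compare()` is a two-sided Mann–Whitney U test. For
$n_1 n_2 \le 400$ the p-value is exact, from a tie-aware dynamic program
over doubled midranks that counts all rank-sum-partitioned subsets — a
complete enumeration, not a Monte-Carlo approximation. Larger problems
use the tie-corrected normal approximation with continuity correction.
The crossover at 400 keeps the exact path under a millisecond.

`classify_airmass()` labels each day onshore (> 75% of hours from the
ocean sector), offshore (< 25%), or mixed, with strict inequalities so
the 75% edge is mixed; days with > 25% missing hours are unknown.

# Enrichment and partitioning

The aerosolization factor AF is the same-day, same-site ratio of aerosol
concentration (pg m^-3^) to water concentration (pg L^-1^), in L m^-3^.
Pairs with a censored member are excluded by default (with recorded
reasons); a substitution policy retains them at their reported
detection-limit values.

Compounds are classified by the bubble scavenging coefficient
$K_s = K_{aq}/K_a$: water-accumulating ($K_s < 1/T$), interface, or
bubble-interior ($K_s > T$), with threshold width $T = 10$. The
`transfer_class()` refinement separates surface-active compounds
($\log K_{ow} \ge 4$): a compound can be strongly surface-active yet
poorly bubble-scavenged (octinoxate in the default registry), in which
case its AF reflects surface-film, not bulk, transport and it is excluded
from the log AF vs log $K_{ow}$ regression, whose slope estimates the
transfer exponent γ.

# Compartmental transfer and exposure

The order-of-magnitude chain: river discharge = concentration × flow
(1 US gallon = 3.78541 L, so 1 µg/L at 1 MGD is 3.785 g/day);
ocean-to-air flux = SSA flux × enrichment factor × (water concentration /
seawater sodium, 10.8 g/L); onshore transfer = air concentration × wind ×
boundary-layer height × coastline length (1 ng m^-3^ with the defaults
gives 86.4 g/day per km); inhalation = air concentration × 0.7 m^3^/h;
global extrapolation multiplies a per-km rate by 1.634 × 10^6^ km of
coastline, halved twice (impacted fraction, onshore-time fraction), over
365.25 days. The enrichment-factor value (100) and the global numbers are
registry assumptions; estimates that depend on them carry
`exploratory = TRUE`, and every step is degree-1 homogeneous in its
concentration argument so median and maximum inputs propagate cleanly.

`photochemical_factor()` corrects aged concentrations for first-order
photochemical loss: with a 4-day e-folding lifetime and a 3–4 day
accumulation period the factor is $e^{3/4}$–$e^{1}$ ≈ 2.12–2.72, i.e.
measured concentrations of photolabile compounds are two to three times
lower than freshly emitted ones.

# Design decisions and limitations

- **Forced-zero tracer regressions** encode the assumption that a
  compound absent from sewage is absent from sewage-driven aerosol; the
  free-intercept alternative is available through `regress()`.
- **Censoring policy** defaults to exclusion because detection-limit
  substitution biases forced-zero slopes; substitution is offered for
  plotting parity.
- **The 50 m / 54 km footprint** is the single most influential
  assumption in cross-model flux comparison; both widths are exposed in
  the constants registry.
- **Exact Mann–Whitney enumeration** is preferred over `wilcox.test`'s
  tie-handling because campaign data are heavily tied after censoring;
  the normal fallback is only engaged beyond $n_1 n_2 = 400$.
- The transfer-chain estimators are deliberately order-of-magnitude: no
  plume dispersion, no size-resolved deposition, no population-weighted
  exposure. They bound the pathway; they do not model it.
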