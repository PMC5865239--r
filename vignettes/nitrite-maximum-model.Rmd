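---
title: "Modelling nitrifier functional types and the primary nitrite maximum"
author: "nitricline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nitrifier functional types and the primary nitrite maximum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitricline)
```

## The scientific problem

Nitrification — the microbial oxidation of ammonium to nitrite and of
nitrite to nitrate — is carried out by two distinct chemoautotrophic
guilds: ammonia-oxidizing organisms (AOO, in the open ocean mostly
archaea) and nitrite-oxidizing organisms (NOO, mostly larger
bacteria). In stratified subtropical water columns, nitrite
accumulates in a narrow band at the base of the sunlit layer — the
primary nitrite maximum (PNM) — just below the deep chlorophyll
maximum, and its peak concentration consistently exceeds the nearby
ammonium maximum. `nitricline` implements a mechanistic explanation
in three tiers:

1. **Redox-balanced whole-organism stoichiometries.** Summing
   electron-donor, oxygen, and biomass-synthesis half-reactions with
   an electron fraction `f` routed to synthesis yields the full AOO
   and NOO metabolisms, from which growth yields follow in closed
   form: `y_NH4 = 1/(1 + d/(6f))` and `y_NO2 = 2f/d` with `d` the
   electron equivalents of biomass (20 for C5H7O2N). At `f = 0.03`
   the AOO needs ~112 mol NH4+ and the NOO ~333 mol NO2- per mole of
   biomass nitrogen: the NOO demands roughly three times more DIN.
2. **Trait differences from cell size.** Diffusive-uptake allometry
   makes the biomass-specific affinity scale with cell radius as
   r^-2; a tenfold larger NOO cell volume therefore implies a
   4.6-fold affinity penalty.
3. **Resource-ratio competition in a 1D column.** A nine-variable
   nitrogen-cycle ecosystem embedded in a diffusive water column
   shows phytoplankton excluding both nitrifiers wherever light
   permits photoautotrophy (their subsistence DIN concentrations,
   R\* = K L/(mu_max - L), are far lower), while below the euphotic
   zone the nitrifiers take control and ambient NH4+ and NO2-
   approach the nitrifier R\* values. The yield and affinity
   differences raise the NOO's R\* above the AOO's, so nitrite
   accumulates above ammonium — the PNM.

## State variables and process laws

Nine concentrations (mol N m^-3 internally; umol/L at the user
surface) interact through a closed nitrogen budget: NH4+, NO2-,
NO3-, sinking detritus, and the biomass of heterotrophic bacteria,
AOO, NOO, picophytoplankton, and a microzooplankton grazer.

* Nitrifiers grow by Monod kinetics, `mu = y Vmax R/(R + K)`, with
  culture-derived AOO parameters (Vmax 50.8 per day at 30 C, K 133
  nM) and NOO kinetics scaled allometrically from them.
* Phytoplankton growth combines a DIN saturation sum `gamma_N` (used
  exactly as the sum of the three Monod terms — it can exceed 1, and
  the uptake partition divides by the same sum, so no cap is needed),
  an Arrhenius temperature factor, and photoacclimated light
  limitation: the chlorophyll-to-carbon ratio takes its
  balanced-growth value, and absorbed light saturates growth
  exponentially. Under saturating light this pins absorbed photons at
  twice the nutrient-temperature capacity, so realized growth tends to
  `(1 - e^-2)` of it.
* Heterotrophs remineralize detritus with yield `y_D = 0.14`,
  releasing the remainder as NH4+; grazing is a saturating function
  of total microbial prey with efficiency 0.5, excreting the rest;
  linear prey mortality and quadratic grazer mortality close the
  loop into detritus.
* Every transfer is assembled from a 22-entry flux ledger mapped
  through a signed incidence matrix, so the nine tendencies sum to
  zero at machine precision for any state.

Temperature modifies all rates except the nitrifiers' (the exemption
is a switch, on by default). The Arrhenius form is written with
`A_E (1/(T+273.15) - 1/T_0)`; the bundled default `A_E = -4000 K` is
negative so that rates increase with warming.

## The water column

The physical scaffold is a 2000 m column at 5 m resolution (the
bundled default): a diffusivity profile with a surface mixed layer
decaying over `z_mld`, an interior background, and a 100 m bottom
boundary layer that smooths the sediment interface; Beer-Lambert
light attenuation by water and chlorophyll; and a double-exponential
subtropical temperature fit (26 C at the surface to 2 C at depth).
Detritus sinks with the third-order QUICK reconstruction (upwind
fallback in the two cells against each boundary, where the QUICK
stencil does not fit); nothing sinks in through the surface, and the
bottom cell accumulates what arrives — conceptually a sediment layer
whose remineralization feeds slow deep recycling. Time stepping is
classical fixed-step RK4 to equilibrium.

Numerical choices worth knowing:

* **Time step.** `auto_dt()` takes half of the stricter of the
  diffusive (`dz^2/2K`) and advective (`dz/w_s`) bounds, and
  additionally caps the step at 0.01 d. The cap exists because the
  fastest timescale in the model is not transport but nutrient
  turnover by high-affinity uptake during transient blooms
  (`B Vmax/K` reaches tens per day); without it, fixed-step RK4
  oscillates around zero concentrations and the clipping ledger
  inflates the nitrogen inventory.
* **Negative concentrations** produced by a step are clipped to zero
  and the created mass logged per variable; `nitrogen_budget()`
  reconciles inventory drift against this ledger exactly. With
  clipping disabled the scheme conserves total N to round-off.
* **Convergence** is declared when the maximum over variables and
  depths of `|dC/dt|/(C + eps)` (eps = 1e-6 umol/L), estimated from
  successive daily-averaged states across a 10-day trailing window,
  falls below the tolerance. With diel forcing the daily averaging
  makes the metric insensitive to the light cycle's phase. The
  slowest mode in the subtropical configuration is the quasi-
  exponential decay of deep heterotroph biomass toward its
  subsistence boundary (e-folding ~250 d), so tolerances below
  ~1e-4 per day cost several more simulated millennia while the
  upper-column structure is already static.
* **Initial condition:** 20 umol/L nitrate below 250 m ramping to
  zero at the surface, a 1e-3 umol/L inoculum of every population,
  and no NH4+/NO2-/detritus. Twin runs from different inocula agree
  at equilibrium, which is what licenses this arbitrary choice.

## Parameter provenance and calibration

Parameters printed in primary sources are used verbatim: the
stoichiometric `f = 0.03` and `d = 20 +/- 4`, the AOO uptake kinetics
and their uncertainties, nitrogen quotas of 0.12 and 1.2 fmol N per
cell, `y_D = 0.14`, `g_max = K_g = 1` (per umol/L units), and grazer
efficiency 0.5. The remaining rates live only in supplementary
material and are **calibrated defaults**, chosen once to reproduce
the qualitative structure of a stratified oligotrophic column — a
DCM near 100 m, a PNM of order 100-1000 nM just below it, an
ammonium maximum of smaller magnitude, nanomolar-to-tens-of-nanomolar
deep DIN tails — and marked as such in
`attr(ecosystem_params(), "provenance")`. The load-bearing ones:

* `m_b = 0.01` per day mortality: together with the NOO maximum
  growth rate (0.07 per day) it sets the deep nitrite tail through
  R\* = K L/(yVmax - L) ~ 48 nM.
* `K_D = 0.03`, `VmaxD = 0.714` per day: saturated heterotroph
  growth of 0.1 per day and a remineralization profile that releases
  most NH4+ between the DCM and ~300 m while leaving the bottom
  reactor a minor term.
* `z_mld = 20 m`, `K_max = 1e-2`, `K_min = 1e-5` m^2/s: a mixed
  layer confined to the upper ~50 m so that the PNM sits in the
  weakly mixed interior; with deeper `z_mld` the transport term
  swamps the R\* signal at the peak (the high-mixing fixture does
  exactly this on purpose).
* Light: `phi = 0.03` mol C per mol photons, `a_chl = 0.02` m^2 per
  mg Chl, `theta_max = 0.25` g Chl per g C, `I_max = 1400` uEin
  m^-2 s^-1, `k_w = 0.04` per m, `k_chl = 0.02` m^2 per mg Chl.
  These place the deep chlorophyll maximum near 130 m. Chlorophyll
  self-shading matters qualitatively: with `k_chl` doubled the
  phytoplankton collapse at the base of the euphotic zone becomes a
  near-discontinuity, and the single unresolved transition cell
  carries an ammonium spike fed by remineralization that neither
  guild can absorb; at the default value the transition is smooth
  and the no-difference experiment's two peaks coincide.
* Phytoplankton allometric coefficients are anchored so a 0.6 um
  cell has mu_max ~ 0.7 per day and specific affinity of order
  100 L per umol N per day; the 88.2 figure from the size-scaling
  literature is a calibration aid, not a target.
* The NOO volume factor defaults to 10; the ~50-fold ratio suggested
  by some recent observations is available as
  `ecosystem_params(noo_volume_factor = 50)`.

## What the fixtures emulate — and what they do not

`fixture_config()` bundles three columns: `subtropical_stratified`
(shallow mixed layer under a deep euphotic zone — the PNM case),
`high_mixing` (mixed layer deeper than the euphotic zone, sweeping
DIN and nitrifiers to the surface), and `abiotic_control` (no
biomass; nutrients only mix). They emulate the *ecological geometry*
of real columns: competitive exclusion above, nitrifier control
below, top-down losses declining with depth. They do not emulate
seasonality, horizontal advection, iron or copper limitation,
photoinhibition (deliberately absent — the vertical structure emerges
from competition alone), anaerobic nitrogen cycling, or the
community-level diversity of yields and affinities; a passing test
suite therefore says the mechanism is implemented faithfully, not
that any single real profile is reproduced quantitatively.

## Experiment tags and diagnostics

`apply_experiment()` isolates the two AOO/NOO differences: with both
active, the modelled nitrite maximum exceeds the ammonium maximum
roughly tenfold or more; with only the yield or only the affinity
difference the peak ratio falls to a few-fold, matching the
point-balance prediction `y_AOO : y_NOO ~ 1:3`; with neither, the
two peaks coincide. `rstar_profile()` reports the depth-resolved
subsistence concentrations with unsustainable depths masked `NA`
(never negative), `pnm_metrics()` locates peaks with parabolic
sub-cell refinement (ties to the shallower depth; the bottom 100 m
sediment band is excluded from peak scans), `oxidation_rate_profiles()`
returns the two nitrification steps in nmol/L/d, and
`nitrogen_budget()` audits conservation against the clipping ledger.
`tracer_aor()` implements the 15N incubation rate formula exactly as
published, including its sample-volume factor; because that makes
the nominal units nM per liter-day, a `include_volume = FALSE`
variant is provided.

In the deep, weakly mixed column the modelled nitrite sits close to
the NOO subsistence concentration; around the peak itself vertical
mixing holds concentrations above R\* — the two-regime structure
(transport-influenced upper PNM, organism-controlled lower PNM) that
motivates comparing both diagnostics.

## The ensemble

`run_ensemble()` repeats the column equilibrium under perturbed
parameters: normal draws for the culture-measured AOO kinetics,
a uniform 1-20 NOO volume factor entering through its cube root, and
uniform +/-50% bands for the listed uncertain ecosystem parameters.
Member draws are derived from `(seed, member index)` alone, so
results are independent of execution order; non-converged members
are flagged and excluded from the mean/s.d. envelopes. The
desk-scale default is 50 members; the published-scale experiment
(~1000) is a single argument away but is not run in the test suite.

## Problem sizes used by the test suite

The bundled defaults are 5 m resolution and a 1e-4 per day
tolerance. The water-column tests run the subtropical fixture at
10 m resolution: the experiment variants converge at a 1e-3 per day
tolerance within ~4000 simulated days (the no-difference case uses
3e-4 over a 9000-day horizon, since its peak equality emerges only
near full convergence), the grid-refinement check compares 10 m
against 5 m at a matched 4000-day age (tolerance-stopped runs of
different ages are not comparable, because the peak itself drifts
slowly), and the twin runs use a fixed 9000-day horizon. These sizes
were chosen as the coarsest configuration whose peak structure is
grid-converged to within a few percent.

## Known limitations

* Oxygen is not a state variable; an optional fixed-profile Monod
  limitation hook exists (`ecosystem_params(o2 = ...)`) but is off
  by default, matching the oxygenated domain of interest.
* Deep equilibria inherit the slow diffusive timescale of the
  quiescent interior: profiles below the thermocline keep drifting
  at ~0.1% per century of model days long after the upper-column
  ecology is static, so runs of different durations should not be
  compared pointwise near sharp gradients. For the same reason the
  equilibrium forgets its initial seeding only slowly in norm:
  because the no-flux column conserves total nitrogen, twin runs
  started from different inocula (with matched nitrogen) converge in
  structure within a few thousand days — identical peak ratios,
  peak depths within a fraction of a cell — while the residual
  profile difference decays with an e-folding of order 1e4-1e5 days.
  Claims of strict initial-condition independence should therefore
  be made on structural diagnostics, not profile norms, unless very
  long integrations are affordable.
* Equilibria below ~1000 m retain a slow memory of the initial
  nitrate inventory (interior diffusion is weak by construction);
  conclusions there should rest on the R\* diagnostics rather than
  absolute concentrations.
* The 15N tracer formula is a standalone utility; no isotope mass
  balance for carrier additions is implemented.
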