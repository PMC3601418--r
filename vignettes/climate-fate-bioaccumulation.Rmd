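---
title: "Methods: multimedia fate and fish bioaccumulation under climate scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimedia fate and fish bioaccumulation under climate scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(climfate)
```

`climfate` implements two screening experiments on the same question — how
much do the long-term temperature and precipitation shifts projected for the
end of the century move exposure concentrations of neutral organic
chemicals? This vignette documents the models, the parameter choices that
matter, what the synthetic study conditions do and do not represent, and the
numerical decisions.

## 1. The steady-state multimedia fate model

### Temperature physics

Every temperature effect enters through two relations. Partition
coefficients follow the van't Hoff form

$$K(T) = K_{ref}\,\exp\!\left[-\frac{\Delta U}{R}\Big(\frac{1}{T}-\frac{1}{T_{ref}}\Big)\right],$$

with the internal energy of phase change $\Delta U$ in kJ/mol (positive
$\Delta U$: $K$ rises with warming). The three coefficients of a chemical
are kept thermodynamically consistent: $\log K_{OW} = \log K_{AW} + \log
K_{OA}$ at the reference temperature and $\Delta U_{AW} = \Delta U_{OW} -
\Delta U_{OA}$, so the triangle closes at *every* temperature (a property
test asserts this at 268–313 K). Degradation rate constants follow
Arrhenius, $k(T) = k_{ref}\exp[-(E_a/R)(1/T - 1/T_{ref})]$, so warming with
$E_a > 0$ shortens half-lives.

Defaults for the hypothetical-chemical grid: $\Delta U_{OW} = -20$ kJ/mol;
$\Delta U_{OA}$ from the configurable linear map $-(10 + 3.5\,\log K_{OA})$
kJ/mol (more exothermic octanol sorption for heavier chemicals); activation
energies 10 kJ/mol in air (OH-radical chemistry) and 30 kJ/mol in condensed
media; reference half-lives 1,000 h (air), 10,000 h (water), 30,000 h
(soil, sediment) — persistent chemicals, so that fate patterns rather than
reactivity dominate the maps. All are arguments, not constants.

### World, transport and mass balance

The world is a reduced stand-in for a global multi-region parameterization:
four regions — Arctic (ARC), northern Europe (NEU), southern Africa (SAF)
and a rest-of-world reservoir (ROW) — each with five bulk compartments
(1,000 m atmosphere, 10 cm soil, 20 m freshwater, 3 cm sediment, 100 m ocean
mixed layer), linked by a closed chain of balanced atmospheric (1-week
exchange time) and surface-ocean (5-year) flows ARC–NEU–ROW–SAF. Regional
areas, ocean/land/freshwater splits, annual-mean temperatures (268–293 K)
and rain rates (0.25–1.0 m/yr) are conventional round numbers; everything
sits in the `fate_world` object and serializes to YAML.

Fugacity capacities use the standard bookkeeping: $Z_{air} = 1/RT$,
$Z_{water} = Z_{air}/K_{AW}(T)$, organic carbon $0.35\,K_{OW}(T)\,Z_{water}$
(Karickhoff), aerosol from a $K_{OA}$-based particle–gas relation
($\log K_p = \log K_{OA} + \log f_{OM} - 11.91$, $f_{OM} = 0.2$). D-values
cover degradation, inter-region advection, two-film air–water exchange, rain
dissolution, wet (scavenging ratio $2\times10^5$) and dry aerosol
deposition, air–soil diffusion, soil runoff, freshwater discharge,
sediment diffusion/deposition/resuspension, and two permanent removals:
sediment burial and POC export below the ocean mixed layer. The linear
balance `(losses − gains) f = E` is solved by dense factorization (the
systems are 20×20 here; anything below ~150 compartments is trivial), and
the solver refuses to return if the mass balance does not close to 1e-9
relative — conservation is a hard invariant, not a diagnostic.

A dynamic integrator (`dynamic_solve()`) exists solely to verify that the
steady state is the long-time limit; the scenario analysis itself is
annual-mean steady state (seasonality is resolved only in the fish model,
where it is the point). Vegetation, sea ice and snow are not modelled.

### The climate scenario

`apply_climate_scenario()` shifts every compartment of a region by ΔT and
scales its rain rate by (1+ΔP), leaving the baseline world untouched. The
default deltas — ARC +5.0 K/+15%, NEU +3.0 K/+10%, SAF +3.5 K/−10%, ROW
+3.0 K/0% — encode Arctic amplification, wetter high latitudes and
subtropical drying, all inside the multi-model end-of-century envelope
(+1.1 to +6.4 °C, ±20% precipitation). Emissions (1,000 mol/h to the air
of each non-Arctic region, 0.1% of that to Arctic air, so the Arctic burden
is transport-dominated) are held fixed across scenarios; the optional
`scale_emission_with_temperature()` models temperature-responsive passive
volatilization ($E \propto \exp[(\Delta U_A/R)(1/T-1/T_{ref})]$, with the
condensation-sign convention $\Delta U_A < 0$) and is OFF by default.

Because the model is linear in emissions, every concentration ratio is
invariant to emission magnitude — asserted as a property test, and the
reason the ratio maps are meaningful without a real emission inventory.

### What the scan shows

Under the default conditions the 315-chemical scan stays within a factor of
1.64 of baseline everywhere (median deviation 9%): air concentrations rise
broadly, bulk soil falls, dissolved concentrations go both ways with the
more hydrophobic chemicals responding positively. The PCB-153 reference run
(literature-style property set: log K~OW~ 6.9 / K~AW~ −2.0 / K~OA~ 8.9,
ΔU~OA~ = −80 kJ/mol, persistence-class half-lives) shows air up 7–27%
while the global inventory falls ~27% and overall persistence
$P_{OV} = \sum M / \sum(\text{degradation rate})$ falls ~25% — faster
degradation everywhere outweighs enhanced volatilization. The inventory
reduction sits a couple of points above the ~20–25% band expected of this
scenario class; the Arctic +5 K delta acts on cold compartments where the
Arrhenius factor is steepest, and we report the number as computed rather
than trimming the scenario to the band.

## 2. The bioenergetics–bioaccumulation model

### Thermal performance and growth

Daily growth follows a Wisconsin-style energy budget,

$$\frac{dW}{dt} = W\,\frac{a\,C_{spec}\,ED_{prey} - R_{spec}\,O}{ED_{fish}},$$

with specific consumption $C_{spec} = C_A W^{C_B}\, p\, f_C(T)$ and specific
respiration $R_A W^{R_B} Q_{10}^{(T-T_{ref})/10}$ (uncapped — metabolic
costs keep climbing past the feeding optimum). The consumption multiplier
$f_C$ is the part that carries the climate signal: zero at or outside the
critical limits, a $Q_{10,cons}$ exponential rise to 1 at $T_{opt}$
(2.3, steeper than the respiratory 2.0, so aerobic scope widens toward the
optimum), and a steep power-law collapse to zero at $CT_{max}$.

The defaults describe a round-goby-like warm-water benthic fish:
$CT_{min} = -0.5$ °C, $T_{opt} = 26$ °C, $CT_{max} = 30$ °C, and a baseline
temperature cycle $12 + 12\sin(2\pi(d - 121.75)/365)$ °C (0–24 °C, peak in
early August, a Lake-Erie-like year). Three of these choices were genuinely
open and deserve their reasoning:

* **The sub-optimal limb is exponential, not polynomial.** A power-law rise
  from $CT_{min}$ makes mid-range consumption so weak relative to Q10
  respiration that *any* warming reduces growth — the opposite of the
  within-scope physiology the model exists to express. With the
  exponential limb, a warming offset multiplies feeding by
  $\approx Q_{10,cons}^{\Delta T/10}$ everywhere below the optimum.
* **$CT_{min}$ sits just below the winter minimum.** Great Lakes gobies
  overwinter and keep feeding weakly near 0 °C. Placing a hard feeding
  cutoff inside the experienced temperature range also creates unphysical
  ratio spikes (a scenario fish feeding while the baseline fish is hard-off
  gives unbounded relative responses near the cutoff day).
* **$CT_{max} = 30$ °C is the feeding-collapse threshold, not the acute
  lethal limit** (which is several degrees higher). With the baseline peak
  at 24 °C, +2 °C puts the summer at the optimum (fastest growth) and +3 °C
  overshoots it, so five-year growth orders baseline < +1 < +2 and falls
  back to roughly baseline at +3 — the within-scope/overshoot pattern the
  scenario comparison is about. These landmarks were fixed from that growth
  pattern and then frozen; no parameter was revisited against the
  concentration-ratio summaries.

Weight is floored at half the initial weight (starvation clamp); the floor
never binds under the default scenarios.

### Toxicokinetics

Uptake and loss use kinetic (Arnot–Gobas-style) rate constants per day:
gill uptake $k_1 = E_W\,\gamma W^{0.65-1} f_R(T)$ with gill extraction
$E_W = 1/(1.85 + 155/K_{OW})$; elimination $k_2 = k_1/(L_{fish} K_{OW}
\cdot 10^{-6})$; dietary uptake $k_D = E_D\,C_{spec}$ with gut assimilation
$E_D = 1/(3\times10^{-7} K_{OW} + 2)$; fecal egestion $k_E = 0.1\,k_D$;
growth dilution $k_G = \dot W/W$; biotransformation $k_M = \ln 2 / HL_B$.
Water and diet concentrations are constant (diet at lipid–water equilibrium
with the freely dissolved concentration unless supplied), so ratios are
invariant to the exposure level.

The concentration ODE is advanced with the *exact* solution for
piecewise-constant daily rates, $C_{t+1} = C^* + (C_t - C^*)e^{-\lambda}$
with $C^* = U/\lambda$: unconditionally stable and exact for the fastest
cells ($HL_B = 0.1$ d, $\lambda \approx 7$ d$^{-1}$), where an explicit
Euler day step would need ~30 sub-steps to be merely stable. Growth stays
explicit Euler (its equation is nonlinear and slow). A test pins the
constant-environment simulation to the algebraic steady state
$(k_1 C_{wd} + k_D C_{diet})/(k_2+k_E+k_M)$ within 0.1%.

### What the scan shows, and its honest limits

Year-3 daily ratios over the 9×5 grid (log K~OW~ 0–8, $HL_B$ 0.1–1,000 d)
under +2/+3 °C reproduce the expected structure: increases in spring and
autumn (up to +30% at +3 °C), decreases in late summer (down ~30% at
+3 °C), both concentrated at $HL_B \le 1$ d and log K~OW~ > 6, with the
POP-like corner (log K~OW~ 6–8, $HL_B \ge 100$ d) clearly damped relative
to the fast-metabolizing corner.

Two quantitative features of this parameterization are weaker than the
benchmark behaviour of a fully calibrated goby model and are reported as
such rather than tuned away. First, the POP-like corner retains a
persistent ~10–20% concentration *surplus* under warming: the consumption
Q10 raises dietary uptake ~20–30% through the warm season while growth
dilution of a year-3, weight-limited fish rises only ~10%, and the small
egestion term cannot close the gap. Second, for the same reason the
POP-like corner shows essentially no seasonal *decreases*. Both would
respond to species-specific consumption/egestion coefficients that are
outside what this synthetic parameterization can claim to know.

## 3. Uncertainty screen

`uncertainty_screen()` runs three seeded Monte Carlo sets — chemical inputs
only (log-normal perturbation of the partition coefficients in log10 space,
sd 0.5, and of the half-lives), climate inputs only (uniform ΔT in
+1.1–+6.4 K, ΔP in ±20%), and both — and reports each group's variance
share of a chosen output (Arctic air ratio or baseline concentration). Its
role is the contextual claim of the analysis: the chemical-input
uncertainty of any real assessment spans an order of magnitude or more,
against which a within-factor-of-2 climate signal is modest. n = 200 draws
by default; the screen is the package's only stochastic component and takes
an explicit seed.

## 4. Problem sizes and numerical notes

The shipped experiment sizes — 315 grid chemicals × 2 steady states of a
20-compartment world (~15 s), a 45-cell × 3-scenario five-year daily fish
scan (<1 s) — were chosen as the smallest setups that cover the documented
partitioning-space and half-life ranges with the stated resolutions; both
scale linearly if refined, and a grid-refinement test checks that halving
the chemical-space step moves the headline fold-change by <5%. Degenerate
inputs are rejected loudly (non-positive half-lives or volumes, singular or
negative-solution fate systems, unstable dynamic steps, all-zero emission
maps); ratio maps are only formed where the baseline output is positive,
which the emission pattern guarantees.

## 5. Known limitations

The four-region world has no vegetation, sea-ice, snow or permafrost-carbon
compartments, no primary-productivity/organic-carbon scenario coupling, and
its deltas are illustrative values inside the projection envelope, not a
downscaled product — so the ratio maps indicate directions and magnitudes
of thermodynamic forcing, not regional predictions. The fish model is a
single organism with fixed exposure: no food-web rewiring, no
species-specific calibration, no human-diet endpoint. Ionizing chemicals
and mercury are out of scope (the partitioning physics assumes neutral
organics).
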