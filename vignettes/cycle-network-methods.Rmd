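---
title: "The PGHS-1 cycle-network model: methods and design choices"
author: "pghsnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The PGHS-1 cycle-network model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pghsnet)
```

## The model

Prostaglandin H synthase-1 (PGHS-1, also COX-1) is a bifunctional enzyme:
its cyclooxygenase (COX) site oxygenates arachidonic acid (AA) to the
hydroperoxide PGG2, consuming two O2 per turnover, and its peroxidase (POX)
site reduces PGG2 to PGH2 at the heme, oxidising the heme and ultimately an
exogenous reducing cosubstrate (RC, e.g. phenol or adrenaline). The two
activities are coupled through the branched-chain mechanism: the POX cycle
generates a tyrosyl radical on Tyr385 in the COX channel, which abstracts a
hydrogen atom from bound AA and thereby ignites COX turnover; the released
PGG2 feeds the POX cycle of other enzyme molecules, making the system
autocatalytic. During catalysis the enzyme also destroys itself
(self-inactivation) through its radical-bearing intermediates.

Rather than positing a handful of lumped reactions, the model works at the
level of *microstates* of the catalytic domain. A catalytic state is a
composition of three components:

* heme (POX site): `Fe(III),PP`, `Fe(IV),PP*+` (ferryl-oxo plus porphyrin
  radical cation, "Intermediate I"), or `Fe(IV),PP` (ferryl, reduced
  porphyrin, part of "Intermediate II");
* Tyr385: ground state or tyrosyl radical;
* COX site: empty, AA, arachidonyl radical AA*, or peroxyl radical PGG2*.

All 3 x 2 x 4 = 24 compositions are realised (labels `E1`–`E24`), plus three
COX-dead, peroxidase-only species (`D1`–`D3`, one per heme state) and one
absorbing fully-inactive species (`FIE`): 28 enzyme forms in total. The six
metabolites AA, O2, RC, OC (oxidised cosubstrate), PGG2 and PGH2, and an
explicit damage sink for ligands discarded on inactivation, complete a
35-dimensional mass-action ODE system.

## Composition-driven reaction templates

The reaction list is not hand-enumerated; it is *generated* by applying
fourteen templates to every species whose composition matches the template's
predicate (`pghs_reactions()`):

| template | transformation | rate |
|---|---|---|
| G1 | AA binding to Tyr*-bearing empty sites (reversible) | `k1`, `Kd1` |
| G2 | AA binding to ground-Tyr empty sites (reversible) | `k12`, `Kd12` |
| G3 | H abstraction: Tyr* + AA -> Tyr + AA* | `k2` |
| G4 | oxygenation: AA* + 2 O2 -> PGG2* | `k3` (O2 squared) |
| G5 | PGG2 release regenerating Tyr* | `k4` |
| G6 | peroxidase step: Fe(III) + PGG2 -> Fe(IV),PP*+ + PGH2 | `k7` |
| G7 | PP*+ reduction by RC | `k8` |
| G8 | ferryl reduction by RC | `k6` |
| G9 | Tyr* reduction by RC | `k5` / `k10` |
| G10 | intramolecular e- transfer PP*+ + Tyr -> PP + Tyr* | `k9` / `k11` |
| G11 | direct H abstraction by PP*+ from bound AA | `k13` |
| S1 | any PP*+-bearing species -> FIE | `kin1` |
| S2 | E5, E9, E15, E20 -> FIE | `kin2` |
| S3 | COX-site radical-bearing species -> COX-dead | `kin` |

Occupancy-conditional rates encode steric control: intramolecular electron
transfer is fast through an empty COX channel (`k9` = 310 /s) and slow when
the channel is occupied (`k11` = 1.1 /s); reduction of the Tyr385 radical by
RC uses `k5` for empty or PGG2*-occupied sites and the near-zero `k10` when
arachidonate blocks the channel. Where the occupancy class of a state is not
stated by the mechanism (AA*-occupied sites in G9), the arachidonate-like
branch (`k10`) is used, on the steric argument that the arachidonyl radical
fills the channel exactly as AA does.

Under the default `composition_complete` policy every matching species
reacts, which yields 91 reaction instances; the `paper_enumerated` policy
retains only the 56 instances that carry an explicit reaction number in the
source scheme and exists for comparison — the published count of 66 lies
between the two closures and cannot be reconstructed exactly because the
full listing is not available. Dynamics depend only on composition, so the
generative closure is the reproducible choice.

Every reaction converts exactly one enzyme form into one enzyme form, so
three moieties are conserved analytically: total enzyme, RC + OC, and the
arachidonate moiety (free AA + site-bound AA/AA*/PGG2* + PGG2 + PGH2 +
damage sink). `pghs_conservation()` checks all three on every trajectory;
the test suite requires drift below 1e-6 relative (typically ~1e-13).

## The unified parameter set

`pghs_parameters()` carries the 18 fitted constants (defaults in the
roxygen page, units 1/(uM s), 1/s, uM; `k3` in 1/(uM^2 s)). Binding steps
are parameterised by on-rate and dissociation constant with
`koff = kon * Kd`. Two peroxidase profiles are provided:
`phenol_pgg2` (default) and `adrenaline_h2o2`, which replaces the
peroxidase subset `k5, k6, k7, k8` by the values fitted for the
H2O2/adrenaline assay. `k10` is kept at its tabulated 0.1 1/(uM s) even
though the mechanism discussion treats it as approximately zero — the
tabulated value wins, and a config override is one argument away.

## Simulation

`pghs_simulate()` integrates the system with the BDF solver `vode`
(via deSolve) using an Rcpp mass-action right-hand side and an analytic
Jacobian. Numerical choices that matter:

* **Smooth rate laws.** The RHS is the raw mass-action polynomial, with no
  clamping of negative concentrations. A clamped RHS is only C0; in testing
  it provoked solver undershoot of fast quasi-steady intermediates to
  -2e-5 uM at the self-inactivation shoulder, while the smooth form keeps
  worst-case negativity at ~1e-9 uM across a nine-condition scan.
* **Seeding.** Ignition needs a peroxide tone; the default configuration
  seeds 0.01 uM PGG2. The activation-threshold analysis depends on this
  choice, which is therefore exposed prominently in `pghs_config()`.
* **Oxygen.** Initial O2 defaults to 200 uM (air-saturated buffer) and may
  be clamped constant; at `k3` = 173 1/(uM^2 s) oxygenation is far from
  rate-limiting, so results are insensitive to O2 above roughly 50 uM.
* **Initial enzyme state.** The whole pool starts as the resting
  holoenzyme `E1` unless `init` overrides it.
* **Tolerances.** Defaults rtol 1e-8, atol 1e-10; halving them moves the
  PGH2 endpoint by less than 1e-4 relative (tested).
* **Output grid.** 0 plus 400 log-spaced points from 1 ms. Fluxes are
  recomputed from the stored states after integration. Because the run
  starts from instantaneously mixed free enzyme and substrate, net binding
  fluxes are discontinuous at t = 0 (a ~20 us equilibration transient);
  flux *maxima* quoted for binding reactions therefore exclude the t = 0
  grid point.

The ODE count (35) differs from a formulation that eliminates states via
the conservation laws; the laws are enforced as checks instead.

## Derived observables

* `oxygen_consumption_rate()`: V_O2(t) = 2 x sum of oxygenation fluxes.
* `activity_duration()`: width of {t : V_O2 >= 5% of max}; the operational
  definition behind "the enzyme is active for tens of seconds".
* `dose_response()` / `apparent_km()`: one simulation per AA value; Vmax is
  the plateau (flagged if the curve has not flattened within 5% at the last
  two grid points) and Km is read at half-maximum by monotone
  interpolation. A hyperbolic fit is deliberately avoided: at high RC the
  curve is sigmoidal and a Michaelis fit would be mis-specified, while the
  half-maximum reading remains a well-defined *apparent* constant.
* `eadie_scatchard()`: (V/E, V/AA/E) coordinates with two diagnostics, a
  line-deviation metric and a majority-of-second-differences concavity
  flag. A true Michaelis system is exactly linear (used as the oracle in
  tests); positive cooperativity shows as the classic hook — V/AA/E first
  rises with V/E at the sigmoid foot, then falls along a downward-concave
  arc — so concavity is judged by majority rather than at every point.
* `activation_threshold()`: log-bisection on AA per RC level until PGH2 at
  t_eval (default 300 s, past the activity burst) crosses the criterion
  (default 0.02 uM) within 1%.
* `consumption_ratio()`: cumulative (RC0 - RC(t))/(AA0 - AA(t)) at t
  (default 30 s). Complete PGG2 -> PGH2 conversion would give 2.
* `flux_table()`: max-over-time net fluxes of the PGH2-producing,
  PGG2-releasing and cycle-connecting reactions, one simulation per RC
  level, at 35 nM enzyme and 80 uM AA — the conditions of the flux
  analysis, which the source table itself leaves unstated. "Rate" means
  max-over-time because the rates are strongly time-varying.

## Calibration

`pghs_fit()` estimates a masked subset of the 18 constants by weighted
least squares against `pghs_dataset` time series. Declared choices (the
original optimisation pipeline behind the published constants is not
described, so these are this package's own):

* log10 parameterisation with bounds +/-3 decades around the defaults;
* scale-free weights 1/max(value)^2 per observable within each dataset
  (per-dataset scaling would down-weight the ~10x smaller PGH2 curves
  relative to PGG2 and erase most of the information about inactivation);
* seeded Latin-hypercube multistart (default 16 starts), all starts scored,
  the best few polished by derivative-free Nelder-Mead (golden-section in
  one dimension) — gradient-based polishing stalls on the penalty plateaus
  left by failed integrations at extreme parameter values;
* failed simulations contribute a large finite penalty rather than an
  exception, so the optimizer can pass through;
* parameter grouping is fixed by the template-to-constant map of the
  network generator; regrouping is out of scope.

`profile_objective()` re-minimises over the remaining free parameters along
a grid for one parameter; flat profiles flag constants the data do not
constrain (e.g. `k8`, which is near zero and sits under everything else).

### Parameter-recovery harness

Because the calibration data behind the published constants exist only as
figures, the calibration surface is validated by *recovery*: synthetic
datasets are generated from the default constants
(`generate_fixtures()`), noise is applied, and the fit must return the
truth. The harness fixture uses prostaglandin-kinetics conditions at RC in
{10, 100, 1000} uM with 15 log-spaced sampling times over 1–600 s. The
low-RC condition is essential and was chosen on identifiability grounds,
once, before running the recovery test: the COX-inactivation constant
`kin` shares its dominant source states (E5, E9, E15, E20) with the much
larger fixed `kin2`, so its distinctive leverage comes from two-radical
states that are populated appreciably only when little cosubstrate is
available to drain them; at the generator's default conditions
(RC >= 100 uM) the objective is flat in `kin` over a decade, with the
low-RC condition it has a clear curvature minimum at the truth.

## Morris screening

`pghs_morris()` implements the elementary-effects design: r trajectories
(default 100) of k+1 points on a p = 4 level grid (jump
delta = p/(2(p-1)) = 2/3) in the unit hypercube, mapped log-uniformly to
x/÷10 ranges around the defaults; per parameter, mu is the signed mean and
sigma the standard deviation of the elementary effects, and the ranking
statistic is sqrt(mu^2 + sigma^2). The output functional is the area under
the PGH2 time course at 35 nM enzyme, 80 uM AA, 100 uM RC over 1200 s.
Levels, trajectories, ranges and the use of signed mu (which can cancel
for non-monotone responses — the absolute-mean variant is not used) are
declared choices; the source analysis states only the ranking formula and
the output functional. The qualitative orderings the screening must
reproduce — the PP*+-driven inactivation (`kin1`) outranking the
Intermediate-II route (`kin2`), and the binding dissociation constant
`Kd12` outranking its insensitive on-rate `k12` — hold with wide margins
and are asserted in the acceptance suite at r = 100.

## Synthetic fixtures

`generate_fixtures()` emulates the three calibration dataset classes:
prostaglandin production kinetics (35 nM enzyme, 80 uM AA, phenol at
100/1000/5000 uM), AA-consumption kinetics (AA at 0.5/1/2/20 uM, 1000 uM
phenol; the condition text and the figure caption disagree on whether the
varied quantity is AA or enzyme, and the methods text wins), and
adrenochrome accumulation (adrenaline at 0.32–3.22 uM, 1050 uM H2O2, no
AA). Sampling defaults to 10 log-spaced points per scenario span; noise is
multiplicative Gaussian (sd 5%) truncated at zero, as appropriate for
scale-proportional concentration error. The generator emulates curve
shapes and noise scale — it does not emulate instrument baselines,
autocorrelated errors, or inter-batch enzyme-activity variation, so
passing recovery tests show identifiability under the model's own
error assumptions, not robustness to real experimental artefacts.

## Known limitations

* **Incomplete peroxidase conversion.** Under the default constants most
  PGG2 remains unconverted (consumption ratio RC/AA well below the
  stoichiometric 2), and PGG2 accumulates to a plateau rather than
  declining after the COX burst: peroxidase turnover cannot outlive the
  enzyme because the PP*+-driven inactivation extinguishes the remaining
  POX cycle within seconds. Observables that depend on sustained late POX
  activity inherit this.
* **Flux-table magnitudes scale with total enzyme.** The PGG2-release flux
  is bounded by k4 x E_total (0.455 uM/s at 35 nM), so literature flux
  tables reported without their enzyme concentration can disagree with the
  computed maxima by large factors even when the kinetic structure
  (which cycles dominate at which RC) is reproduced.
* `kin` is only weakly identifiable from metabolite time courses at
  moderate-to-high cosubstrate (see the recovery harness above); `k8` and
  `k12` are flagged by flat profiles, consistent with the screening.
* NSAID/inhibitor binding, the PGHS-2 isoform, dimer allostery and
  graph-theoretic cycle enumeration are out of scope.

## Problem sizes used by the checks

The test suite and acceptance script run on desk-scale problems chosen as
the package's own defaults: single simulations use the 400-point reporting
grid; the recovery fit scores 16 starts and polishes 4; the Morris screen
uses r = 100 trajectories over the 18 constants (1900 model evaluations).
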