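---
title: "Modelling ligand rebinding and cavity migration in hexacoordinate globins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ligand rebinding and cavity migration in hexacoordinate globins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngbkin)
```

## The physical picture

Neuroglobin and other hexacoordinate globins keep their heme iron
six-coordinate at rest: the distal histidine occupies the sixth axial
position, and an exogenous ligand (CO, O2, NO) can only bind after the His
has dissociated. When a bound CO is photodissociated by a nanosecond laser
pulse, the ligand finds itself in the distal pocket (the primary docking
site, DS) and from there it can either rebind the iron, escape to the
solvent through the His gate, or wander through a chain of internal
hydrophobic cavities. The observed rebinding kinetics at ~436 nm is
multiphasic over nine to ten decades of time, and the different phases
carry the rates of these elementary steps.

`ngbkin` implements the minimal branched reaction scheme that accounts for
these kinetics, over eight explicit states:

* `B0` — CO-bound protein (absorbing on a <= 1 s window);
* `DS` — the geminate pair;
* `A`, `B` — sequential internal docking sites;
* `T1` — a lumped dead-end trap (high barrier to the solvent);
* `T2` — a lumped trap with its own solvent connection;
* `P5` — five-coordinate deoxy protein, ligand in solvent;
* `P6` — bis-His six-coordinate deoxy protein.

Transitions: `DS -> B0` (k_m1), `DS <-> P5` (k_2 and k_m2·[CO]),
`DS <-> A` (k_c, k_mc), `A <-> B` (k_d, k_md), `B <-> T1` (k_e, k_me),
`B <-> T2` (k_f, k_mf), `T2 <-> P5` (k_3 and k_m3·[CO]) and
`P5 <-> P6` (k_b, k_mb). Two rates are bimolecular (k_m2, k_m3,
M^-1 s^-1); they only ever enter the generator multiplied by the CO
molarity, so the model is a linear (pseudo-first-order) system
`dp/dt = Q p` with columns of `Q` summing to zero.

Three modelling choices deserve comment, because the scheme drawing alone
does not force them:

* **Unit analysis fixes the branch topology.** Of the fifteen rates, only
  k_m2 and k_m3 carry M^-1 s^-1; a bimolecular entry rate must connect the
  solvent to a protein state, which uniquely assigns T2 (not T1) the
  second solvent channel and makes T1 the dead-end branch.
* **His coordination only competes while the ligand is in solvent.** The
  P5/P6 equilibrium is defined for the deoxy protein with the ligand
  outside; we do not allow P6 formation while the ligand occupies internal
  cavities. This is the minimal reading of the competing-reaction picture.
* **B0 is absorbing by default.** Thermal CO dissociation (k_OFF ~ 0.1
  s^-1) is negligible over the ~1 s observation window; it can be enabled
  with the `k_off` argument of `build_generator()` / `simulate_scheme()`,
  in which case dissociation re-forms the geminate pair.

Unless stated otherwise, 1 atm CO is taken as 1.0 mM dissolved CO near
20 °C (a configurable Henry coefficient of 1e-3 M/atm), the photolysis
yield is 1 (traces are normalized), and the default observable is the
unbound fraction N(t) = 1 − B0(t). An optional weight vector lets P6
contribute with a different effective extinction — the residual
absorbance plateau around 10 ms reflects the six-coordinate spectrum —
but since extinction coefficients are sample-dependent we default to the
unweighted population observable.

```{r example-sim}
rt <- ngb_rates("cace")          # icefish rate table at 20 degC
cond <- condition(co_atm = 1)    # 1 mM CO
sim <- simulate_scheme(rt$rates, cond, log_times(1e-9, 1, 10))
round(tail(sim$states[, "B0"], 3), 4)
```

## Numerics of the simulation

Rate constants span ~1e-2 to 1e10 s^-1, so the ODE system is extremely
stiff. The default integrator is `deSolve::lsoda` with the analytic
Jacobian (which for a linear system is just `Q`), `rtol = 1e-10` and
`atol = 1e-12`; these tolerances hold the populations to well below 1e-8
absolute error against the closed-form solution, which is the contract the
tests enforce. (Nominal tolerances an order looser would sit exactly at
the contract boundary; tightening them costs little because the system is
only 8-dimensional.) Because the scheme is linear and time-invariant, a
closed-form solution by eigendecomposition of `Q` is also available
(`method = "eigen"`), roughly two orders of magnitude faster; it is what
the fitting machinery evaluates internally. A scaling-and-squaring Padé
matrix exponential (`method = "expm"`) serves as the fallback when either
route fails (near-defective eigenbasis, integrator breakdown), and the
result is flagged. The test suite cross-checks all routes against an
independent matrix exponential (`Matrix::expm`) on random stiff rate sets.

Populations are reported on log-spaced time grids (default 1 ns to 1 s),
matching how rebinding curves are measured and displayed.

## Global trace fitting

`fit_traces()` fits the scheme to one or more traces by least squares on
the normalized signal over a log-time-resampled grid (10 points per
decade), so every kinetic phase contributes comparably and a million-point
oscilloscope trace does not drown the nanosecond decades. Parameters are
searched in log10 space within bounds (default 1e-3 to 1e12).

The 15-dimensional landscape is multimodal in a structured way: solutions
exist in which the T2 solvent channel substitutes for the His-gate entry
route, or in which the trap branches are switched off and the A/B chain
absorbs their flux. Plain multi-start Levenberg-Marquardt from
Latin-hypercube draws finds these impostors more often than the truth. The
default strategy (`strategy = "staged"`) therefore exploits the scheme's
natural hierarchy:

1. fit the geminate/escape/entry trio (k_m1, k_2, k_m2) with everything
   else off — these rates dominate the visible phases;
2. densely screen the His-coordination pair (k_b, k_mb), whose basin is
   narrow because the hexacoordination plateau is a percent-level feature;
3. jointly refit the five core rates, then screen the migration branch
   with the core held, carrying several refined candidates (including one
   with solvent re-entry through T2 disabled) into independent full
   refits;
4. polish with seeded basin hops at three widths, interleaved with
   dedicated re-screens of the weakly coupled subsystems (the T2 branch
   and the His pair).

All randomness is derived from a single seed; a fixed seed yields a
bit-identical `fit_result`. Uncertainties are linearised (from the
residual Jacobian); `profile_identifiability()` provides 1-D profile
objectives and flags flat directions, which is the honest answer for the
dead-end trap rates when the data carry no T1 flux. With a single trace
and all fifteen rates free the problem is structurally unidentifiable and
the fit warns accordingly; two CO pressures are the minimum informative
design because only the bimolecular steps scale with [CO].

What the synthetic studies show — and what they do not: on the
two-pressure pairs generated from the packaged rate tables at 0.5 %
Gaussian noise (the seeded study conditions shipped in the test suite),
the well-determined rates (k_m1, k_2, k_m2, k_b, k_mb) are recovered to
within ±0.15 log10 units and the His equilibrium constant K_H to within
±10 %. A caveat on K_H: the hexacoordination plateau is a percent-level
feature, so at this noise level the least-squares optimum for the
k_b/k_mb ratio itself scatters by tens of percent from one noise
realization to the next — descending from the generating values gives the
same scatter, so this is estimator variance, not search failure. K_H
precision claims should always be made for a stated realization or from
replicate experiments. The migration-branch rates are only weakly
determined — their profiles are shallow, and the fitted values should be
read as order-of-magnitude estimates, exactly as their large tabulated
uncertainties suggest. Real traces add baseline drift, photoselection and
detector nonlinearity that the additive-Gaussian generator does not
emulate, so passing recovery tests bounds estimator behaviour under the
stated noise model only.

## Thermodynamic layer

`tst_delta_g()` converts a rate constant into an activation free energy by
transition-state theory with transmission coefficient 1,
ΔG‡ = RT ln(k_B T / (h k)), with R = 1.98720e-3 kcal/(mol K) and CODATA
k_B/h. Bimolecular rates are first brought to pseudo-first order at a 1 M
standard state (flagged in the output of `rates_delta_g()`), the standard
dimensional convention. `eyring_fit()` regresses ln(k/T) on 1/T to
separate ΔH‡ and ΔS‡; per-temperature rate sets are fitted independently
and then regressed, rather than fitting a single temperature-global model
— mirroring how activation parameters are conventionally extracted from
flash-photolysis series over, say, 5–20 °C.

Derived binding constants for the resting (six-coordinate) protein:

* K_H = k_b / k_mb, the His-coordination equilibrium;
* k_ON = k_m2 · k_m1 / (k_m1 + k_2), the effective bimolecular on-rate to
  the five-coordinate protein (entry rate times inner binding yield);
* k_ON,obs = k_mb · k_ON [CO] / (k_b + k_ON [CO]), the much slower
  observed rate when His coordination competes, bounded by k_mb.

```{r derived}
derived_constants(ngb_rates("cace"))
```

Reported values are conventionally rounded to two significant figures;
full precision is retained internally.

## Relaxation fits

Autoxidation of the oxy protein (oxy -> met, single-wavelength trace at
580 nm, normalized between an oxy and a ferricyanide-met reference via
`normalize_endpoints()`) and stopped-flow CO displacement by excess NO
(415 nm) are fitted with one or two exponentials under positivity
constraints (`fit_exponential()`). For two components the fit is reported
ordered by amplitude, and the kinetics are flagged heterogeneous only when
the minor amplitude reaches 5 % of the span — a below-threshold minor
phase is reported but not flagged. The displacement off-rate
(`koff_from_displacement()`) is the dominant-amplitude rate. Fits are
unweighted; amplitude weighting is a config-level choice we deliberately
avoid since the traces are normalized.

## Implicit ligand sampling

`compute_grid()` estimates the free energy of inserting a rigid diatomic
CO probe at every node of a regular grid (default 0.5 Å spacing) by
Boltzmann-averaging the probe-protein interaction energy over trajectory
frames and 20 probe orientations:

G(r) = −k_B T ln ⟨exp(−E(r, Ω)/k_B T)⟩_{frames, Ω}

relative to the non-interacting bulk reference, so empty space is exactly
zero. The interaction is a 12-6 Lennard-Jones sum with Lorentz–Berthelot
combination, a 10 Å cutoff without switching, and an energy cap of 100
kcal/mol applied before exponentiation (which also bounds G by the cap in
overlap regions). The CO probe parameters are the standard two-site set
(ε_C 0.11, ε_O 0.12 kcal/mol, R_min/2 2.10 and 1.70 Å, bond 1.13 Å);
well depths are stored positive although force-field tables print them
negative. The probe is apolar — no charges — and its bond midpoint sits on
the grid node.

Orientations come from a deterministic Fibonacci lattice
(`probe_orientations()`): reproducible, quasi-uniform, and covering the
full sphere (the two probe sites differ, so u and −u are distinct poses).
Twenty orientations resolve the orientational average well inside
cavities; in the steep repulsive shoulder near walls the 20-point
quadrature can deviate from a converged orientational integral by a few
tenths of kcal/mol — maps should be read quantitatively below ~3–4
kcal/mol and qualitatively above. Frame alignment prior to gridding is the
caller's responsibility (`align_frames()` provides a Kabsch aligner).

`path_profile()` extracts migration barriers between user-supplied
waypoints (cavity centres) on the 26-connected grid graph. The path
objective is minimax — minimise the highest free energy met along the
path — because with free energies that are negative in the wells a
sum-of-edge-costs objective is unbounded on an undirected graph, while the
minimax cost is exactly the saddle height that determines the rate. The
reported barrier per leg is max(G along the leg) − G(leg start).

The toy trajectory generator (`gen_toy_trajectory()`) builds a jittered
Lennard-Jones template: a large spherical cage (radius 4.6 Å, walls near
the probe's LJ minimum distance, hence a deep insertion minimum) with an
angular exit channel, and a tight second cage (radius 2.8 Å, mostly
repulsive interior). This gives desk-scale analogues of a buried
favourable cavity, an exit channel saddle and an unfavourable pocket, with
per-frame Gaussian jitter of 0.15 Å emulating thermal disorder. It is
emphatically not a protein: barriers from the toy system test the
machinery (against a brute-force Widom-insertion oracle), not biology, and
the package makes no attempt to reproduce figure-read barrier values for
the real proteins, which would require the original trajectories.

## Synthetic data and the study conditions

The generators default to the conditions of the flash-photolysis study
they emulate: log-spaced 1 ns – 1 s sampling, CO pressures of 1 and 0.1
atm, 20 °C, additive Gaussian noise of σ = 0.005 (0.5 % of the span,
a realistic averaged-photomultiplier noise level; 2 % represents a poor
trace), photolysis yield 1. Temperature series use four temperatures,
278.15–293.15 K, a stand-in for the unspecified number of temperatures in
typical 5–20 °C series. The three packaged rate tables are the most
meaningful test points because every derived quantity printed alongside
them can be checked.

Problem sizes used in the shipped tests were chosen to keep the whole
suite in the tens of minutes on one core: 181-point traces for fitting,
50-frame toy trajectories on coarse (1 Å) grids for the ILS cross-checks,
100-replicate recovery studies for the relaxation fits. All are
configurable upwards.

## Known limitations

* The scheme is minimal by construction: the four real migration pathways
  are lumped into two branches, so branch-level rates are effective, not
  structural.
* Fitted migration rates are weakly identifiable from two-pressure data;
  only the core five rates (and K_H) should be quoted with confidence.
* The ILS module treats the probe as rigid and apolar; electrostatics and
  probe flexibility are out of scope.
* The observed k_ON,obs formula assumes rapid His pre-equilibrium; at CO
  concentrations far above saturation it returns k_mb by construction.
* No Bayesian posterior sampling; uncertainties are linearised or
  profile-based.
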