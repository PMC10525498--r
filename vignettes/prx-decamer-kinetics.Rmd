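---
title: "Modelling the peroxiredoxin dimer-decamer cycle with prxcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the peroxiredoxin dimer-decamer cycle with prxcycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prxcycle)
```

## The biological problem

Typical 2-Cys peroxiredoxins (Prx) are obligate dimers whose dimers stack
reversibly into ring-shaped decamers, and the decamer is roughly 100-fold
more active as a peroxidase than the free dimer.  Oxidation of a catalytic
site by H2O2 produces a sulfenic acid (SOH); condensation with the resolving
cysteine produces a disulphide bridge (SS) that locks the locally unfolded
conformation and destabilises the decamer, which then falls apart into
dimers.  A kinetic model of Prx activity that resolves this cycle needs
three ingredients, and `prxcycle` provides all three:

1. a tractable reaction network for the ten-site decamer
   (`enumerate_network()`),
2. rate constants for the five-dimer association/dissociation equilibrium,
   obtained by simulating and fitting isothermal titration calorimetry
   (ITC) dilution experiments (`simulate_itc()`, `fit_koff()`),
3. in-silico peroxidase assays that quantify what the dimer-decamer
   transition does to apparent activity (`simulate_hrp_assay()`,
   `simulate_nadph_assay()`).

## Symmetry reduction of the decamer network

A decamer has ten catalytic sites.  With three relevant site states
(SH, SOH, SS) a naive enumeration is astronomically redundant: physically
indistinguishable configurations are related by

* **mirror symmetry** -- the two sites of a dimer are equivalent,
* **rotational symmetry** -- the choice of "first" dimer in the ring is
  arbitrary,
* **planar symmetry** -- the ring can be viewed from either face, which
  reverses its orientation.

`prxcycle` implements the group generated by the 5 rotations, the ring
reversal and the five within-dimer swaps explicitly; it has order 320.  A
configuration's canonical form is the lexicographically smallest member of
its orbit under the site-state priority SH > SOH > SS.  Canonicalisation is
idempotent and constant on orbits, and the test suite verifies the species
counts against an independent brute-force partition of all raw site
assignments into orbits (no canonical forms involved), so the two code
paths check each other.

When several microscopic transitions of one canonical parent collapse onto
one canonical product, the reaction is emitted once with an integer
**statistical factor**: the first oxidation of the fully reduced decamer
has factor 10 (ten equivalent sites), the oxidation of a fully reduced
free dimer factor 2.

Two enumeration modes are provided:

* `"single_SS"`: decamer sites range over {SH, SOH}; exactly one bridge may
  form; a bridged decamer is insensitive to further oxidation and
  dissociates irreversibly into its five dimers in a single step.  This
  gives 129 canonical decamer configurations (39 bridge-free + 90 with one
  bridge) and 270 collated reactions (90 sulfenilation + 90 condensation +
  90 dissociation).
* `"multi_SS_one_per_dimer"`: up to one bridge per dimer unit (at most
  five); bridged species continue to oxidise, and every bridged species has
  its own single-step dissociation.  This gives 377 canonical decamers and
  1963 collated reactions.  Two bridges on one dimer unit are structurally
  excluded, as is any sulfinic (SOOH) site inside a decamer.

```{r enumerate}
net <- enumerate_network("single_SS")
net
network_counts(net)
```

**Species counting convention.**  The stand-alone single-bridge network
contains 136 species in total: 129 decamers, the five dimer species that
dissociation releases, and H2O2/H2O.  The default `"boundary_excluded"`
convention reported by `network_counts()` excludes the three boundary
species of this network -- the fully reduced decamer (supplied by the
association equilibrium of the host model) and the clamped H2O2/H2O pool --
giving the headline count of 133.  The alternatives (`"all"`,
`"decamers_only"`) are one keyword away; nothing in the kinetics depends on
the convention, it is purely a reporting choice.

## Mass-action kinetics and units

Units are fixed package-wide: concentrations in uM, time in s, volume in
uL, amounts in nmol.  The dimer-decamer transition is modelled as a single
mass-action step with five reactants,

$$v_{diss} = k_{off}\,[decamer], \qquad v_{ass} = k_{on}\,[dimer]^n,$$

with $n = 5$ mechanistically and $k_{on} = k_{off} / K_d^{app}$ tethered
through the apparent dissociation constant ($K_d^{app} = 1.1\ \mu M^4$ by
default).  The package also supports the phenomenological exponent
$n = 130$ description of the switch-like transition; $[dimer]^{130}$ is
evaluated in log space to avoid under/overflow.  Defaults
(`kinetic_parameters()`): $k_{off} = 0.055\ s^{-1}$ (the package's own ITC
estimate, see below), decamer sulfenilation
$k_{SOH}^{dec} = 100\ \mu M^{-1} s^{-1}$ with the dimer constant 100-fold
lower, condensation $1.7\ s^{-1}$, and a bridged-decamer dissociation
constant of $100\ s^{-1}$ -- not a measured quantity, only required to far
exceed every other rate in the system (it is configurable and logged into
every result).

Derived diagnostics, not inputs: the critical transition concentration
(~0.8 uM) and $C_{0.5} = 2\,(K_d/n)^{1/(n-1)}$, the total Prx (dimer
units) at which half the subunits are decameric:

```{r c05}
c_half(Kd_app = 1.1, n = 5)
equilibrium_distribution(2, Kd_app = 1.1)
```

ODE systems are compiled from networks and integrated with the stiff
`lsoda` solver (relative tolerance 1e-8, absolute 1e-12 uM).  Total Prx
subunits are conserved to better than 1e-6 relative along every
trajectory, which the test suite asserts.

## ITC dilution experiments

`simulate_itc()` mimics serial-injection dilution calorimetry: small
volumes of a concentrated (hence decameric) Prx stock are injected into a
large cell; each injection dilutes the decamers below their equilibrium
and the endothermic dissociation releases heat until, once the cell
concentration passes the critical transition, injected decamers no longer
dissociate.  Injections are instantaneous, perfectly mixed, and increase
the cell volume; the syringe holds the dimer/decamer equilibrium at the
syringe concentration.  Because the first injection of a real experiment
partially pre-reacts by syringe diffusion (and is discarded in analysis),
the simulated cell starts with one injection's worth of fully dissociated
dimers.

The chemical power is
$$P(t) = n\,(v_{ass} - v_{diss})\,V\,\Delta H$$
in ucal/s with $\Delta H$ in kcal per mol of dimer, so endothermic
dissociation is negative -- the conventional thermogram orientation.  The
instrument sees this through a first-order low-pass response
(`apply_instrument_response()`; the time constant defaults to 10 s, a
typical calorimeter response, since response times are rarely reported
alongside published thermograms; plus optional offset and linear drift).  Per-injection
heats are trapezoidal areas between injections, and the dissociation
enthalpy can be recovered as the maximum per-injection heat divided by the
moles of dimer delivered per injection.

```{r itc}
pro <- itc_protocol()           # 1.6 uL / 200 s / 51 uM / 1400 uL / 156 kcal/mol
trace <- simulate_itc(pro, kinetic_parameters())
heats <- injection_heats(trace)
round(heats$heat_ucal[c(1:3, 33:35)], 2)
estimate_enthalpy(heats, pro)
```

**The baseline artefact.**  When the injection period is too short for the
trace to return to baseline (slow dissociation, e.g. the exponent-130
parameterisation with $k_{off} = 0.005\ s^{-1}$ and 180 s intervals) and
the dissociation shuts off sharply at the transition, the piecewise-linear
baseline anchored in the final 10% of each inter-injection window tracks
the sagging signal; subtracting it manufactures a single apparent
exothermic peak at the transition that is present in the corrected trace
but absent from the raw one.  `baseline_correct()` reproduces this
mechanism, which explains the lone "association" peak seen in published
dilution thermograms as a correction artefact.

## Fitting the dissociation rate constant

`fit_koff()` estimates $k_{off}$ (optionally also the instrument time
constant) by Levenberg-Marquardt least squares (`minpack.lm`,
finite-difference step 1e-4, bounds at zero) on the measured-scale power
residuals, with $k_{on}$ tethered as $k_{off}/K_d^{app}$ throughout.  With
the default PRDX1 protocol, a noiseless self-consistency refit from a
10-fold displaced start recovers the generating $k_{off} = 0.055\ s^{-1}$
(and thus $k_{on} = 0.050\ \mu M^{-4} s^{-1}$) to well under 1%, and with
2% Gaussian noise the truth falls within two reported standard errors in
at least 90% of seeded replicates -- both asserted by the test suite.
`read_digitised_trace()` ingests external two-column time/power tables
(unit conversion, monotonicity validation, resampling to a uniform grid),
so digitised published thermograms can be fitted without manual steps.

## Peroxidase assays and the inhibition-like effect

Two model variants are compared throughout:

* **full-activity dimer-only**: dimer topology, but every site oxidises at
  the decamer rate constant -- the conventional modelling shortcut;
* **mixed dimer-decamer**: explicit association/dissociation, decamer-rate
  oxidation of decamers, 100-fold slower oxidation of free dimers.

In the HRP competition assay (`simulate_hrp_assay()`), HRP and Prx compete
for a 1 uM H2O2 pulse; compound I accumulation is read out as
$\Delta A_{398} = \epsilon_{398}\,\ell\,[CpdI]$ with
$\epsilon_{398} = 4.2 \times 10^4\ M^{-1} cm^{-1}$, $\ell = 1$ cm, and the
fractional-inhibition transform
$k_{Prx}[Prx] = k_{HRP}[HRP]\,(\delta_{max} - \delta_{obs})/\delta_{obs}$
turns end points into an apparent rate constant (through-origin and
free-intercept fits are both reported; the free fit's positive x-intercept
is the signature of the "inhibited-looking" dimer fraction).  The HRP rate
constant itself has no safe default and must be supplied;
`paper_repro_params()` ships literature-sourced values
($k_{HRP} = 17\ \mu M^{-1} s^{-1}$ and the PRDX2 constants listed in its
help page).  Known limitation, deliberately not "fixed": the
fractional-inhibition transform is exact only in the pseudo-first-order
regime and systematically mis-estimates rate constants that differ from
$k_{HRP}$; the test suite demonstrates exact recovery for an HRP-like
competitor under trace peroxide and the package leaves the published
analysis convention untouched otherwise.

The NADPH-linked assay (`simulate_nadph_assay()`) couples Prx disulphide
reduction to NADPH oxidation through thioredoxin and thioredoxin reductase
(50 uM Trx, 0.5 uM TRR, kcat 10 s^-1, 5 uM H2O2, 150 uM NADPH; the assay's
total Prx is not fixed by those conditions and defaults to 1 uM in dimer
units).  TRR turnover is modelled as saturating in the small-KM limit
(explicit Michaelis constants are available as parameters).  The
initial-rate window starts at the point of maximal NADPH consumption --
immediately after the brief lag while oxidised Trx accumulates -- and
extends while a linear fit keeps $R^2 \ge 0.999$ (minimum 5 points);
`initial_rate_kcat()` divides the slope by total Prx.

Across every configuration in the default grids the mixed model consumes
no more H2O2 than the full-activity model at every time point, and its
derived rate constants are correspondingly lower -- the inhibition-like
effect of sequestering reduced sites in low-activity dimers.  Three
mechanisms produce it: the equilibrium pins a CTC-scale dimer pool even at
rest; hetero-oxidised dimers (one SH site paired with an oxidised partner,
`hetero_oxidised_reduced_fraction()`) cannot join decamers; and under
H2O2 load the association reaction falls out of equilibrium
(`disequilibrium_ratio()` > 1) so reduced dimers accumulate.

## Dilution re-equilibration

`dilution_reequilibration()` computes the pre-dilution equilibrium,
divides by the dilution factor and simulates the relaxation.  "Time to
equilibrium" is operationalised as the first time from which the remaining
displacement -- the sup over species of $|x(t) - x(\infty)|$, normalised by
the initial displacement -- stays below 1%.  The normalisation matters: for
strong dilutions the final decamer concentration can be many orders of
magnitude below the working scale, and a criterion relative to the final
values would never terminate in any meaningful sense, whereas the
remaining-displacement criterion reproduces the experimental intuition
that a 1 uM solution relaxes in the same ~84 s after a 10x or a 50x
dilution (pure exponential decay at $k_{off}$) while concentrated
solutions take strictly longer at 50x.  These times matter in practice
only for millisecond-scale stopped-flow assays, where the
`dilution_factor_at_t0` option of the HRP assay shows higher apparent
activity for a freshly diluted (still decamer-rich) stock than for a
pre-equilibrated one.

## What the synthetic data emulate -- and what they do not

`make_synthetic_itc()` composes the chemical simulation, the instrument
response, seeded additive Gaussian noise (scaled to the peak power, 2% by
default) and optional linear drift, and writes two-column CSV traces plus
a JSON ground-truth sidecar that only tests may consume.  This emulates
the visual character of digitised published thermograms: multi-injection
endothermic traces, first-order smoothing, drift, and the sharp cessation
of heat at the transition.  It does **not** emulate pixel-quantisation or
axis-calibration errors of plot digitisation, correlated instrument noise,
syringe back-diffusion chemistry (only its first-injection consequence),
or thermal-diffusion instrument physics -- so passing recovery tests show
that the estimator is correct and well-calibrated under the stated noise
model, not that digitised literature data are free of systematic error.
Likewise the assay fixtures are deterministic model outputs in the exact
CSV dialects the analysis functions read.

## Numerical choices

* Stiff integration: `lsoda`, rtol 1e-8, atol 1e-12 uM.
* Equilibrium root: bracketed `uniroot` on the dimer concentration
  (monotone problem) plus Newton polishing; the defining relation holds to
  ~1e-12 relative.
* $[dimer]^n$ in log space; zero concentrations short-circuit to zero rate.
* Instrument filter: exact first-order-hold discretisation, so a constant
  input reproduces the textbook exponential step response to machine
  precision, and integrated heat is preserved up to the filter state left
  at the end of the trace.
* Trapezoidal per-injection heats (the power jumps at injections make the
  quadrature first-order at window boundaries; energy-bookkeeping checks
  therefore sample at 0.02 s).
* Degenerate inputs are errors with diagnoses, not silent NA: unknown site
  states, rings that are not 5 dimers, SOOH inside decamers, zero dimer
  pools in state fractions, zero decamer in the disequilibrium ratio,
  all-zero traces in fitting, missing `k_HRP`.

## Problem sizes used by the checks

The shipped checks run the single-bridge enumeration (6,144 raw
configurations reduced to 133-convention counts in under a second), the
extended enumeration (32,768 raw decamer configurations, ~2 s), ITC
simulations of 8-35 injections at 0.02-1 s sampling, 20-replicate noisy
refits of the default protocol, and assay grids over four Prx
concentrations with ~140-species ODE systems -- sizes chosen so the entire
suite completes in about a minute and a half on one core while still
crossing every regime the models distinguish (below/above the transition,
pre/post-CTC injections, lag/linear/exhausted assay phases).
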