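# prxcycle

Kinetic modelling of the peroxiredoxin (Prx) dimer–decamer cycle.

Typical 2-Cys peroxiredoxins stack reversibly from dimers into ring-shaped
decamers that are ~100-fold more peroxidatically active than the free
dimers. Oxidation of a catalytic site by H₂O₂ (SH → SOH), condensation to a
disulphide bridge (SOH → SS) and the bridge-driven dissociation of the
decamer couple the protein's quaternary structure to its activity.
`prxcycle` is for modellers and enzymologists who want to resolve this
cycle quantitatively: it builds the symmetry-reduced reaction network of
the ten-site decamer, estimates the association/dissociation kinetics from
isothermal titration calorimetry (ITC) dilution experiments, and simulates
the standard in-vitro peroxidase assays for model variants with and
without explicit decamerisation.

## The model in brief

* **Decamerisation** is a single mass-action step of five dimers:
  v_diss = k_off·[decamer], v_ass = k_on·[dimer]⁵, with k_on = k_off/K_d(app)
  and K_d(app) = 1.1 µM⁴ by default. A phenomenological exponent of 130 is
  also supported (evaluated in log space) for the switch-like description
  of the transition.
* **Decamer oxidation network**: decamer configurations are reduced by the
  symmetry group generated by the 5 ring rotations, the planar (ring
  reversal) reflection and the within-dimer mirror swaps (order 320);
  reactions are collated with integer statistical factors (the first
  oxidation of the fully reduced decamer has factor 10). With a single
  disulphide bridge triggering one-step dissociation, the network closes
  at 270 reactions over 129 canonical decamer configurations; the headline
  species count of 133 follows from the documented counting convention
  (boundary species — the fully reduced decamer and the clamped H₂O₂/H₂O
  pool — excluded; see `?network_counts`).
* **ITC**: serial injections of a concentrated, decameric stock into a
  buffer cell; chemical power P = n·(v_ass − v_diss)·V·ΔH (endothermic
  dissociation negative), first-order instrument response, per-injection
  heats, enthalpy recovery and Levenberg–Marquardt estimation of k_off
  with k_on tethered through K_d.
* **Assays**: HRP competition (compound-I absorbance at 398 nm and the
  fractional-inhibition transform) and NADPH-linked (Trx/TRR-coupled)
  assays, each for a *full-activity dimer-only* variant (dimer topology,
  decamer kinetics) and a *mixed dimer–decamer* variant (explicit
  association/dissociation, 100-fold slower dimers).

## Worked example

```r
library(prxcycle)

## 1. the symmetry-reduced decamer oxidation/dissociation network
net <- enumerate_network("single_SS")
net
#> <prx_network> 136 species, 270 reactions (mode: single_SS)
#>   reactions by kind: condensation=90, decamer_dissociation=90, sulfenilation=90
unlist(network_counts(net))     # documented counting convention
#>   species reactions
#>       133       270
export_sbml(net, kinetic_parameters(), "decamer_network.xml")

## 2. equilibrium diagnostics: half the subunits are decameric at C_0.5
c_half(Kd_app = 1.1, n = 5)
#> [1] 1.369732

## 3. simulate the PRDX1 ITC dilution protocol and refit k_off
pro <- itc_protocol()   # 1.6 uL per 200 s, 51 uM stock, 1400 uL cell, 156 kcal/mol
trace <- apply_instrument_response(simulate_itc(pro, kinetic_parameters()),
                                   instrument_model())
fit_koff(trace, pro, instrument_model(), Kd_app = 1.1, koff_init = 0.55)
#> <prx_fit>
#>   koff = 0.055 +/- 1.3e-14 s^-1
#>   kon  = 0.05 +/- 1.1e-14 uM^-4 s^-1 (tethered, kon = koff/Kd)
#>   converged: TRUE (9 iterations)

## 4. the inhibition-like effect of decamerisation on apparent activity
par <- paper_repro_params()          # literature-sourced assay constants
cfg <- hrp_assay_config()            # 5 uM HRP, 1 uM H2O2, Prx series
full  <- simulate_hrp_assay(cfg, par, "full_activity_dimer_only")
mixed <- simulate_hrp_assay(cfg, par, "mixed_dimer_decamer")
kf <- fractional_inhibition_k(full$delta_obs,  full$delta_max,  par$k_HRP, cfg$HRP_init)
km <- fractional_inhibition_k(mixed$delta_obs, mixed$delta_max, par$k_HRP, cfg$HRP_init)
c(full = kf$k_through_origin, mixed = km$k_through_origin)
#>      full     mixed
#> 175.87530  81.28540
```

Reading the output: the noiseless refit recovers the generating
dissociation constant exactly (0.055 s⁻¹, hence k_on = 0.050 µM⁻⁴s⁻¹ by
tethering) — the standard errors are those of a perfect-model fit and
shrink to numerical noise. In the assay comparison, partitioning the
reduced Prx pool into high-activity decamers and 100-fold-less-active
dimers roughly halves the apparent second-order rate constant extracted by
fractional inhibition (175.9 → 81.3 µM⁻¹s⁻¹ here): reduced sites
sequestered in dimers — a resting pool at the critical-transition scale,
hetero-oxidised dimers that cannot re-associate, and the association
reaction lagging behind dissociation under H₂O₂ load — behave like an
inhibited fraction of the enzyme.

See the vignette (`vignettes/prx-decamer-kinetics.Rmd`) for the model
assumptions, parameter meanings and numerical choices, including the
baseline-correction artefact that manufactures a lone exothermic peak at
the critical transition concentration and the dilution re-equilibration
analysis.

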