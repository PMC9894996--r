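# zfetk — PBPK toxicokinetics for zebrafish eleutheroembryos

`zfetk` predicts the *internal* exposure of zebrafish eleutheroembryos
(zfe, 0–120 hours post-fertilization) to waterborne chemicals. The zfe is
a workhorse of regulatory ecotoxicology (OECD FET test and relatives),
but assays dose the water, not the animal — and the animal is a moving
target: organs grow, the yolk is resorbed, the chorion shields uptake
until hatching, and the medium itself loses chemical to plastic and air.
`zfetk` is aimed at modellers and experimentalists who need tissue and
whole-body concentration—time profiles, want to calibrate
compound-specific parameters from sparse literature TK data, or want to
design exposure windows that hit a target internal dose.

## The model

A ten-compartment growing-organism PBPK ODE system (yolk, liver,
skeleton, gut, eye, brain, heart, skin, muscle, other) plus water,
device polymer, air and a metabolized sink. The core pieces, in standard
notation:

- **Ontogeny** — organ volumes
  `V_k(t) = V_embryo(120) · (exp(K_gk,T (t − τ_k,T)) − 1)` above the
  onset `τ_k,T`, zero below; growth rates scaled and onsets advanced by
  the Arrhenius factor `exp(T_A/T_R − T_A/T)`; exponential yolk
  resorption.
- **Uptake** — `F = φ_chorion` (constant, through the chorion) before
  48 hpf for chorionated embryos, `F = φ · V_embryo^(2/3)`
  (surface-area-scaled, transcutaneous) after hatching or when
  dechorionated.
- **Distribution** — per-tissue flux
  `dQ_i/dt = F · (V_i/V_embryo) · (s(C_w)·C_w − C_i/P_i:w)` with
  QSAR-derived partition coefficients rescaled by one factor `f_pc`,
  and optional uptake saturation `s = 1/(1 + C_w/Sat50)`.
- **Liver metabolism** — optional linear (`K_met`) or Michaelis–Menten
  (`V_max`, `K_M`) clearance per hepatocyte, into a terminal sink.
- **Medium** — dynamic losses to the device polymer and air, dosing
  events, daily renewals; closed-system mass balance holds to solver
  precision.
- **Statistics** — lognormal (geometric-SD) error model, uniform-prior
  Metropolis MCMC with split-R̂ diagnostics, AIC/BIC structure
  comparison at the maximum-posterior sample, Saltelli/Jansen Sobol
  sensitivity indices, and a literature-like synthetic TK data
  generator for end-to-end recovery testing.

Bisphenol presets (BPA, BPAF, BPF, BPS) ship with published
maximum-posterior values (e.g. BPA: `f_pc = 0.365`, `φ = 8.00 µL/h/mm²`,
`φ_chorion = 0.495 µL/h`, `σ = 2.76`). The physiology table, partition
priors and FET design constants are clearly-labelled synthetic
reconstructions (`inst/extdata/*_synthetic.json`); see the methods
vignette (`vignettes/zfetk-methods.Rmd`) for provenance and limitations.

## Worked example

Simulate the standard FET-style scenario — one embryo per 2 mL well,
1 µM BPA from 1 hpf for 144 h, daily medium renewal, 26 °C:

```r
library(zfetk)
sim <- simulate_zfe(fet_design(1000), compound_preset("BPA"))
print(sim)
#> zfe simulation: BPA | 1441 time points over 1 - 145 hpf
#>   final whole-body conc: 4.833 ng/mg ( 0.02117 nmol/uL )
tk_metrics(sim)
#> zfe TK metrics: Cmax 19.54 ng/mg at tmax 40.34 h post-dosing;
#> AUC 1608 ng/mg*h; final BCF 21.26
```

The embryo peaks at ~19.5 ng/mg about 40 h after dosing (shortly before
the chorion effect has fully faded), then the concentration *falls*
although no elimination is modelled — dilution by growth plus loss of
the lipid-rich yolk, the classic apparent-clearance signature of this
system. The final bioconcentration factor (~21) sits inside the wide
range reported for BPA in embryos.

Comparing the four bisphenols under identical exposure:

```r
run_covariates("analog_compare", dt = 0.5)
#>   compound Cmax_ng_mg tmax_h_postdose AUC_ng_mg_h AUC_rel
#> 1      BPA    19.5431           40.34     1608.43 1.00000
#> 2     BPAF    23.5844           35.34     1693.01 1.05259
#> 3      BPF    22.9206           54.84     2129.69 1.32408
#> 4      BPS     0.3981            3.62       21.95 0.01364
```

BPS internal exposure is ~1.4 % of the other analogs (its low
hydrophobicity gives it far smaller tissue:water partition
coefficients), matching its weak in-vivo potency ranking.

Other entry points: `simulate_zfe()` for arbitrary
`exposure_design()`s, `mcmc_sample()` / `posterior_summary()` /
`compare_structures()` for calibration, `sobol_pbpk()` for sensitivity,
`generate_dataset()` for synthetic TK data, and a CLI
(`inst/cli/zfetk`, or `zfetk_cli()`) with subcommands `simulate`,
`calibrate`, `compare-structures`, `sobol`, `covariates`,
`generate-data`.

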