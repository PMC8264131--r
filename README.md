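# dialysim

Bench-scale hemodialysis pharmacokinetics in R: simulate a closed-loop
dialysis circuit, estimate hemofilter drug clearance with the
hematocrit-corrected formula, and relate bench results to clinical
pharmacokinetics (in vitro/in vivo correlation, time scaling, membrane-area
extrapolation, plasma protein binding).

## Who this is for

Drug clearance during intermittent renal replacement therapy is hard to
predict: it depends on membrane material and area, blood and dialysate flow
rates, and drug–membrane interactions. Bench circuits that dialyze a small
(≈2 L) reservoir of bovine blood let pharmacologists profile a drug across
many membranes and flow settings without clinical trials. `dialysim` is for
the people running and analysing such experiments: it provides the
estimators they compute, a simulator that generates realistic run data so
every estimator is testable end to end, and the correlation layer that maps
bench clearances onto published clinical values.

## The model in brief

Drug in the reservoir is carried by plasma water only (filter transit is too
fast for red-cell equilibration), so with hematocrit Hc the effective flow
is `Qp = BFR·(1 − Hc)` and the effective volume `Vp = V_blood·(1 − Hc)`. A
membrane of diffusive clearance `CL_m` drives a mono-exponential decline
`C(t) = C0·exp(−CL_m·t/Vp)`, with `C_post = C_pre·(1 − CL_m/Qp)` and
`C_dial = CL_m·C_pre/DFR`. Clearance is estimated from paired pre/post
samples by

    CL = (1 − Hc) · [BFR·C_pre − C_post·(BFR − UFR)] / C_pre

Membranes can alternatively be specified by their mass-transfer–area
coefficient K0A, with clearance from the countercurrent dialyzer solution
`CL = Qp·(e^{N(1−R)} − 1)/(e^{N(1−R)} − R)`, `N = K0A/Qp`, `R = Qp/Qd`, so
that simulated clearance responds to flow settings the way real dialyzers
do. Saturable drug adsorption to the membrane (the teicoplanin case) is
available as a finite site pool with first-order uptake.

## Worked example

Simulate twelve replicate runs of gentamicin (10 mg/L start) on a
polysulfone membrane with 117 ml/min clearance, blood flow 300 ml/min,
dialysate flow 500 ml/min, hematocrit 0.35, 5 % assay noise, then estimate
the condition summary:

```r
library(dialysim)

m <- membrane_spec("F80s", "polysulfone", 1.8, "fixed_clearance",
                   cl_membrane = 117)
cond <- study_condition(m, dialysis_settings(),
                        drug_spec("gentamicin", 10), replicates = 12)
runs <- generate_study(list(cond), noise = noise_model(cv = 0.05, seed = 42))
estimate_study(runs)
#>   membrane       drug bfr_ml_min dfr_ml_min cl_ml_min cl_uncorrected_ml_min
#> 1     F80s gentamicin        300        500  116.1705              178.7238
#>   sd_ml_min  n n_excluded
#> 1    4.9747 96  0
```

The mean recovered clearance (116.2 ml/min) sits within noise of the
configured 117 ml/min; `n = 96` counts the retained per-timepoint estimates
(12 runs × 8 samples). A noncompartmental summary of one run gives the
elimination rate `k_el = CL/Vp`:

```r
pk_summary(runs[[1]])
#> $auc 104.4   $k_el 0.091   $half_life 7.62   $vd 1296
```

Correlating the packaged six published in vitro / in vivo clearance pairs:

```r
invitro <- read_clearance_csv(system.file("extdata", "table2_invitro.csv",
                                          package = "dialysim"))
invivo <- read_invivo_reference(system.file("extdata", "invivo_reference.csv",
                                            package = "dialysim"))
correlate_clearances(pair_clearances(invitro, invivo))
#> <ivivc_correlation> n = 6 (df 4), invitro_on_invivo
#>   slope 1.1276, intercept -5.56 ml/min
#>   Pearson r 0.98661, R^2 0.97339, adj R^2 0.96674, RSS 244.43
```

A Pearson r near 0.99 over membranes and drugs spanning 39–156 ml/min is
what makes the bench model usable as a stand-in for clinical clearance
measurements.

## Command line

A thin wrapper is installed at `exec/dialysim`:

```sh
dialysim simulate --config study.yaml --out runs.csv --seed 42
dialysim estimate --runs runs.csv --out clearance.csv
dialysim ivivc    --invitro clearance.csv --invivo reference.csv --out ivivc.json
dialysim bind     --samples binding.csv --out binding_out.csv
dialysim report   --study DIR --out report.json
```

An example study configuration (the six-condition gentamicin membrane/flow
grid) ships at `inst/extdata/gentamicin_grid.yaml`.

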