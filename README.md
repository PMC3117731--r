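# atorkin

Mechanistic modeling of atorvastatin biotransformation in primary human
hepatocytes, and of how inter-individual variability in CYP3A4 and UGT1A3
expression propagates into drug exposure.

Atorvastatin circulates as a hydroxy-acid (AS) and its lactone (ASL); in
the hepatocyte both are hydroxylated by CYP3A4 to para-/ortho-metabolites,
AS is lactonized by UGT1A3, lactones hydrolyze back chemically and via
paraoxonase, and everything is moved across the membrane by transporters
and passive diffusion while binding unspecifically to intracellular
macromolecules. `atorkin` implements this network as an 18-state stiff ODE
system (6 compounds × {medium, intracellular free, intracellular bound})
and layers on top of it everything a dynamic-modeling study needs:

* **Simulation** — full (mechanistic transport) and reduced
  (transport-lumped) model variants, compiled right-hand side, mass
  conservation to 1e-6 over 20 h, SBML Level 3 export/import.
* **Estimation** — weighted least-squares criterion
  `J = Σ ((c_calc − c_meas)/s)²` with floors on `s` and censoring-aware
  data handling, inequality constraints (`fu_acid > fu_lactone`,
  permeability orderings) via exterior penalty, a self-adaptive (µ+λ)
  evolutionary strategy (8+4) with log/logit search scales, multi-start
  and local polish; simultaneous multi-donor fits with maximal rates tied
  across donors by relative abundance.
* **Identifiability** — finite-difference sensitivities, Fisher
  information `F = SᵀWS`, Cramér–Rao relative errors and parameter
  correlations, and the iterative reduction loop that lumps unidentifiable
  active-transport/passive-diffusion pairs into apparent clearances
  `κ_im`, `κ_ex`.
* **Population** — relative-abundance scaling `r_max,li = r_max,ref ·
  c_li/c_ref`, virtual liver banks (log-normal, relative s.d. 259% for
  CYP3A4 and 137% for UGT1A3, n = 150), per-subject AUC / c_max / t(c_max)
  over 0–1200 min at a 50 pmol·ml⁻¹ dose, log-logistic distribution fits.
* **Synthetic data** — seed-deterministic triplicate time series on the
  experimental grid (0–600 min, 11 points) with proportional+additive
  noise and 0.5-pmol quantification censoring, donor protein tables, liver
  banks.

## Worked example

```r
library(atorkin)

# a 30 um hepatocyte, and the donor-2 lactone-channel rates predicted from
# donor-1 rates and the measured CYP3A4 protein ratio 611/1027
cell_volume_pl(30)                  # 14.1372 pL
round(scale_rmax(1228, 1027, 611))  # 731  pmol/min/ml
round(scale_rmax(2756, 1027, 611))  # 1640 pmol/min/ml

# donor-1 time-series experiment: 10 uM dose on 1.5e6 cells in 2 ml
p <- default_parameters(1)
g <- experiment_geometry()
sim <- simulate_model(p, g, t_grid = seq(0, 600, by = 5))
round(100 * tail(recovery_timecourse(sim), 1), 1)  # 84.2 (% recovered)
```

The recovery number is the measured-material balance: the unspecifically
bound intracellular pool is lost during sample preparation, which is why
total recovery decays from 100% even though the model conserves mass
exactly (checked to 1e-6).

The analysis workflow lives in `analysis/` as numbered drivers, each
writing its tables under `results/`:

```sh
Rscript analysis/01_simulate_donor1.R        # profiles, AUC ratios, recovery, SBML
Rscript analysis/02_fit_synthetic.R          # ES fit on noisy synthetic data
Rscript analysis/03_identifiability_reduction.R
Rscript analysis/04_population_variability.R
```

`04` prints, for a 150-liver virtual bank (CYP3A4 input spread 174% at this
sample size, UGT1A3 128%):

```
 definition metric sample_mean sample_rel_sd_pct
         AS    auc     61766.3              93.2
         AS   cmax       144.6              39.7
         AS t_cmax        57.7              46.8
   acid_sum    auc    189622.9              18.5
   acid_sum   cmax       275.1              10.1
   acid_sum t_cmax       161.5              33.7
```

i.e. the exposure of the summed active acids (AS+ASpOH+ASoOH) varies far
less across the population than the enzyme expression that drives it —
hydroxylation converts parent into active metabolites, so losses in one
active species reappear in another — while parent-drug AUC remains the
most variable metric.

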