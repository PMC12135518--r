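# teicopk

Population pharmacokinetics and dosing optimization of teicoplanin in
renal transplant recipients.

Early after kidney transplantation, patients commonly receive teicoplanin
for gram-positive (notably MRSA) infection or perioperative prophylaxis
while their renal function is severely impaired and still recovering.
Because teicoplanin is cleared renally, is highly protein bound and has a
long half-life, fixed dosing produces widely varying exposure in this
population. This package implements the full quantitative workflow a
pharmacometrician would use to address that problem:

* **Kinetics** — closed-form two-compartment intravenous-infusion model
  with superposition over arbitrary loading/maintenance schedules
  (`pk_params()`, `regimen()`, `conc_at()`, `trough_at()`, `auc_window()`),
  including exact handling of piecewise-constant (time-varying) covariates.
* **Population model** — typical values, a creatinine-clearance power law
  on clearance, log-normal inter-individual variability and log-scale
  residual error (`pop_model()`, `teicoplanin_model()`).
* **Estimation** — a first-order conditional (Laplace-at-mode) nonlinear
  mixed-effects engine written for this package (`pkfit()`, `foce_ofv()`),
  structural model comparison (`compare_structural()`), stepwise covariate
  modeling with the 3.84/6.63 OFV gates (`scm()`), and a subject-resampling
  bootstrap (`pk_bootstrap()`).
* **Diagnostics** — goodness-of-fit tables with CWRES (`gof_table()`),
  prediction-corrected visual predictive checks (`pc_vpc()`), and
  PE/MPE/RMSE validation metrics (`validation_metrics()`,
  `external_validation()`).
* **Dosing optimization** — Monte Carlo probability of target attainment
  by renal-function stratum against trough (>= 15 / >= 40 mg/L) and
  AUC24/MIC >= 610.4 targets, and lowest-dose regimen selection
  (`simulate_stratum()`, `pta_auc_mic()`, `select_regimen()`,
  `regimen_grid()`).
* **Synthetic cohorts** — a generator reproducing the study design (79
  subjects, sparse trough-anchored sampling, published covariate
  distributions) so everything is testable without clinical data
  (`generate_cohort()`, `cockcroft_gault()`, `crcl_trajectory()`).

The central model, written in the field's notation:

    CL (L/h) = 0.711 x (CrCL/17)^0.198 x e^eta1      omega_CL = 40.1%
    Vc (L)   = 11.3 x e^eta2                         omega_Vc = 37.3%
    CLd = 4.22 L/h,  Vp = 35.3 L                     proportional error 14.6%

with `ln Y = ln F + e1` residual error on the log-concentration scale.

## Worked example

```r
library(teicopk)

m <- teicoplanin_model()

# trough and daily exposure of the standard regimen for a typical patient
# with CrCL 8 mL/min
p <- individual_params(m, c(CRCL = 8))
r <- standard_regimen()          # 400 mg q12h x3, then 400 mg q24h
trough_at(p, r, 72)              # pre-dose trough at 72 h (mg/L)
auc_window(p, r, 72, 96) / 24    # average concentration over 72-96 h

# Monte Carlo PTA for a low-renal-function stratum
s <- simulate_stratum(m, regimen(400, 5, maintenance_dose = 200), "<10",
                      n = 1000, seed = 1)
s

# fit a synthetic cohort generated from the published model
cohort <- generate_cohort(seed = 1)
fit <- pkfit(cohort$data,
             covariate_effects = list(covariate_power("CL", "CRCL", 17, 0)))
fit
```

Output from this session:

```
> trough_at(p, r, 72)
[1] 16.16046
> auc_window(p, r, 72, 96) / 24
[1] 22.41125
> s
PTA, CrCL <10 mL/min, 400 mg q12h x 5, 200 mg q24h (n = 1000)
  Cmin72 >= 15: 89.8%   Cmin168 >= 15: 53.8%
  Cmin72 >= 40: 0.0%   Cmin168 >= 40: 0.2%
> fit
Population PK fit (FOCE), 2-compartment model
  79 subjects, 302 observations; OFV = -98.848; converged
  theta: CL=0.759, Vc=11.7, CLd=4.75, Vp=36.6
  CL ~ (CRCL/17)^0.305
  omega (%): CL=30.8, Vc=24.5
  proportional residual (%): 15.4
```

A typical patient with CrCL 8 mL/min on the standard regimen sits just
above the 15 mg/L trough target at 72 h (16.2 mg/L) with an average
concentration of 22.4 mg/L over the 72-96 h day. The simulated PTA values
sit within Monte Carlo error of the published table (91.8% and 56.7% for
this regimen and stratum), and the fit recovers the generating typical
values (0.711 L/h, 11.3 L) from one sparse 79-subject study within
sampling error.

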