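# adprogress

Monthly-grid forecasting of Alzheimer's disease progression from sparse,
irregular longitudinal clinical data.

Given a subject's past visits — clinical diagnosis (NC / MCI / AD dementia)
and up to 22 continuous markers (ADAS-Cog13, MMSE and other cognitive
scores, MRI volumes, PET and CSF measures) with most entries missing — the
package predicts the diagnosis probabilities, ADAS-Cog13 and ventricular
volume for **every month** into the future, for any horizon. It is aimed at
researchers modelling dementia progression on ADNI/TADPOLE-style cohorts,
and at anyone who needs a fully seeded, self-contained testbed for
longitudinal forecasting under heavy missingness.

## The model

The core is a minimal gated recurrent cell over a monthly grid. With input
$x_t = (s_t, g_t)$ (one-hot diagnosis, continuous markers):

```
u_t = tanh(W_u x_t + b_u)
f_t = sigmoid(U_h h_{t-1} + U_u u_t + b_f)
h_t = f_t * h_{t-1} + (1 - f_t) * u_t        (elementwise)
```

with a softmax head for next-month diagnosis probabilities and an affine
head for the 22 continuous markers. Training minimizes a masked multi-task
loss — cross-entropy on observed diagnoses plus mean absolute error on
observed continuous entries, equally weighted; missing entries contribute
nothing — with Adam and hand-written backpropagation through time (verified
against finite differences in the test suite). Forecasts are recursive:
each predicted vector is fed back as the next month's input.

Missing inputs are handled by three interchangeable strategies: **forward
filling** (last observation carried forward), **linear filling**
(interpolation, trailing gaps forward-filled), and the integrative **model
filling**, in which the model's own one-step-ahead predictions stand in for
missing inputs during both training and inference, with gradients flowing
through the filled values.

Alongside the gated RNN the package implements a linear state-space
baseline (`h_t = A h_{t-1} + B x_t + b`, the cell's exact linearization), a
constant-prediction baseline, and an SVM/SVR harness with separate models
per target, input-window length and 6-month horizon (3 x 4 x 10 = 120
models, interpolated to monthly predictions). Evaluation is TADPOLE-style:
multiclass AUC and balanced class accuracy for the diagnosis, MAE for
ADAS-Cog13 and for ventricles as a fraction of intracranial volume, with
group-wise (stable / progressive / reverting) and yearly-horizon
breakdowns, repeated 18:1:1 subject splits with disjoint test sets, and
corrected resampled t-tests with BH-FDR for model comparison.

Real ADNI/TADPOLE data are access-controlled, so a seeded synthetic-cohort
generator emulates their structure (visit schedules, marker marginals,
per-feature observation rates, NC -> MCI -> AD transitions with rare
reversions); every experiment in the package runs end-to-end on it. See the
vignette `vignettes/progression-forecasting.Rmd` for the full methods
account.

## Worked example

```r
library(adprogress)

sim <- simulate_cohort(sim_config(n_subjects = 120, seed = 7))
x <- sim$cohort
x
#> <ad_cohort> 120 subjects, 860 visits (mean 7.17/subject), 1-month grid

fit <- train_progression_model(
  x, strategy = "model",
  train_config(hidden = 32, epochs = 40, lr = 3e-3, batch_size = 32,
               seed = 1))
fit
#> <progression_model> minimalrnn (model filling), 1 layer(s) x 32 units;
#>   final training loss 2.892

s <- x$subjects[["S0007"]]   # a normal control, last seen at month 14
fc <- forecast(fit, s, horizon_months = 24)
round(fc[c(1, 12, 24), c("month", "p_NC", "p_MCI", "p_AD", "ADAS13")], 3)
#>    month  p_NC p_MCI  p_AD ADAS13
#> 1     15 0.945 0.053 0.002  8.614
#> 12    26 0.906 0.092 0.003  9.336
#> 24    38 0.379 0.616 0.005 10.147
```

The forecast rows are months after the subject's last visit: the model
keeps this subject a normal control over the first year but projects
conversion to MCI by month 38 (p_MCI 0.62), with ADAS-Cog13 slowly
worsening — the gradual NC -> MCI -> AD progression the generator builds
in.

Scoring a cohort uses the standard protocol (first half of each subject's
timepoints as input, second half as targets):

```r
fc_all <- forecast_cohort(fit, x)
ev <- evaluate_forecasts(fc_all, x)
round(unlist(ev[c("mauc", "bca", "adas_mae", "ventricles_mae")]), 4)
#>           mauc            bca       adas_mae ventricles_mae
#>         0.9627         0.8896         6.1662         0.0091
```

(mAUC/BCA near 1 mean the three diagnosis classes rank and classify
cleanly; the MAEs are in ADAS-Cog13 points and in ventricle/ICV ratio
units. These are in-sample numbers on synthetic data — for honest test
metrics use `run_benchmark()`, which holds subjects out.)

A thin command-line driver wraps the same functions:

```sh
Rscript inst/cli/adprogress.R simulate --n 500 --seed 1 --out cohort.csv
Rscript inst/cli/adprogress.R train --cohort cohort.csv --fill model \
    --hidden 128 --epochs 100 --seed 1 --out model.json
Rscript inst/cli/adprogress.R forecast --model model.json \
    --input cohort.csv --horizon 72 --out forecast.csv
```

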