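# acrisk

Personalized risk of acute cellular rejection (ACR) after lung
transplantation, from three early plasma/physiology time series: soluble
CD31 (sCD31, pg/ml), the PaO2/FiO2 oxygenation ratio, and the respiratory
SOFA score, each sampled at 24, 48 and 72 h post-transplant.

ACR strikes a large fraction of lung-transplant recipients in the first
year, has no specific clinical signature, and is confirmed only by
transbronchial biopsy. sCD31 — the shed ectodomain of the CD31 receptor,
released when endothelium, leukocytes or platelets are activated — is a
candidate early biomarker: event patients show *declining* post-operative
sCD31 trajectories while non-event patients' levels rise. `acrisk` turns
that observation into a tested, reusable analysis chain for cohorts of the
form (3 variables × 3 timepoints × n patients, binary outcome).

## What the package computes

**Multivariate dynamics.** The pooled series are modelled as a vector
autoregression

$$Y_t = a + W_1 Y_{t-1} + \dots + W_p Y_{t-p} + e_t,$$

with the lag order chosen by the Hannan–Quinn criterion. Around the VAR
sit the standard diagnostics: augmented Dickey–Fuller stationarity tests
(with per-patient differencing), a Johansen trace cointegration screen,
Granger-causality F-tests for every directed pair (does PaO2/FiO2 help
predict sCD31 beyond its own lags?), Durbin–Watson residual checks, and
held-out forecasting scored by RMSE / MAE / MAPE / correlation.

**Class separation.** Dependent multidimensional dynamic time warping —
one warping path shared by all dimensions, Euclidean frame cost,
path-length-normalized distance — measures how far apart the two outcome
classes' standardized (sCD31, PaO2/FiO2) profiles are.

**Classification.** A compact temporal convolutional network (1929
trainable parameters: linear spatial-filter dense 3→16, conv1d 16→32 and
32→2 with batch normalization and ReLU, dropout, global average pooling,
one sigmoid head) is trained by Adam on the class-weighted binary cross
entropy, with the head bias initialized at log(pos/neg) and stratified
k-fold cross-validation. Everything — backpropagation included — is plain
R, seed-deterministic.

**Risk.** Head pre-activations z (log-odds) become per-patient risk
scores: the probability e^z/(1+e^z), the cohort-referenced cumulative risk
percentage (empirical fraction of cohort z-values ≤ z, scaled to 0–100),
and the literal integrated-sigmoid value log((1+e^z)/2).

Because no individual-level clinical dataset is distributed, the package
includes a first-class synthetic cohort generator whose defaults emulate
the target setting: 40 recipients, 7 events (17.5%), H24 sCD31 median near
4240 pg/ml, opposite multiplicative class trends, and a lag-1 dependence
of sCD31 on oxygenation so Granger structure is recoverable.

## Worked example

```r
library(acrisk)

coh <- generate_cohort(generator_config(seed = 1))
coh
#> ACR cohort: 40 patients, 7 events (prevalence 17.5%)

panel <- pooled_panel(coh)          # 120 x 3 pooled series
dp <- difference(panel)             # differenced within patients

adf_test(dp$values[, "scd31"])
#> ADF test: tau = -9.7210, p = 9.544e-17 (lags 0, n 79)

select_lag_order(dp, 3)$order
#> [1] 1

granger_test(dp, "pf_ratio", "scd31", 1)
#> Granger test pf_ratio -> scd31 (m = 1): F = 0.0165, p = 0.898

class_separation(cohort_class_series(coh))$normalized_distance
#> [1] 1.486214

parameter_count(network_spec())
#> [1] 1929
```

Reading the numbers: after one within-patient difference the pooled sCD31
series is clearly stationary (the ADF tau of −9.7 is far beyond any
critical value); HQIC picks a lag-1 VAR for this 120-tag panel; at the
default generator coupling (`granger_coef = 0.15`, noise 0.08) the
embedded oxygenation→sCD31 influence is too weak to surface at n = 40
(p = 0.898) — with the strong-coupling setting used in the test suite
(`granger_coef = 0.8`, low noise, n = 200) the test rejects in ≥ 18 of 20
seeds; and the opposite class trends put the normalized DTW distance
between class representatives near 1.5.

The full chain — diagnostics, forecast, DTW, cross-validated training,
risk table — runs from one configuration:

```r
dir <- tempfile()
run_pipeline(run_config(seed = 1), dir)
writeLines(pipeline_report(dir))
```

which writes `cohort.csv`, `diagnostics.json`, `forecast.csv`, `dtw.json`,
`eval_report.json`, `history.csv`, `parameter_manifest.json`,
`risk_table.csv` and `run_log.txt`, each stamped with the configuration
hash.

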