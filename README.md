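# bpgadose

Individualised warfarin dosing after heart valve replacement is hard:
the drug's therapeutic window is narrow, between-patient maintenance doses
vary up to twenty-fold, and the mapping from routine clinical covariates to
the eventual stable dose (mg/d) is nonlinear. `bpgadose` implements a
hybrid prediction model for this problem — a three-layer back-propagation
(BP) neural network whose initial weights and thresholds are searched by a
real-coded genetic algorithm (GA) — together with the variable-selection
and validation machinery around it, and a seeded synthetic multi-centre
cohort generator so the whole pipeline runs reproducibly without access to
registry data. It is aimed at biostatisticians and clinical-modelling
researchers studying dose-prediction algorithms.

## The model

For selected covariates $x \in [0,1]^m$ (min–max scaled) the network is

$$\hat y = W_{ho}\tanh(W_{ih}x + b_h) + b_o,$$

trained by full-batch gradient descent on the MSE (learning rate 0.1,
≤ 1000 epochs, error goal 0.001 on the normalized dose). The hidden size is
searched over $h = \mathrm{round}(\sqrt{m+n}) + \alpha$, $\alpha = 1..10$,
by holdout MAE. The GA encodes all weights/thresholds as one real vector in
$[-1,1]^{L}$ and maximises

$$F = \Big(\sum_i |\hat y_i - y_i| + \varepsilon\Big)^{-1}$$

with roulette selection $p_i = f_i / \sum_j f_j$, single-point tail-swap
crossover (rate 0.95), single-gene mutation (rate 0.09) and elitism
(population 50, 100 generations). The best chromosome initialises BP
training. Variables enter the model through an ANCOVA screen (Type I
sequential SS; keep partial $\eta^2 \ge 0.001$ and $p < 0.05$) after a 50%
data-integrity filter, with height and weight always enrolled. Validation
reports MAE, RMSE and the *ideal percentage* — predictions within 20% of
the actual dose — overall and in low (< 2.5), intermediate ([2.5, 3.0]) and
high (> 3.0 mg/d) dose subgroups, on an internal (random 3:1) and an
external (centres with < 200 cases) hold-out.

## Worked example

```r
library(bpgadose)

cfg <- pipeline_config(cohort = cohort_config(n_patients = 3000),
                       hidden = "search", seed = 42)
res <- run_pipeline(cfg, out_dir = "demo-out")
print(res$internal)
```

The run logs each stage to standard error and prints:

```
[bpgadose] simulated cohort: 3000 rows, 8 centres
[bpgadose] selected 11 variables: age, ef, lvdd, operation_history, albumin,
           creatinine, aptt_preop, first_anticoagulant_day, warfarin_origin, height, weight
[bpgadose] split: train 2060 / internal 686 / external 254
[bpgadose] hidden-size search chose h = 12 (candidate MAEs 4:0.148 5:0.130 ... 13:0.126)
[bpgadose] GA best fitness 0.0040; BP stopped after 1000 epochs (max_epochs)
[bpgadose] internal: MAE 0.132 RMSE 0.167 ideal 99.6%
[bpgadose] external: MAE 0.129 RMSE 0.169 ideal 99.6%

Accuracy report (n = 686)
  MAE  0.132 mg/d
  RMSE 0.167 mg/d
  total          Under     0 (  0.0)  Ideal   683 ( 99.6)  Over     3 (  0.4)
  low            Under     0 (  0.0)  Ideal    91 ( 96.8)  Over     3 (  3.2)
  intermediate   Under     0 (  0.0)  Ideal   530 (100.0)  Over     0 (  0.0)
  high           Under     0 (  0.0)  Ideal    62 (100.0)  Over     0 (  0.0)
```

Reading this: on 3000 simulated patients the screen kept 11 of the 12
candidate covariates (urea nitrogen missed significance at this seed, and
height/weight are mandatory), the small centres (254 cases) formed the
external group, and the trained network predicted 99.6% of internal-
validation doses within the 20% clinical band with a mean absolute error of
0.132 mg/d. Errors are small because the synthetic generator's dose spread
(SD ≈ 0.21 mg/d) is concentrated; see the vignette for what the generator
does and does not emulate. `demo-out/` receives the cohort CSV, selection
and scaler JSON, model JSON, GA trajectory CSV, both accuracy reports, the
internal-vs-external comparison and a seed-stamped manifest; rerunning the
same config reproduces every file byte for byte.

A thin CLI wrapping the same functions is in
`inst/cli/bpgadose-cli.R` (`simulate`, `select`, `split`, `train`,
`evaluate`, `compare`, `run`).

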