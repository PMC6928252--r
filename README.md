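# nplsnest

Tri-linear partial least squares regression (N-PLS) with **nested
resampling** quality control for in vivo study designs.

## The problem

Fully crossed condition × time studies in animals produce replicated,
multivariate, time-resolved data in which every time point is a terminal
endpoint: one animal contributes one condition × time cell, and all of its
measurements — histology and mechanics, signaling and phenotype — are
nested within that animal. Multidimensional PLSR models of such data are
conventionally fit to replicate-averaged arrays, so the (often large)
animal-to-animal variance never reaches the model. Latent variables that
"statistically improve" the global-average model may then encode nothing
more than the particular animals used.

`nplsnest` classifies latent variables as **robust** or **fragile** by
refitting the model under resampling schemes that respect the animal
nesting hierarchy:

* **jackknife** (leave-one-replicate-out): omit one whole animal per
  condition × time cell, re-average, refit — a weak test; what dies here
  is severely underpowered;
* **subsample** (leave-one-replicate-in): keep exactly one animal per cell
  ("n-of-one" data), refit — a conservative test; what survives reflects
  a large, reproducible effect size;
* **randomization null models**: shuffle within each condition, refit,
  flag weights beyond one null SD.

Resampling can be **paired** (the same animal selected in the independent
and dependent blocks) or unpaired, and always moves whole animals: a
replicate's observations are removed or retained as a group.

## The model

`X` (conditions × times × variables) and `Y` (likewise) share the
condition mode. Each latent variable is extracted from the mode-1 unfolded
residuals by alternating projections

    w = Xᵀu,  t = Xw,  q = Yᵀt,  u = Yq

(unit-norm `w`, `q`; `u` initialized to PC1 of the `Y` residual), iterated
until the change of ‖t‖ ≤ 1e-10. The inner coefficient
`b = (tᵀt)⁻¹ tᵀu` links the blocks; `X` is deflated by `t wᵀ`, `Y` by
`b t qᵀ`; prediction is `Ŷ = Σₙ bₙ tₙ qₙᵀ`. Combined weights are
factorized post hoc into time × variable parts (leading singular vectors,
factorization residual reported). Model order is selected by
leave-one-condition-out cross-validated RMSE; ensemble members are fit at
the global optimum, sign-aligned to the global model, and summarized as
mean ± SD per weight — **robust** means the interval strictly excludes
zero.

## Worked example

A synthetic study shaped like an intestinal inflammation design (2 tissue
regions × 2 doses, 12 signaling inputs, 2 phenotype outputs, 6 time
points, N = 5 animals per cell), with 2 planted latent variables and
in-vivo-scale replicate noise:

```r
library(nplsnest)

pm  <- study_fixture("intestine", n_lvs_true = 2, replicate_noise_sd = 0.4, seed = 101)
gen <- generate_planted(pm)
tensors <- average_replicates(gen$dataset)

cv <- loo_crossvalidate(tensors, spec_modes23(), max_lvs = 3, seed = 1)
cv
#> <cv_result>
#>   RMSE (standardized): LV1=1.08 LV2=1.002 LV3=0.9914
#>   optimal LVs: 3 | Pearson R = 0.480 | Spearman rho = 0.519

std   <- standardize_tensors(tensors, spec_modes23())
model <- npls_fit(std$tensors, n_lvs = cv$optimal_n_lvs, seed = 2)

null <- build_null(tensors, spec_modes23(), n_lvs = cv$optimal_n_lvs,
                   n_iter = 100, seed = 3, reference = model)
mask <- classify_significant(model, null)

ens <- run_ensemble(gen$dataset,
                    resampling_scheme("subsample", n_iter = 100, seed = 4,
                                      n_lvs = cv$optimal_n_lvs),
                    spec_modes23(), reference = model, cv = FALSE)
subset(summarize_robustness(ens, mask = mask)$lv_summary, axis == "combined")
#>    block lv     axis robust_fraction n_significant n_retained retained_fraction
#> 1      X  1 combined       0.4166667            30         22         0.7333333
#> 4      X  2 combined       0.1527778            24         11         0.4583333
#> 7      X  3 combined       0.0000000            26          0         0.0000000
#> 10     Y  1 combined       0.5833333             3          3         1.0000000
#> 13     Y  2 combined       0.3333333             3          3         1.0000000
#> 16     Y  3 combined       0.0000000             1          0         0.0000000
```

Reading: cross-validation picks 3 LVs for the global-average model, and
the randomization null declares coordinates on all three significant
(`n_significant`). But subsampling — refitting on one random animal per
cell, 100 times — shows LV3's weights never hold up (`robust_fraction` 0,
`retained_fraction` 0): the third component fits the replicate
configuration, not the biology. LV1 survives in both blocks. Interpret
LV1, be cautious with LV2, and do not mine LV3.

Real data enter the same pipeline from long-format CSV (one row per
observation: `condition, time, time_unit, variable, block, replicate_id,
pairing_id, value`) via `read_long_csv()`; studies publishing only
mean/SD tables can be simulated with
`simulate_replicates_from_summary()`.

## Command line

Every stage is also a subcommand driven by a JSON config
(see `?read_config`):

```sh
Rscript -e 'nplsnest::npls_main()' simulate --config run.json
Rscript -e 'nplsnest::npls_main()' fit      --config run.json
Rscript -e 'nplsnest::npls_main()' null     --config run.json
Rscript -e 'nplsnest::npls_main()' resample --config run.json --seed 7
```

Outputs (model JSON, CV and ensemble CSVs, draw logs) land in the
config's `output_dir`, each with a manifest entry (command, config hash,
seed) for exact reruns.

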