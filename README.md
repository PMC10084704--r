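# metayield

Few-shot prediction of chemical reaction yields for **unseen reagents**,
combining a random forest with a small meta-learned "attention" head and a
principled procedure for choosing which few reactions to measure.

## Who this is for

High-throughput experimentation (HTE) teams and computational chemists who
have a screened reaction space (e.g. a Pd-catalysed coupling: aryl halide x
ligand x base x additive, descriptor-encoded) and want to predict yields for
a reagent that was never screened, after measuring only ~5 reactions with
it. Held-out-reagent prediction is an out-of-distribution problem on which
plain tree ensembles deteriorate; this package implements the few-shot
middle ground.

## The model

Reactions are encoded by concatenating per-component descriptor vectors,
one block per role:

    x_i = x_arylhalide (+) x_catalyst (+) x_additive (+) x_base

A regression forest `F = {h_1, ..., h_M}` is fitted on the training
reagents and frozen. Each reaction is re-represented by its tree-output
vector `x'_i = (h_1(x_i), ..., h_M(x_i))`, and a small feed-forward head
`f_theta` (M -> 40 -> 40 -> 1, ReLU) maps `x'` to a yield — the head *is*
the attention over trees; its uniform special case is the classic
random-forest prediction. The head's initialization is meta-learned (MAML)
over reagent-defined tasks: for task `T_i` (support/query split of one
additive's reactions),

    min_theta  sum_i  L_Ti( f_{theta - alpha * grad L_Ti(f_theta)} )

with mean-squared task loss, optimized by Adam, differentiating through the
inner step exactly. For a new reagent, one gradient step on its few
measured reactions gives `theta_fewshot`:

    theta_fewshot = theta_meta - alpha * grad L_support(theta_meta)

The support reactions themselves are chosen by t-SNE embedding of the
reagent's candidate reactions followed by Kennard-Stone maximin selection,
so the measured handful covers the reagent's reaction space homogeneously.

A synthetic HTE generator with known ground truth (group shifts, structural
families, bounded noisy yields) makes the whole pipeline testable offline,
and an evaluation harness provides the leave-reagent-out benchmark, an
enlarged-training-set forest baseline, ablations, top-k high-yield
selection and permutation-and-retrain feature importance.

## Worked example

```r
library(metayield)

gd <- gen_dataset(synth_config(seed = 1))      # 3960-reaction synthetic screen
ds <- gd$dataset
sp <- split_by_group(ds, n_train = 4, n_val = 1, seed = 3,
                     train_fraction = 0.1375)  # 2.5%-of-data training regime

bm <- run_fewshot_benchmark(ds, sp, "metarf",      n_finetune = 5,
                            seeds = 1:5, clip = TRUE)
bl <- run_fewshot_benchmark(ds, sp, "rf_baseline", n_finetune = 5,
                            seeds = 1:5, clip = TRUE, sampling_reps = 3)
bm
#> benchmark_result: metarf (n_finetune = 5, 5 seeds)
#>   R2 = 0.6340  RMSE = 14.5707  MAE = 11.1047
#>   top-k true-yield mean = 99.2 (ideal 100.0, random 42.3)
bl
#> benchmark_result: rf_baseline (n_finetune = 5, 5 seeds)
#>   R2 = 0.6184  RMSE = 14.8094  MAE = 11.5277
#>   top-k true-yield mean = 99.5 (ideal 100.0, random 42.3)
```

Read: pooled over all 17 test additives' unmeasured reactions, the
meta-learned model explains R² = 0.63 of the yield variance (RMSE 14.6
percentage points), against 0.62 (RMSE 14.8) for a random forest whose
training set was enlarged by the same number of randomly chosen fine-tune
reactions. One adaptation step is what carries the model: before
fine-tuning, its pooled RMSE is 21.8–24.2 per seed
(`bm$summary$rmse_pre`). The top-10 line says the 10 reactions predicted
best truly average 99.2% yield (oracle ranking: 100%, random picks: 42%).

Propose which reactions to measure for one new additive:

```r
plan <- select_fewshot(ds, group_value = sp$test_groups[1], n = 5,
                       embed_config(seed = 1))
plan
#> selection_plan for group 'additive_11': 5 of 180 candidates
#>   order: 1910, 1942, 1855, 1857, 1967
write_selection_plan(plan, "plan.csv")
```

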