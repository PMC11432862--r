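# edrva

Outcome-aware clustering and risk prediction for 72-hour emergency
department (ED) return-visit admissions (RVA).

An RVA is a treat-and-release ED visit followed within 72 hours by a return
visit that ends in hospital admission — a rare (~0.8% of discharges),
high-stakes outcome. `edrva` is an R implementation of a two-step prediction
pipeline for this problem, aimed at quantitative researchers working on
clinical risk models for rare outcomes on tabular EHR-style data:

1. **DICE (deep significance clustering)** — joint optimization of an
   autoencoder $f_\theta$, latent k-means centroids $c_1,\dots,c_K$ and a
   logistic outcome head on softmin cluster memberships
   $m_{ik} \propto \exp(-\lVert f_\theta(x_i)-c_k\rVert^2/\tau)$, minimizing

   $$L = \tfrac{\alpha}{n}\textstyle\sum_i\lVert x_i-\hat x_i\rVert^2
        + \tfrac{\beta}{n}\sum_i\lVert z_i-c_{a(i)}\rVert^2
        + \gamma\,\mathrm{CE}(p, y),$$

   accepted only if every adjacent pair of risk-ordered clusters differs
   significantly in outcome rate by a Wald test (`alpha_sig = 0.05`). The
   number of clusters is chosen by a deterministic search maximizing
   validation AUC of a membership-based classifier.
2. **Step-2 classifiers** — L1 logistic regression / gradient-boosted trees
   on the membership probabilities plus up to 20 variables chosen by greedy
   forward feature search (FFS) maximizing validation AUC; operating points
   from Youden's J ($\max$ sensitivity + specificity − 1) on validation
   scores; metric panel of AUC (stratified bootstrap CI), sensitivity,
   specificity and positive likelihood ratio
   $\mathrm{PLR}=\mathrm{sens}/(1-\mathrm{spec})$, subgroup AUCs,
   discharge-variable ablation, additive feature attributions, and a
   5-variable clinical risk-score baseline.

Real RVA cohorts are protected EHR extracts, so the package ships a
synthetic ED-visit generator (`generate_cohort()`) with planted risk-tiered
cluster structure, monthly seasonality, realistic demographics, lab
missingness and a 0.8%-prevalence outcome; every stage of the pipeline is
exercised and tested end-to-end on it. See the methods vignette
(`vignettes/methods.Rmd`) for the model, the generator's design and its
limits.

## Worked example

```r
library(edrva)

spec  <- cohort_spec(20000, seed = 1)          # 0.8% RVA, 2 tiers, RR 4.5
tab   <- generate_cohort(spec)
split <- monthly_split(list(month = tab$month, y = tab$outcome), seed = 2)
fm    <- build_matrix(tab, split$train_idx)    # train-row statistics only

dice  <- fit_dice(fm, split, dice_config(seed = 3), k = 2)
print(dice)
#> dice_model: K = 2, latent dim 8, significant (min Wald p = 1.72e-11)
#>   training cluster outcome rates: 0.0029, 0.0133

asg <- assign_clusters(dice, fm, split$test_idx)
round(asg$risk_ratio, 2)
#> [1] 15.46

mem <- assign_clusters(dice, fm, seq_len(nrow(fm$X)))$membership
clf <- fit_classifier(
  classifier_spec("l1_logistic", use_dice = TRUE, use_ffs = TRUE, seed = 4),
  fm, split, memberships = mem)
rep <- evaluate_model(clf, fm, split$test_idx, memberships = mem, seed = 5)
print(rep)
#> eval_report (n = 1996, 16 positives)
#>   AUC 0.769 (95% CI 0.680-0.849)
#>   sensitivity 0.375, specificity 0.821, PLR 2.097
```

Reading the output: on the training rows the two DICE tiers differ in
outcome rate by a factor of ~4.5 (0.0133 / 0.0029, the planted ratio), with
an overwhelmingly significant Wald test; the DICE + LR + FFS classifier
separates held-out RVA from non-RVA visits with AUC ≈ 0.77 against a
generative-model ceiling of ≈ 0.8. The *test-set* risk ratio (15.5 here) is
an extremely noisy statistic — a 10% split of 20000 visits holds only ~16
positives — which is why the automated checks measure the ratio on the full
cohort instead; expect every test-set quantity above to move visibly with
the seed.

`run_experiment()` wires the whole grid (nine model presets mirroring the
DICE/FFS/baseline combinations) from one master seed:

```r
ex <- run_experiment(experiment_config(cohort = spec, master_seed = 1))
ex$results   # model, AUC + CI, sensitivity, specificity, PLR
```

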