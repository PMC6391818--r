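# metadann

Meta-prediction of miRNA:mRNA interactions from the numeric scores of
four established target predictors — miRanda, miRDB, PITA and
TargetScan.

## The problem

Individual miRNA target predictors disagree: each one misses validated
interactions the others find, and each scores on its own axis (miRanda
alignment energies, miRDB confidence percentages, PITA ΔΔG values,
TargetScan context+ scores). Worse, for a given miRNA:gene pair any
subset of the four tools may simply produce no score at all. `metadann`
is for computational biologists who have whole-genome score dumps from
these tools plus a list of validated interactions (e.g. a
miRTarBase/TarBase export) and want a single calibrated call per pair.

## The model

Scores are first made comparable: each predictor's raw score is mapped
by the affine min–max transform from its native range onto (−1, 1), with
miRDB negated first so that on the common axis every predictor scores
predicted interactions *low*. The published default cutoffs land at
−0.424, −0.2, 0.028 and 0.920 for miRanda, miRDB, PITA and TargetScan.

Records are then routed by score availability into eleven subsets — D4
(all four tools scored), D3-1…D3-4 (three tools), D2-1…D2-6 (two tools);
pairs with fewer than two scores are not classified. One module is
trained per subset. Each module stacks two classifiers:

1. **A dual-threshold, two-step significance-voting decision tree.**
   Every predictor *p* carries four cutoffs
   `t_true_1(p) ≤ t_true_2(p) < t_false_2(p) ≤ t_false_1(p)`.
   At step 1 the stringent cutoffs vote (score < `t_true_1` is a "true"
   vote, score > `t_false_1` a "false" vote; in between, abstention) and
   a strict majority decides. Ties go to step 2 with the relaxed
   cutoffs. A second tie is resolved by significance voting: the side
   with the larger aggregate distance of its scores beyond the relaxed
   cutoffs, `d_T2 = √Σ max(0, t_true_2 − s)²` versus
   `d_F2 = √Σ max(0, s − t_false_2)²`, wins. The cutoffs themselves are
   tuned coordinate-wise over spike candidates of the information-gain
   curve IG(x) = H(labels) − Σ_j f_j(x) H(labels | side j of x).
2. **A small neural network** on the encoded feature vector — the n
   scaled scores plus the six tree quantities
   (N_T1, N_F1, N_T2, N_F2, d_T2, d_F2), i.e. 10/9/8 inputs for
   4/3/2-predictor modules — with hidden layers of 10 and 20 tanh
   nodes and a 2-node tanh output that is exponentially normalized to a
   (p_interaction, p_no_interaction) pair.

The tree alone ("C-I") and a network on the bare scores ("C-II") are
available as reference variants.

## Worked example

Everything below runs offline: the packaged generator emulates
whole-genome score dumps (native ranges, class imbalance, predictor
complementarity, realistic missingness).

```r
library(metadann)

round(scaled_default_cutoffs(), 3)
#>    miranda      mirdb       pita targetscan
#>     -0.424     -0.200      0.028      0.920

sim <- simulate_interactions(sim_config(n_samples = 2000, seed = 42))
fit <- metadann(sim$truth, variant = "dann", epochs = 200, seed = 1)
fit
#> meta-predictor (variant dann) with 7 availability module(s): D4, D3-1, D3-2, D3-3, D3-4, D2-1, D2-2
summary(fit)
#>   module n_train n_test cv_acc cv_acc_sd cv_sens cv_spec cv_f1 cv_mcc test_acc
#> 1     D4     784    196  0.945     0.017   0.683   0.967 0.642  0.619    0.939
#> 2   D3-1     305     77  0.984     0.006   0.833   0.993 0.852  0.851    0.909
#> 3   D3-2      82     21  1.000     0.000   1.000   1.000 1.000  1.000    0.952
#> 4   D3-3     189     47  0.952     0.016   0.733   0.971 0.695  0.706    0.957
#> 5   D3-4     100     26  0.950     0.018   0.500   0.978 0.444  0.460    0.962
#> 6   D2-1      36      9  0.944     0.049      NA   0.970 0.333  0.333       NA
#> 7   D2-2      41     11  0.976     0.041   0.667   1.000 0.667  0.667    0.909

head(predict(fit, sim$scores), 3)
#>      label     score module
#> 1 negative 0.1193659   D3-2
#> 2 negative 0.1194014   D2-2
#> 3 negative 0.2089580     D4
```

Each `summary()` row is one availability module: its training/held-out
sizes, cross-validated sensitivity/specificity/accuracy/F1/MCC (mean
over stratified 3- or 5-fold CV, s.d. for accuracy) and the accuracy on
the module's 20% independent test split. `predict()` scales raw scores,
routes each pair to its module and returns the call, the network's
interaction probability and the serving module; pairs whose availability
pattern had too little training data are returned as `NA` (the `NA`
sensitivity above is a CV fold of the tiny D2-1 subset that contained no
positives). At this cohort size only seven of the eleven patterns have
enough records to train — with a larger simulated cohort (or real score
dumps) all eleven come up.

A command-line front end wrapping the same functions ships in
`inst/cli/metadann.R` (subcommands `simulate`, `prepare`, `train`,
`predict`, `evaluate`, `ig`).

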