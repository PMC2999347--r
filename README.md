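# sirnaforest

Random-forest feature selection and support-vector classification of
siRNA potency from the 19-nt antisense guide sequence.

## The problem

Synthetic short interfering RNAs (siRNAs) silence a target gene through
the RNAi pathway, but different siRNAs against the same transcript can
differ widely in how much target mRNA they leave behind. Given a 19-nt
antisense sequence (5'→3', excluding the 3' two-nucleotide overhang) and
the measured remaining relative mRNA level in [0, 1], an siRNA is
**potent** (positive) when the remaining level is ≤ 0.5 and non-potent
(negative) otherwise. `sirnaforest` is a toolkit for learning and
evaluating sequence-based predictors of that label, aimed at people
designing siRNA libraries or studying which sequence properties drive
silencing efficacy.

## The method

1. **Encoding.** Each sequence becomes 120 features in six groups:
   19 positional nucleotide codes (A = 0.1, U = 0.2, G = 0.3, C = 0.4),
   4 mononucleotide, 16 dinucleotide and 64 trinucleotide frequencies
   (overlapping windows, each group a probability vector), overall G/C
   content plus 15 local G/C contents in sliding windows of five
   nucleotides, and the minimum free energy (MFE) of the predicted
   secondary structure via a pluggable folding backend.
2. **Feature selection.** Ten random forests (1000 trees each) are grown
   with per-node feature-sampling sizes
   m ∈ {2, 3, 5, 7, 9, 11, 13, 15, 17, 20}. Each forest ranks features by
   the z-score of out-of-bag permutation importance: for tree *t* and
   feature *j*, the raw score is the number of correct classifications on
   *t*'s out-of-bag instances minus the number after permuting column *j*
   within those instances; the forest's raw score is the per-tree mean,
   and z = raw / (sd/√B). Features ranked in the top 20 by at least 5 of
   the 10 forests are selected.
3. **Classification.** A soft-margin SVM with the RBF kernel
   K(x, y) = exp(−γ‖x−y‖²) (defaults γ = 1.2, C = 1.2) is trained on the
   selected features.
4. **Evaluation.** Stratified fivefold cross-validation; the held-out
   decision values of all folds are pooled and summarized as accuracy,
   sensitivity, specificity, MCC, a threshold-sweep ROC curve with
   trapezoidal AUC, and the Pearson correlation of the SVM output with
   the inhibition level (1 − remaining mRNA).

Because the siRNA compilations such methods are trained on are typically
not redistributable, the package ships a seeded synthetic-data generator
that plants motif effects (by default UCC potency-increasing, GAG
potency-decreasing) in a linear level model with Gaussian noise, so the
whole protocol can be exercised and tested end to end.

## Worked example

```r
library(sirnaforest)

sim <- simulate_sirna(generator_config(n = 400, seed = 20))
dataset_counts(sim$dataset)
#> n_positive n_negative
#>        205        195

res <- run_all(sim$dataset, seed = 20, B = 200)
head(res$selection$report, 8)
#>   feature n_forests mean_raw_score mean_z_score correlation
#> 1    GAG%        10      4.1770000    11.838893  -0.5728415
#> 2    UCC%        10      3.0915000    10.417374   0.5459551
#> 3     GA%         9      0.5455556     2.998665  -0.3571204
#> 4     UC%         9      0.4072222     2.683056   0.2354416
#> 5      C%         6      0.3708333     2.592213   0.2553553
#> 6    CCA%         6      0.1650000     2.564670   0.1977539
#> 7      G%         5      0.3310000     2.544152  -0.2678483
#> 8    CUC%         6      0.2941667     2.496785   0.1686413

res$evaluation
#> 5-fold CV (pooled): accuracy 65.00%, sensitivity 63.90%, specificity 66.15%
#> MCC 0.3005, AUC 0.7363, score-efficacy r 0.5794
```

The report reads like the usual importance table: both planted motifs are
recovered by all ten forests with the largest z-scores, their correlation
with efficacy carries the planted signs, and the cross-validated SVM on
the selected features separates potent from non-potent siRNAs well above
chance while its continuous output tracks the knockdown level.

A thin command-line wrapper over the same functions is installed at
`inst/cli/sirnaforest.R` with subcommands `simulate`, `extract`,
`select`, `train`, `evaluate` and `run-all`.

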