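# protclass

Binary classification of protein sequences from compositional and
evolutionary features.

Some protein families — cyclin-dependent kinase inhibitors are the motivating
example — are so heterogeneous in sequence that similarity search and domain
signatures miss a substantial fraction of known members. An alternative is to
learn a discriminative model over alignment-free features of the sequence
itself. `protclass` provides that workflow end to end for any two-class
problem: feature encodings, classifier training, leave-one-out evaluation with
decision-threshold scanning, and the standard performance metrics, all behind
tidyverse-style functions that take and return tibbles.

## What it computes

**Encodings.** Five fixed-dimension sequence encodings:

| Encoding | Dim | Definition |
|---|---|---|
| `AAC` | 20 | amino-acid composition: fraction of each residue, `count(a)/N` |
| `SAAC` | 60 | split AAC: the composition of three contiguous thirds, concatenated |
| `DPC` | 400 | dipeptide composition: adjacent ordered pair counts over `N − 1` |
| `GAP1` | 400 | one-gap dipeptides: ordered pairs `(p, p + 2)` over `N − 2` |
| `PSSM400` | 400 | evolutionary composition from a PSI-BLAST PSSM (below) |

For `PSSM400`, each per-position log-odds score *x* of the profile is first
normalized with the logistic function *g(x) = 1 / (1 + e^(−x))*, then for
every query-residue type *a* and substitution column *b* the normalized
scores are summed over the positions holding *a* and divided by the sequence
length *N*, giving a 20 × 20 composition-like matrix flattened to 400
dimensions.

**Classifiers.** Two families behind one contract — a continuous decision
score thresholded by `label = (score ≥ Th)`:

- a soft-margin SVM with the RBF kernel `K(u,v) = exp(−γ‖u−v‖²)`
  (`svm_config(C, gamma)`; backend: e1071's C-SVC, raw decision values);
- a one-hidden-layer feed-forward network trained by vanilla online
  backpropagation against 1/0 targets, with per-layer linear/logistic
  activations, learning rate 0.1 by default, and the returned weights taken
  from the training cycle with minimal sum of squared errors
  (`ann_config(hidden_units, activations, learning_rate, max_cycles, seed)`).

**Evaluation.** `loocv()` holds each sequence out exactly once, collects the
held-out scores, sweeps thresholds from −1.0 to 1.0 in steps of 0.1, and
reports per-threshold sensitivity `100·TP/(TP+FN)`, specificity
`100·TN/(TN+FP)`, accuracy, Matthews correlation coefficient and positive
predictive value `TP/(TP+FP)`, the accuracy-maximizing row (ties broken by
the smallest SN–SP gap), and the ROC curve with trapezoidal AUC on the
held-out scores.

**Synthetic data.** `simulate_sequences()` generates a labeled two-class
dataset whose classes differ only in residue composition (the positive class
up-weights K, R, E, P by a factor `1 + effect`), and
`simulate_profiles()` builds matched synthetic PSSM profiles, so the whole
pipeline — including the PSSM parser — is testable without any database
search.

## Worked example

```r
library(protclass)

data <- simulate_sequences(n_pos = 56, n_neg = 300, effect = 0.9, seed = 1)
cv <- loocv(data, "AAC", svm_config(C = 1))
cv
#> <protclass_cv> SVM on AAC, n = 356 (LOO)
#>   best threshold -0.40: ACC 96.35%, SN 87.50%, SP 98.00%, MCC 0.86, PPV 0.89
#>   held-out ROC AUC 0.9772
```

356 models were fitted, each on 355 sequences; every sequence was scored by
the model that never saw it. At the selected threshold of −0.40 the classifier
recovers 87.5% of the 56 positives (sensitivity) while rejecting 98% of the
300 negatives (specificity), for 96.35% accuracy overall; the MCC of 0.86
summarizes the fourfold table on a −1…1 scale, and the AUC of 0.977 is the
threshold-independent ranking quality of the held-out scores. Note the
negative best threshold: with a 56/300 class imbalance the decision scores
sit on the majority-class side, so the operating point that balances
sensitivity against specificity lies below zero.

`tidy(cv)` returns the full 21-row threshold table, `glance(cv)` the one-row
summary, `autoplot(cv)` / `autoplot(cv$roc)` the threshold scan and ROC
curve. Real data enter through `read_labeled_fasta()` (training sets) or
`read_fasta()` plus `read_psiblast_pssm()` (per-sequence ASCII profiles from
`psiblast -num_iterations 3 -evalue 0.001 -out_ascii_pssm ...`).

A command-line interface wraps the same functions
(`inst/exec/protclass`, installed under `exec/`):

```sh
protclass simulate --pos-out pos.fasta --neg-out neg.fasta --effect 0.9 --seed 1
protclass crossval --pos pos.fasta --neg neg.fasta --encoding AAC --out-prefix run1
protclass train    --pos pos.fasta --neg neg.fasta --model-out model.rds
protclass predict  --model model.rds --fasta query.fasta --threshold -0.4 --out calls.tsv
```

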