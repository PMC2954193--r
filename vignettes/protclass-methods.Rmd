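---
title: "Methods: encodings, classifiers and evaluation in protclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: encodings, classifiers and evaluation in protclass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protclass)
```

`protclass` builds binary protein-sequence classifiers from alignment-free
features. This vignette records the model and its assumptions, the numerical
conventions the package freezes, and the reasoning behind the design choices
that were genuinely open.

## The problem and the model

Given a positive and a negative set of protein sequences, the package encodes
each sequence as a fixed-dimension numeric vector, trains a scoring
classifier, and evaluates it by leave-one-out cross-validation (LOO CV) with
a scan over decision thresholds. The underlying assumption is that class
membership is reflected in sequence-intrinsic statistics — residue
composition, local residue order, or the evolutionary substitution profile —
rather than in detectable homology, which is exactly the regime where
similarity search fails for heterogeneous families such as CDK inhibitors.

## Encodings and their conventions

All encoders require sequences over the canonical 20-letter alphabet;
`sanitize_residues()` enforces this first. Residues are ordered
alphabetically (A, C, D, …, Y) and ordered pairs are indexed
`20·idx(a) + idx(b)`. Any fixed order would do; this one is frozen so that
feature columns, sparse-format indices and trained models are stable across
sessions.

* **AAC** (20-d): residue counts over `N`. Sums to 1.
* **SAAC** (60-d): AAC of three contiguous parts, concatenated. When `N` is
  not divisible by 3 the parts have lengths `floor(N/3)`, `floor(N/3)`,
  `N − 2·floor(N/3)`: "three equal parts" underdetermines the split, and a
  deterministic rule is required for reproducibility. The remainder goes to
  the C-terminal part, keeping the first two parts identical in length.
* **DPC** (400-d): adjacent ordered pairs divided by `N − 1`, the number of
  adjacent pairs actually present. This keeps the vector on the simplex,
  which we prefer over dividing by the constant 400 because it makes vectors
  from different-length sequences directly comparable.
* **GAP1** (400-d): ordered pairs with one intervening residue, divided by
  `N − 2` valid pairs, by the same logic; `gapped_dpc(s, gap = 0)` reduces
  exactly to DPC, which the tests exploit.
* **PSSM400** (400-d): see below.

No scaling is applied beyond these definitions: compositional fractions
already lie in `[0, 1]`.

## The PSSM-400 encoding

Profiles are consumed as PSI-BLAST ASCII matrices (the `-out_ascii_pssm`
layout). Only the first block — the 20 integer log-odds columns — is used.
The second (weighted-percentage) block is ignored deliberately: the logistic
normalization `g(x) = 1/(1 + e^{−x})` is centred at 0 and symmetric in ±x,
which is meaningful for signed log-odds but not for percentages. The parser
remaps the file's column order (A R N D C Q E G H I L K M F P S T W Y V)
onto the package's alphabetical order and rejects scores outside |x| ≤ 20 as
a corruption guard.

After normalization, the `N × 20` matrix is pooled into 400 dimensions: for
query-residue type `a` and column `b`, the normalized scores over all
positions holding `a` are summed and divided by `N`. The pooling statistic is
a genuine free choice — sum, per-residue mean, and length-normalized sum all
produce a 20 × 20 layout. We default to the length-normalized sum because it
makes proteins of different lengths comparable (mirroring the
"composition" framing of the other encodings) while still weighting a
residue type by its abundance, which the per-residue mean would discard. The
alternatives remain available via `pssm400(..., aggregate =)` but are not
the default anywhere.

Running the profile search itself is out of scope: profiles arrive as files.
For the canonical search the flags are three iterations at E-value 0.001
against a large protein database. `synthesize_profile()` provides a
deterministic stand-in (self-score on the query residue's column, off-score
elsewhere, optional integer Gaussian noise, clamped to the parser's band) so
the parser, normalizer and pooling can be tested in isolation.

## Classifiers

Both families implement one contract: a continuous decision score, then
`label = (score ≥ threshold)`, with equality counting as positive.

**SVM.** C-classification with the RBF kernel via e1071/libsvm; the
optimizer is standard machinery, not this package's contribution. Decision
values are used raw — no probability calibration — so they behave like
margin distances. Three conventions worth recording:

* *Score orientation.* The backend orients decision values toward whichever
  class it encounters first in the training rows; `protclass` re-orients
  them so that positive scores always mean the positive class, making
  held-out scores invariant to dataset row order.
* *Internal standardization.* The backend's default per-feature
  standardization is kept (constant columns excluded). Composition fractions
  have magnitudes around 1/20–1/400, so without it the squared distances are
  ≈ 0 and the RBF kernel with the conventional `gamma = 1/dimension` default
  degenerates toward a constant matrix, collapsing all decision scores into
  a narrow band. Standardization is part of the classifier, not the
  encoding; the feature vectors themselves are untouched.
* *`C = 0`.* Published parameter tables sometimes list `C = 0`, which is
  degenerate for soft-margin training. It is interpreted as "backend default
  cost" (1), and both the requested and the effective value are echoed in
  the training summary.

Default `C = 1`, `gamma = 1/dimension`. No class weighting is applied by
default even for imbalanced sets (56 vs 300 is the reference design); the
threshold scan compensates at evaluation time, which is why selected
thresholds on imbalanced data are typically negative.

**ANN.** A fully-connected net with one hidden layer, trained by vanilla
online backpropagation with 1/0 targets. Activations are configurable per
layer (linear or logistic; the input activation is applied elementwise to
the features, so classic topologies like linear–logistic–logistic or
all-logistic are expressible). Learning rate defaults to 0.1. The SSE over
the training set is recorded after every cycle, and the model returned is
the weight snapshot at the cycle of minimal SSE — "train to `max_cycles`,
keep the best" — rather than a patience-based stop, because it is exactly
reproducible and captures the intent of terminating where SSE is least.
Weight initialization is uniform in (−0.5, 0.5) from an explicit seed;
within LOO CV the seed is offset by the fold index so the entire CV is one
deterministic function of (data, config).

The implementation is in-package rather than delegated: available R fitters
optimize by quasi-Newton methods and do not expose the per-cycle SSE trace
and minimal-SSE snapshot this contract requires. It is adequate for the
small, shallow topologies it targets and makes no claim to efficiency at
scale.

## Evaluation protocol

LOO CV trains `n` models on `n − 1` sequences. Encodings are computed once
per sequence before splitting: every encoding is a function of one sequence
(and its own profile), so nothing about the held-out sequence leaks into the
training folds. The held-out scores are then swept over thresholds −1.0 to
1.0 in steps of 0.1 (21 points). Metrics are kept at full precision;
two-decimal display is presentation only.

Degenerate fourfold tables are flagged instead of producing NaN: MCC with a
zero denominator is reported as 0 with `mcc_degenerate = TRUE` (an
all-one-class prediction carries no correlation information), and PPV with
`TP + FP = 0` is `NA` with `ppv_undefined = TRUE`.

`select_best()` maximizes accuracy, breaking ties by the smaller |SN − SP|
and then by the lower threshold. The first tie-break encodes the usual
preference for balanced operating points; the second is an arbitrary but
frozen determinism rule.

The ROC curve is computed on the held-out LOO scores, not on training
scores — training scores of a well-fitted SVM are optimistically separated
and would inflate AUC. One step per distinct score handles ties; trapezoidal
AUC then equals the Mann–Whitney U statistic over `n_pos · n_neg`, an
identity the tests assert, alongside a cross-check against an independent
ROC implementation. One caveat of held-out scoring: on null data (classes
exchangeable) LOO AUC is slightly pessimistic — holding out a positive tilts
the training set toward the negatives, so held-out positives score
systematically a little lower — which shifts the null AUC a few hundredths
below 0.5 on top of ordinary sampling noise. Both the full threshold table
and the selected row are
always reported, so any dependence of the selected threshold on the same
scores being summarized is visible to the user rather than hidden.

## The synthetic generator

`simulate_sequences()` emulates the statistical structure of a curated
two-class training set: a small positive class (default 56) against a larger
background class (default 300), the reference study design. Sequences are
i.i.d. residue draws — the negative class from a SwissProt-like background
composition, the positive class from the same composition with the fixed
subset {K, R, E, P} up-weighted by `(1 + effect)` and renormalized. The
signal is compositional rather than motif-based because every supported
encoding is composition-family, so a single planted effect exercises all of
them; the up-weighted subset is arbitrary but frozen for test stability.
Lengths are uniform on 50–250 residues, a typical range for the small
regulatory proteins of the motivating family. `effect = 0` gives exactly
exchangeable classes (the null control); `effect = 0.9` gives strongly but
not perfectly separated classes. Matched synthetic profiles reuse each
sequence's residues, so the same signal flows through the PSSM-400 pipeline.

What the generator does **not** emulate: real CDKI biology (ankyrin repeats,
intrinsic disorder, shared domains between the classes), phylogenetic
correlation between sequences, length–class confounding, or real PSI-BLAST
profiles built from alignments. Passing tests therefore demonstrate that the
pipeline recovers a planted compositional signal under clean conditions —
they do not certify accuracy on real data, and the headline accuracies of
any published study depend on its deposited sequence sets and database-era
profiles, which this package does not bundle.

## Problem sizes and numerical tolerances

The test suite runs the full 356-sequence LOO designs for the AAC pipeline
and property checks at 75–120 sequences elsewhere; encoder oracle
equivalence uses 1000 random sequences and 100 synthetic profiles. Simplex
checks use an absolute tolerance of 1e−9; SVM score comparisons across
row-permuted datasets use 1e−2, reflecting the optimizer's termination
tolerance rather than the package's arithmetic. Worked metric examples are
checked to 0.01 absolute, the precision of two-decimal truncated reference
values.

## Known limitations

* LOO CV refits `n` models; with the in-package backprop ANN this is
  practical only for small `n` or few cycles. The SVM path handles the
  reference design in seconds.
* Decision-score scales differ across SVM implementations, so a threshold
  tuned on one backend's scores (e.g. a published −0.6) does not transfer
  bit-for-bit to another; re-scan on your own scores.
* The CLI accepts thresholds outside [−1, 1] with a warning rather than an
  error, since other backends' scores may legitimately exceed that band.
* No k-fold CV variants, no kernels beyond RBF, no class-weighting defaults,
  no confidence intervals on metrics: point estimates mirror the reference
  protocol.
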