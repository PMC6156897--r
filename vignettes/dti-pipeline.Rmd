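---
title: "Methods: transcriptome-based drug–target interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome-based drug-target interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`dtiscope` treats drug–target interaction (DTI) discovery as binary
classification on fused expression signatures. The underlying biological
assumption is signature sharing: a drug that engages a target perturbs the
same downstream program that knocking the target gene down perturbs, so the
drug's perturbation profile and the gene's knockdown profile carry
correlated information. The classifier's input is the serial concatenation
of one drug profile and one gene profile over a common set of landmark
features — nothing is transformed or dropped, so at the full L1000 scale two
978-feature Z-score profiles give a 1956-feature sample.

Labels form a trichotomy driven by a gold-standard edge list. A (drug, gene)
pair is **positive** when the edge is recorded. If the gene is a known
target of *some* drug but this edge is absent, the pair is **unlabeled** —
the edge may simply be unrecorded, and these pairs form the prediction
universe. Only pairs whose gene targets nothing at all are treated as
**negative**. Because the negative space dwarfs the positives, negatives
are subsampled to a 1:2 positive:negative ratio, deterministically at
uniform intervals over the canonically ordered space (gene-major, then
drug, then credible-row indices, all lexicographic). We read "uniform
intervals" as systematic sampling rather than uniform random draws: it is
reproducible bit for bit and spreads the selection evenly across the gene
space. The selection count is `round(ratio × n_pos)` with half-away-from-zero
rounding, fixed explicitly because platform-dependent rounding would break
reproducibility at half-integers.

### Replicate aggregation: the credible set

Perturbation entities are measured in replicate trials of very uneven
quality. For each entity we compute the trial-by-trial Pearson correlation
matrix, partition the trials by k-means (Euclidean distance on the raw
Z-score vectors, 10 restarts, seeded), and keep two representatives:

* **S1** — the centroid of the cluster with the highest mean pairwise
  Pearson correlation among its members,
* **S2** — the grand mean of all trials, retained so that no information is
  discarded outright.

The number of clusters follows the trial count: no clustering for n ≤ 2,
k = 2 for 2 < n ≤ 5, k = 3 for 5 < n ≤ 15, k = 4 above. The boundary counts
(5, 15) go to the smaller k, and n ≤ 2 skips clustering entirely; this makes
the rule closed and monotone. Three conventions matter in edge cases:

* A singleton cluster's internal correlation is defined as 1.0 (there is
  nothing to disagree with), but singletons are **not eligible** to be S1
  while any multi-member cluster exists. A vacuous 1.0 is the maximum
  possible score, so an eligible singleton — typically an isolated outlier
  trial — would otherwise *always* win, and the selection would routinely
  crown a failed experiment as the entity's representative. Requiring at
  least two members means S1 always reflects observed replicate agreement.
* Ties in the cluster score go to the lowest cluster label, making the
  choice deterministic.
* If S1 and S2 agree within 1e−9 per element (single trial, or all trials
  identical), the credible set keeps a single S1 row.

When replicated trials are exactly identical, k-means cannot place more
centers than distinct points; the effective k is capped at the number of
distinct trials, and if that leaves fewer than two clusters the entity
falls back to the grand mean.

Labels live on entity pairs; every credible-row combination of a pair
inherits the pair's label, and cross-validation folds are split at the
*pair* level so that two representatives of the same pair can never appear
on both sides of a train/validation boundary.

### The classifier and its objective

The network is fully connected: input 2n, hidden layers of 200 and 10 units
at full scale (32 and 8 in the reduced configuration used throughout the
tests), ReLU activations, and a 2-way softmax computed with max subtraction
for overflow safety. Training minimizes

$$J(\theta, b) = \frac{1}{m}\left[\sum_{i=1}^{m} -y_i \ln p_{i,1}
  - (1-y_i)\ln(1-p_{i,1}) \;-\; \eta \sum_{i \in \text{neg}} p_{i,0}\right]$$

where $p_{i,1}$ is the predicted positive-class probability and the second
term — subtracted, with weight η — rewards confident negative-class
probability on the true negatives. The objective is deliberately
non-standard: it can go negative, and its minimum is not a calibrated
probability model. Its purpose is geometric, pushing the decision boundary
toward the positive cluster so that unlabeled pairs are called positive
only with strong evidence. The observable consequence, which the test suite
verifies as a trend over seeds, is that the mean positive-class probability
assigned to true negatives does not increase as η grows over {0, 10, 100};
at η = 0 the objective reduces exactly to plain cross-entropy. The
practical consequence on validation folds is precision near 1 at reduced
recall, and a much smaller fraction of the unlabeled universe called
positive (PoPC).

One hazard deserves note: because the penalty is subtracted, the *most
negative* achievable loss belongs to the degenerate classifier that calls
everything negative. Early stopping that checkpoints on best validation
loss can therefore lock in collapse at high η. The trainer supports
patience-based early stopping on validation loss (default patience 20
epochs) but the end-to-end runs in this package disable it
(`patience = Inf`) and train a fixed number of epochs; monitor the recorded
`val_accuracy` history rather than `val_loss` if you enable it.

Training details: He-scaled random initialization (standard for ReLU;
seeded), minibatch Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e−8), inverted dropout
applied to hidden activations only — not the input or output layer — so that
inference-time forward passes need no rescaling. Probabilities are clipped
to [1e−7, 1 − 1e−7] inside logarithms and logits; the analytic backprop
gradient (which ignores the clip, exact whenever the clip is inactive) is
checked against central differences at 1e−4 relative tolerance in the
standing test suite. All randomness — initialization, shuffling, dropout
masks — flows from one seed, so a fixed seed and data reproduce identical
weights on one thread.

### Scoring, ranking, evaluation

Predictions for the unlabeled universe are ranked by the **D-score**, the
logit of the positive-class probability, $\ln(p/(1-p))$ — the (monotone)
distance from the softmax decision boundary. Probabilities are clipped with
ε = 1e−7 first so the score is finite at saturated predictions; its zero
coincides with the 0.5 decision threshold used for accuracy, F-score and
PoPC, so a pair ranks above zero exactly when it is called positive.
Because saturated predictions tie at the clip value, ties are broken by
(drug, gene) lexicographic order — arbitrary but deterministic. When a pair
has multiple credible-row combinations, the class probabilities of its
fused variants are averaged so the ranking has one row per pair.

Two comparison statistics round out the evaluation. The per-sample
predictive error between a comparator model and the reference network is
the difference in probability assigned to the sample's *true* class;
negative values mean the comparator is worse. Ranked lists are compared to
reference interaction sets (any two-column edge list) by overlap counts in
sliding windows of 500 consecutive predictions (step 1 by default; step =
bin width gives disjoint bins whose counts sum to the prefix overlap). An
enrichment of overlaps at the top of the ranking is the discovery-relevant
signal.

## The synthetic panel generator

No desk-scale artifact can reproduce results computed on the real
L1000 + DrugBank corpus, so the generator exists to make every stage of the
pipeline testable offline with known ground truth. Its generative model:
each gene receives a latent unit-norm signature over the landmark features;
a gene's knockdown mean is the negated signature scaled by
`signal_strength`; a drug's mean is the scaled sum of its target genes'
signatures; trials add i.i.d. Gaussian noise (`trial_noise_sd`); and with
probability `outlier_fraction` a trial is replaced by pure noise with no
planted mean. Outlier trials are drawn at the marginal scale of a real
trial (per-feature variance `signal²/n + noise²`), because a failed
experiment still produces full-magnitude Z-scores; low-amplitude outliers
would be both unrealistic and, since Pearson correlation is
scale-invariant, nearly harmless to the grand mean — which would make
outlier-robustness of the aggregation untestable.

Default conditions: 150 drugs, 150 genes, 1–3 targets per drug (≈300
planted edges), 1–25 trials per entity (a span that exercises every branch
of the k rule), signal strength 2, trial noise 0.5, 10% outliers. The
entity counts mirror a DrugBank-scale gold standard — hundreds of drugs and
targets at roughly two targets per drug — at about one third scale, and were
sized so the labelled pool (~2000 fused samples) is large enough for the
reduced network to generalize rather than memorize; panels much below ~100
edges leave the classifier data-starved. The features are left as
unstandardized Gaussians: per-feature Z-scoring would not change any
pipeline stage's correctness and is omitted.

What the generator does **not** emulate: cell-line and dose/time
covariates, the correlation structure among landmark genes, inference of
non-landmark genes, heavy-tailed noise, and drug promiscuity patterns
beyond the uniform 1–3 targets. Consequently, passing the end-to-end tests
shows that the pipeline's machinery — aggregation, labelling, the penalized
objective, ranking — recovers planted structure under honest noise; it does
not certify accuracy figures on real L1000 data.

## Problem sizes and numerical choices in the test suite

The standing suite runs panels of 16–64 features and up to 150 entities;
the end-to-end recovery test uses the default panel at 32 landmark
features, a [64, 32, 8, 2] network, η = 10, dropout 0.5, learning rate
1e−3 (the larger rate suits the small network; the full-scale default
remains 1e−4), batch 64, 300 epochs, and asserts held-out validation
accuracy above 0.85 plus top-versus-bottom decile enrichment of the
sliding-overlap curve against held-out edges. The aggregation
oracle is exhaustive: for every seeded trial set the selected cluster is
recomputed by brute-force scoring of the produced partition. Outlier
robustness is asserted at signal strength 8 ("high" signal: replicate
agreement well above noise), 30% outliers, where S1 must track the true
entity mean at least as well as S2 for ≥80% of entities. Loss values are
checked against an independent scalar re-implementation at 1e−10, forward
passes against hand arithmetic at 1e−12, and every seeded stage must
reproduce byte-identical output across two runs.

## Known limitations

* The 918-DTI / 3826-positive arithmetic of the reference gold standard is
  not reconstructible from the stated credible-set rule; the package makes
  no attempt to match those counts, and the 3826 → 7652 check exercises the
  sampler's arithmetic only.
* The penalized objective is not a likelihood; reported probabilities are
  not calibrated, and D-scores saturate at ±ln((1−ε)/ε) ≈ ±16.1 for
  confident predictions, where ranking falls back to the deterministic
  tie-break.
* On small panels the classifier leans on entity-identity shortcuts (which
  genes are targets at all) in addition to signature matching; enrichment
  of held-out edges at the very top of the ranking is correspondingly
  weaker than mid-ranking enrichment.
* Single-threaded determinism is guaranteed; multi-threaded BLAS builds may
  reorder floating-point reductions.
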