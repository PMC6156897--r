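# dtiscope

Drug–target interaction (DTI) prediction from perturbation transcriptomes.

Transcriptome-wide perturbation screens such as LINCS L1000 measure how a
cell line responds both to small-molecule treatment and to gene knockdown,
as Z-score profiles over 978 directly measured *landmark genes*. If a drug
inhibits a target, its expression signature should resemble the signature of
knocking that gene down — so a classifier trained on fused (drug, gene)
expression pairs can learn to recognize true interactions and propose new
ones. `dtiscope` implements that pipeline end to end, for people working on
computational drug repositioning and target deconvolution:

1. **Replicate aggregation.** Perturbation entities are measured in 1–25
   replicate trials of varying quality. For each entity the trials are
   clustered by k-means (k chosen from the trial count: k = 2 for 2 < n ≤ 5,
   3 for 5 < n ≤ 15, 4 above 15) and the cluster with the highest mean
   intra-cluster Pearson correlation provides a representative profile S1;
   the grand mean of all trials is kept as a second representative S2. The
   credible set {S1, S2} replaces the raw replicates.
2. **Sample fusion and labelling.** Each classification sample is the serial
   concatenation of a drug profile and a gene profile (978 + 978 = 1956
   features). Given a gold-standard edge list, a (drug, gene) pair is
   *positive* if the edge is recorded, *unlabeled* if the gene is a known
   target of some other drug, and *negative* if the gene targets nothing.
   Negatives are drawn deterministically at uniform intervals from the
   canonically ordered negative space at a 1:2 positive:negative ratio.
3. **Classifier.** A feed-forward network (1956–200–10–2 at full scale;
   ReLU, 50% inverted dropout, softmax output) trained with Adam on a
   penalized cross-entropy objective

   ```
   J = (1/m) [ Σᵢ −yᵢ ln pᵢ₁ − (1−yᵢ) ln(1−pᵢ₁)  −  η Σ_{i∈neg} pᵢ₀ ]
   ```

   where pᵢ₁ is the positive-class probability and η (default 10) rewards
   confident negative-class probability on true negatives. This pushes the
   decision boundary toward the positive cluster, trading a little
   validation accuracy for a much lower fraction of unlabeled pairs called
   positive (PoPC) — i.e. more conservative, higher-precision predictions.
4. **Ranking and cross-reference.** Unlabeled pairs are ranked by the
   D-score, the logit distance to the decision boundary
   `D = ln(p/(1−p))`, and ranked lists are evaluated against reference
   interaction sets by counting overlaps in sliding bins of 500 consecutive
   predictions.

Because the real L1000 + DrugBank inputs are large external resources, the
package ships a first-class synthetic-panel generator (`simulate_panel()`)
that plants a signature-sharing mechanism — each gene has a latent signature,
knockdown profiles are its negation, drug profiles are the sum of their
targets' signatures — so the whole pipeline, including recovery of held-out
interactions, is testable offline.

## Worked example

A complete run on a synthetic panel at the default study conditions
(150 drugs, 150 genes, 1–3 targets per drug, 1–25 trials per entity,
signal strength 2, trial noise 0.5, 10% outlier trials), reduced to 32
landmark features so it finishes in a few seconds:

```r
library(dtiscope)

panel <- simulate_panel(panel_config(n_landmark = 32, seed = 1))
drug_cred <- aggregate_profiles(panel$drug_trials, seed = 2)
gene_cred <- aggregate_profiles(panel$gene_trials, seed = 3)

held_out <- panel$truth_edges[1:90, ]   # interactions to rediscover
pool <- build_sample_pool(drug_cred, gene_cred, panel$truth_edges[-(1:90), ],
                          ratio = 2)
dplyr::count(pool$samples, label)
#>   label        n
#> 1 negative  1472
#> 2 positive   736

fold <- kfold_split(pool, k = 5, seed = 4)[[1]]
fit <- train_dnn(
  pool_features(pool, fold$train),
  as.integer(fold$train$label == "positive"),
  network_config(c(64, 32, 8, 2), dropout_rate = 0.5),
  train_config(eta = 10, learning_rate = 1e-3, epochs = 300,
               batch_size = 64, seed = 5, patience = Inf)
)

cm_val <- predict(fit, pool_features(pool, fold$validation))
classification_metrics(cm_val, as.integer(fold$validation$label == "positive"))[1:4]
#>   accuracy f_score precision recall
#> 1    0.883   0.777         1  0.636

cm_unlabeled <- predict_pairs(fit, pool)
popc(cm_unlabeled)
#> [1] 0.482

ranked <- rank_predictions(cm_unlabeled)
curve <- sliding_overlap(ranked, held_out, bin_width = 500, step = 1)
n <- nrow(curve)
c(top    = mean(curve$overlap_count[1:floor(n / 10)]),
  bottom = mean(curve$overlap_count[(n - floor(n / 10) + 1):n]))
#>    top bottom
#>   8.59   0.90
```

Reading the output: the held-out fold is classified with 88% accuracy, and
precision 1 at recall 0.64 — the penalized objective makes the model call a
pair positive only when it is confident, which is also why fewer than half
of the unlabeled pairs are called positive (PoPC 0.48). The sliding-bin
overlap curve shows the payoff for discovery: windows at the top of the
D-score ranking contain on average 8.6 of the 90 held-out true interactions
per 500 predictions, versus 0.9 at the bottom — the ranking concentrates
real biology where a screening budget would be spent.

`autoplot()` methods are available for fitted models (training history) and
overlap curves; `tidy()` and `glance()` summarize a fitted network.

A thin command-line wrapper for the file-oriented stages (simulate,
aggregate, rank, overlap) is installed at `inst/cli/dtiscope.R`.

## Package layout

- `R/synthetic.R` — panel configuration and generator, TSV writer
- `R/profiles.R` — correlation matrices, k rule, credible-set selection
- `R/dataset.R` — fusion, labelling, negative sampling, pools, k-fold splits
- `R/model.R` — network, penalized objective, backprop/Adam trainer, prediction
- `R/scoring.R` — D-score, ranking, predictive error, PoPC, metrics
- `R/validation.R` — overlap counting and sliding-bin curves
- `vignettes/dti-pipeline.Rmd` — the methods vignette (model, assumptions,
  parameter choices, limitations)
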