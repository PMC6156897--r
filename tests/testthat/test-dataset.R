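test_that("serial fusion concatenates drug block first, losslessly", {
  expect_equal(fuse_profiles(c(1, 2), c(3, 4)), c(1, 2, 3, 4))
  expect_equal(length(fuse_profiles(rnorm(978), rnorm(978))), 1956)

  a <- rnorm(8); b <- rnorm(8)
  fused <- fuse_profiles(a, b)
  expect_false(identical(fused, fuse_profiles(b, a)))
  expect_equal(fused[1:8], a)       # both originals recoverable
  expect_equal(fused[9:16], b)
  expect_error(fuse_profiles(1:3, 1:4), "3.*4")
})

test_that("pair trichotomy follows the label structure", {
  lm <- label_matrix(
    tibble::tibble(drug_id = c("D1", "D2"), gene_id = c("G1", "G1")),
    drug_ids = c("D1", "D2", "D3"), gene_ids = c("G1", "G2")
  )
  expect_equal(classify_pair("D1", "G1", lm), "positive")
  expect_equal(classify_pair("D3", "G1", lm), "unlabeled")  # target of others
  expect_equal(classify_pair("D1", "G2", lm), "negative")   # targets nothing
  expect_error(classify_pair("D9", "G1", lm), "D9")
  expect_error(classify_pair("D1", "G9", lm), "G9")
})

test_that("negative sampling is systematic, deterministic and exact", {
  # the headline operating point: 3826 positives at ratio 2 -> 7652 negatives
  space <- sprintf("n%05d", seq_len(400000))
  sel <- sample_negatives(space, n_pos = 3826, ratio = 2)
  expect_equal(length(sel), 7652)
  expect_identical(sel, sample_negatives(space, n_pos = 3826, ratio = 2))

  # stride-2 systematic sample: indices {0,2,4,6,8} zero-based
  expect_equal(sample_negatives(1:10, n_pos = 2, ratio = 2.5), c(1, 3, 5, 7, 9))
  # exhaustion: space smaller than the request returns everything
  expect_equal(sample_negatives(1:4, n_pos = 3, ratio = 3), 1:4)
  expect_error(sample_negatives(integer(0), n_pos = 1, ratio = 2), "empty")
  # rounding is half away from zero
  expect_equal(length(sample_negatives(1:100, n_pos = 1, ratio = 2.5)), 3)
})

test_that("the sample pool partitions the pair space conservatively", {
  pool <- small_pool(seed = 7)
  samples <- pool$samples
  n_pos <- sum(samples$label == "positive")
  n_neg <- sum(samples$label == "negative")
  expect_equal(n_neg, round(2 * n_pos))

  # conservation: positives + unlabeled + negative space = all row pairs
  grid <- tidyr::expand_grid(drug_id = unique(pool$dm$row_entity),
                             gene_id = unique(pool$gm$row_entity))
  cls <- classify_pair(grid$drug_id, grid$gene_id, pool$lm)
  rows_of <- function(ids, ent) vapply(ids, function(i) sum(ent == i), integer(1))
  n_rowpairs <- function(pairs) {
    sum(rows_of(pairs$drug_id, pool$dm$row_entity) *
          rows_of(pairs$gene_id, pool$gm$row_entity))
  }
  expect_equal(
    n_pos + n_rowpairs(grid[cls == "unlabeled", ]) + n_rowpairs(grid[cls == "negative", ]),
    nrow(pool$dm$rows) * nrow(pool$gm$rows)
  )

  # every positive's label round-trips through classify_pair
  pos <- samples[samples$label == "positive", ]
  expect_true(all(classify_pair(pos$drug_id, pos$gene_id, pool$lm) == "positive"))
  # the three partitions are disjoint on (drug_row, gene_row)
  expect_equal(anyDuplicated(samples[c("drug_row", "gene_row")]), 0)
})

test_that("positives cover all credible-row combinations of each edge", {
  panel <- small_panel(seed = 19, n_drugs = 3, n_genes = 6)
  dc <- aggregate_profiles(panel$drug_trials, seed = 1)
  gc_ <- aggregate_profiles(panel$gene_trials, seed = 2)
  pool <- build_sample_pool(dc, gc_, panel$truth_edges, ratio = 2)
  pos <- pool$samples[pool$samples$label == "positive", ]
  for (i in seq_len(nrow(panel$truth_edges))) {
    d <- panel$truth_edges$drug_id[i]; g <- panel$truth_edges$gene_id[i]
    expect_equal(sum(pos$drug_id == d & pos$gene_id == g),
                 sum(dc$entity_id == d) * sum(gc_$entity_id == g))
  }
  expect_error(build_sample_pool(dc, gc_, panel$truth_edges[0, ], ratio = 2),
               "no positive")
})

test_that("pool features are the fused credible profiles", {
  pool <- small_pool(seed = 7)
  x <- pool_features(pool)
  n <- length(pool$dm$feature_ids)
  expect_equal(ncol(x), 2 * n)
  i <- 5
  expect_equal(x[i, ], c(pool$dm$rows[pool$samples$drug_row[i], ],
                         pool$gm$rows[pool$samples$gene_row[i], ]),
               ignore_attr = TRUE)
})

test_that("k-fold splits are stratified, disjoint, exhaustive and seeded", {
  pool <- small_pool(seed = 7)
  folds <- kfold_split(pool, k = 3, seed = 5)
  expect_length(folds, 3)
  all_val <- dplyr::bind_rows(lapply(folds, `[[`, "validation"))
  expect_equal(nrow(all_val), nrow(pool$samples))
  expect_equal(anyDuplicated(all_val[c("drug_row", "gene_row")]), 0)

  # no entity pair straddles train and validation of the same fold
  for (f in folds) {
    tr <- unique(paste(f$train$drug_id, f$train$gene_id))
    va <- unique(paste(f$validation$drug_id, f$validation$gene_id))
    expect_length(intersect(tr, va), 0)
  }

  # per-fold label stratification at the pair level (within 1 pair)
  pair_counts <- sapply(folds, function(f) {
    p <- dplyr::distinct(f$validation[c("drug_id", "gene_id", "label")])
    c(sum(p$label == "positive"), sum(p$label == "negative"))
  })
  expect_lte(diff(range(pair_counts[1, ])), 1)
  expect_lte(diff(range(pair_counts[2, ])), 1)

  expect_identical(folds, kfold_split(pool, k = 3, seed = 5))
  expect_false(identical(folds, kfold_split(pool, k = 3, seed = 6)))
  expect_error(kfold_split(pool, k = 1, seed = 1), "at least 2")
  expect_error(kfold_split(pool, k = 10000, seed = 1), "exceeds")
})
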