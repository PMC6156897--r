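#' Fuse a drug profile and a gene profile into one sample vector
#'
#' Classification samples are built by serial fusion: the drug profile is
#' concatenated in front of the gene profile with no transformation, so a pair
#' of n-feature profiles yields a 2n-feature sample (978 + 978 = 1956 for the
#' full landmark set). Both originals are recoverable by splitting at n.
#'
#' @param drug_profile,gene_profile Numeric vectors of equal length with the
#'   same feature ordering.
#' @return Numeric vector of length `2n`, drug block first.
#' @export
#' @examples
#' fuse_profiles(c(1, 2), c(3, 4))
fuse_profiles <- function(drug_profile, gene_profile) {
  if (length(drug_profile) != length(gene_profile)) {
    abort(paste0("profile lengths differ: drug ", length(drug_profile),
                 " vs gene ", length(gene_profile)))
  }
  c(unname(drug_profile), unname(gene_profile))
}

#' Build the interaction label structure
#'
#' Wraps a known-interaction edge list into the label structure that drives
#' the positive / unlabeled / negative trichotomy. A gene is a *target gene*
#' if it appears in at least one known edge; pairs involving a target gene but
#' lacking a recorded edge are unlabeled (the prediction universe), while
#' pairs whose gene targets nothing are negatives.
#'
#' @param edges Tibble or data frame with columns `drug_id`, `gene_id` of
#'   known interactions. IDs are whitespace-trimmed; duplicates dropped.
#' @param drug_ids,gene_ids Optional character vectors of the full entity
#'   universes; when given, lookups of unknown IDs error.
#' @return A `label_matrix` list with `known_edges`, `target_gene_ids` and the
#'   optional universes.
#' @export
label_matrix <- function(edges, drug_ids = NULL, gene_ids = NULL) {
  stopifnot(is.data.frame(edges), all(c("drug_id", "gene_id") %in% names(edges)))
  known <- dplyr::distinct(
    tibble(drug_id = trimws(edges$drug_id), gene_id = trimws(edges$gene_id))
  )
  if (!is.null(drug_ids)) {
    bad <- setdiff(known$drug_id, drug_ids)
    if (length(bad)) abort(paste0("edge drug ID not in drug matrix: '", bad[1], "'"))
  }
  if (!is.null(gene_ids)) {
    bad <- setdiff(known$gene_id, gene_ids)
    if (length(bad)) abort(paste0("edge gene ID not in gene matrix: '", bad[1], "'"))
  }
  structure(
    list(known_edges = known,
         target_gene_ids = unique(known$gene_id),
         drug_ids = drug_ids, gene_ids = gene_ids),
    class = "label_matrix"
  )
}

#' Classify a drug-gene pair as positive, unlabeled or negative
#'
#' @param drug_id,gene_id Character vectors (recycled to equal length).
#' @param lm A [label_matrix()].
#' @return Character vector in `{"positive", "unlabeled", "negative"}`.
#' @export
#' @examples
#' lm <- label_matrix(tibble::tibble(drug_id = "D1", gene_id = "G1"))
#' classify_pair(c("D1", "D2", "D2"), c("G1", "G1", "G2"), lm)
classify_pair <- function(drug_id, gene_id, lm) {
  stopifnot(inherits(lm, "label_matrix"))
  drug_id <- trimws(drug_id)
  gene_id <- trimws(gene_id)
  if (!is.null(lm$drug_ids)) {
    bad <- setdiff(drug_id, lm$drug_ids)
    if (length(bad)) abort(paste0("unknown drug ID: '", bad[1], "'"))
  }
  if (!is.null(lm$gene_ids)) {
    bad <- setdiff(gene_id, lm$gene_ids)
    if (length(bad)) abort(paste0("unknown gene ID: '", bad[1], "'"))
  }
  key <- paste(drug_id, gene_id, sep = "\r")
  pos_key <- paste(lm$known_edges$drug_id, lm$known_edges$gene_id, sep = "\r")
  ifelse(key %in% pos_key, "positive",
         ifelse(gene_id %in% lm$target_gene_ids, "unlabeled", "negative"))
}

# round half away from zero, fixed across platforms
round_half_up <- function(x) floor(x + 0.5)

#' Systematic negative sampling at uniform intervals
#'
#' Selects `round(ratio * n_pos)` negatives from the canonically ordered
#' negative sample space by taking indices at uniform intervals
#' (`floor(j * N / needed)` for `j = 0 .. needed-1`). The selection is fully
#' deterministic -- no randomness -- so the same space and counts always give
#' the same negatives. If the space is smaller than the request, all of it is
#' returned.
#'
#' @param space Vector (or tibble of keys) enumerating the negative sample
#'   space in canonical order.
#' @param n_pos Number of positive samples (>= 1).
#' @param ratio Desired negative:positive ratio (> 0); the headline operating
#'   point is 1:2, i.e. `ratio = 2`.
#' @return The selected elements (rows) of `space`, in order.
#' @export
#' @examples
#' sample_negatives(1:10, n_pos = 2, ratio = 2.5)  # stride-2 systematic sample
sample_negatives <- function(space, n_pos, ratio) {
  n_space <- if (is.data.frame(space)) nrow(space) else length(space)
  if (n_pos < 1) abort("`n_pos` must be at least 1")
  if (ratio <= 0) abort("`ratio` must be positive")
  if (n_space == 0) abort("negative sample space is empty")
  needed <- round_half_up(ratio * n_pos)
  if (n_space <= needed) {
    idx <- seq_len(n_space)
  } else {
    idx <- floor((seq_len(needed) - 1) * n_space / needed) + 1L
  }
  if (is.data.frame(space)) space[idx, , drop = FALSE] else space[idx]
}

#' Assemble the classification sample pool
#'
#' Combines credible-set profile tables for drugs and genes with a known
#' interaction edge list into the pool of fused classification samples:
#' every credible-row combination of every known edge becomes a positive
#' sample; negatives are drawn by [sample_negatives()] from the row-level
#' negative space ordered gene-major (gene, drug, gene row, drug row,
#' lexicographic); unlabeled pairs are kept as keys and fused on demand.
#'
#' @param drug_profiles,gene_profiles Credible-set tibbles from
#'   [aggregate_profiles()] (columns `entity_id`, `provenance`, features),
#'   sharing one feature ordering.
#' @param edges Known-interaction edge list (`drug_id`, `gene_id`).
#' @param ratio Negative:positive sample ratio (default 2).
#' @return A `sample_pool` list with the profile matrices (`dm`, `gm`), the
#'   labelled `samples` tibble (`drug_id`, `gene_id`, `drug_row`, `gene_row`,
#'   `label`), the `unlabeled` pair tibble, the [label_matrix()] and the
#'   ratio.
#' @export
build_sample_pool <- function(drug_profiles, gene_profiles, edges, ratio = 2) {
  dm <- profile_matrix(drug_profiles)
  gm <- profile_matrix(gene_profiles)
  if (!identical(dm$feature_ids, gm$feature_ids)) {
    abort("drug and gene profiles have different feature sets")
  }
  lm <- label_matrix(edges, drug_ids = unique(dm$row_entity),
                     gene_ids = unique(gm$row_entity))
  if (nrow(lm$known_edges) == 0) abort("no positive edges")

  drug_rows <- split(seq_along(dm$row_entity), dm$row_entity)
  gene_rows <- split(seq_along(gm$row_entity), gm$row_entity)

  # entity-level pair classification over the full drug x gene grid
  grid <- tidyr::expand_grid(drug_id = unique(dm$row_entity),
                             gene_id = unique(gm$row_entity))
  grid$label <- classify_pair(grid$drug_id, grid$gene_id, lm)

  expand_rows <- function(pairs) {
    pairs$drug_row <- unname(drug_rows[pairs$drug_id])
    pairs$gene_row <- unname(gene_rows[pairs$gene_id])
    tidyr::unnest(tidyr::unnest(pairs, "drug_row"), "gene_row")
  }

  positives <- expand_rows(grid[grid$label == "positive", ])

  neg_space <- expand_rows(grid[grid$label == "negative", ])
  neg_space <- neg_space[order(neg_space$gene_id, neg_space$drug_id,
                               neg_space$gene_row, neg_space$drug_row,
                               method = "radix"), ]
  negatives <- sample_negatives(neg_space, n_pos = nrow(positives), ratio = ratio)

  samples <- dplyr::bind_rows(positives, negatives)
  samples <- samples[c("drug_id", "gene_id", "drug_row", "gene_row", "label")]

  structure(
    list(dm = dm, gm = gm, samples = as_tibble(samples),
         unlabeled = as_tibble(grid[grid$label == "unlabeled",
                                    c("drug_id", "gene_id")]),
         lm = lm, ratio = ratio),
    class = "sample_pool"
  )
}

# credible tibble -> list(rows matrix, row_entity, provenance, feature_ids)
profile_matrix <- function(profiles) {
  stopifnot(is.data.frame(profiles),
            all(c("entity_id", "provenance") %in% names(profiles)))
  feats <- setdiff(names(profiles), c("entity_id", "provenance"))
  m <- as.matrix(profiles[feats])
  if (any(!is.finite(m))) abort("profiles contain non-finite values")
  list(rows = m, row_entity = profiles$entity_id,
       provenance = profiles$provenance, feature_ids = feats)
}

#' Fused feature matrix for pool samples
#'
#' Materializes the fused `2n`-feature vectors for a set of row-level sample
#' keys from a [build_sample_pool()] pool.
#'
#' @param pool A `sample_pool`.
#' @param samples Tibble with `drug_row` and `gene_row` columns (defaults to
#'   the pool's labelled samples).
#' @return Numeric matrix, one row per sample, `2n` columns.
#' @export
pool_features <- function(pool, samples = pool$samples) {
  stopifnot(inherits(pool, "sample_pool"))
  cbind(pool$dm$rows[samples$drug_row, , drop = FALSE],
        pool$gm$rows[samples$gene_row, , drop = FALSE])
}

#' Expand entity pairs to all credible-row combinations
#'
#' @param pool A `sample_pool`.
#' @param pairs Tibble with `drug_id`, `gene_id`.
#' @return Tibble with `drug_id`, `gene_id`, `drug_row`, `gene_row`.
#' @export
expand_pairs <- function(pool, pairs) {
  stopifnot(inherits(pool, "sample_pool"))
  drug_rows <- split(seq_along(pool$dm$row_entity), pool$dm$row_entity)
  gene_rows <- split(seq_along(pool$gm$row_entity), pool$gm$row_entity)
  pairs <- pairs[c("drug_id", "gene_id")]
  pairs$drug_row <- unname(drug_rows[pairs$drug_id])
  pairs$gene_row <- unname(gene_rows[pairs$gene_id])
  as_tibble(tidyr::unnest(tidyr::unnest(pairs, "drug_row"), "gene_row"))
}

#' Stratified k-fold split of the labelled pool
#'
#' Partitions the labelled samples into k cross-validation folds. The split is
#' made at the entity-pair level -- all credible-row combinations of one
#' (drug, gene) pair land in the same fold -- so representative profiles of a
#' pair can never leak between training and validation. Pairs are shuffled
#' with the given seed and dealt round-robin within each label stratum.
#' Unlabeled pairs never enter any fold.
#'
#' @param pool A `sample_pool`.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed for the shuffle.
#' @return List of k folds, each a list with `train` and `validation` sample
#'   tibbles.
#' @export
kfold_split <- function(pool, k, seed = 1L) {
  stopifnot(inherits(pool, "sample_pool"))
  if (k < 2) abort("`k` must be at least 2")
  pairs <- dplyr::distinct(pool$samples[c("drug_id", "gene_id", "label")])
  n_pos <- sum(pairs$label == "positive")
  if (k > nrow(pairs)) abort("`k` exceeds the number of labelled pairs")
  if (n_pos < k) abort("fewer positive pairs than folds")

  pairs <- withr::with_seed(seed, {
    shuffled <- pairs[sample.int(nrow(pairs)), ]
    shuffled <- shuffled[order(shuffled$label, method = "radix"), ]
    shuffled$fold <- stats::ave(seq_len(nrow(shuffled)), shuffled$label,
                                FUN = function(i) ((seq_along(i) - 1L) %% k) + 1L)
    shuffled
  })

  keyed <- dplyr::left_join(pool$samples, pairs,
                            by = c("drug_id", "gene_id", "label"))
  lapply(seq_len(k), function(f) {
    list(train = keyed[keyed$fold != f, setdiff(names(keyed), "fold")],
         validation = keyed[keyed$fold == f, setdiff(names(keyed), "fold")])
  })
}
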