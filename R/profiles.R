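#' Pearson correlation matrix of replicate trials
#'
#' Computes the trial-by-trial Pearson correlation matrix used to judge how
#' internally consistent the replicates of one perturbation entity are.
#'
#' @param trials Numeric matrix, one row per trial, one column per feature.
#' @return Symmetric matrix with unit diagonal, entries in `[-1, 1]`.
#' @export
#' @examples
#' m <- rbind(c(1, 2, 3), c(1, 2, 4))
#' pearson_matrix(m)
pearson_matrix <- function(trials) {
  trials <- as.matrix(trials)
  if (nrow(trials) < 2) abort("need at least 2 trials for a correlation matrix")
  v <- apply(trials, 1, stats::var)
  if (any(v == 0)) {
    abort(paste0("trial ", which(v == 0)[1], " has zero variance"))
  }
  r <- stats::cor(t(trials))
  diag(r) <- 1
  r
}

#' Cluster count rule for replicate trials
#'
#' Maps the number of replicate trials of an entity to the number of k-means
#' clusters used when picking its representative cluster: no clustering for
#' `n <= 2`, k = 2 for `2 < n <= 5`, k = 3 for `5 < n <= 15`, k = 4 above 15.
#' Boundary counts go to the smaller k so the rule is closed and monotone.
#'
#' @param n_trials Positive integer trial count.
#' @return Integer k, or `NA` when no clustering is performed.
#' @export
#' @examples
#' choose_k(4)   # 2
#' choose_k(20)  # 4
choose_k <- function(n_trials) {
  stopifnot(length(n_trials) == 1L, n_trials >= 1)
  if (n_trials <= 2) return(NA_integer_)
  if (n_trials <= 5) return(2L)
  if (n_trials <= 15) return(3L)
  4L
}

#' Mean intra-cluster Pearson correlation
#'
#' The quality score of one cluster of replicate trials: the arithmetic mean
#' of all pairwise Pearson correlations among its members. A singleton cluster
#' scores 1.0 by convention so that it is neither favored nor penalized and
#' the score is always defined.
#'
#' @param trials Numeric trial matrix (rows = trials).
#' @param members Integer indices of the cluster members.
#' @return A single correlation in `[-1, 1]`.
#' @export
intra_class_correlation <- function(trials, members) {
  if (length(members) == 0) abort("cluster has no members")
  if (length(members) == 1) return(1.0)
  r <- pearson_matrix(as.matrix(trials)[members, , drop = FALSE])
  mean(r[upper.tri(r)])
}

#' Select the credible set of one perturbation entity
#'
#' Aggregates all replicate trials of one entity into at most two
#' representative profiles. With three or more trials, the trials are
#' partitioned by seeded k-means (k from [choose_k()], Euclidean distance on
#' the raw Z-score vectors, 10 restarts) and the cluster with the highest mean
#' intra-cluster Pearson correlation becomes S1 (its centroid); ties go to the
#' lowest cluster label. Singleton clusters are not eligible for S1 when any
#' multi-member cluster exists: a lone trial scores a vacuous 1.0 and would
#' otherwise always beat genuinely coherent replicate groups. S2 is always the grand mean of all trials. With two
#' or fewer trials no clustering is done and S1 is the grand mean. If S1 and
#' S2 agree within 1e-9 per element only the S1 row is kept.
#'
#' @param trials Numeric trial matrix (rows = trials) for one entity.
#' @param seed Integer seed for the k-means restarts.
#' @return A list of class `credible_set`: `profiles` (1- or 2-row matrix),
#'   `provenance` (`"S1"`/`"S2"` per row), `k` (clusters used, `NA` if none),
#'   `cluster` (k-means assignment per trial, or `NULL`) and `winner` (label
#'   of the chosen cluster, or `NA`).
#' @export
select_credible_set <- function(trials, seed = 1L) {
  trials <- as.matrix(trials)
  n <- nrow(trials)
  if (n < 1) abort("entity has no trials")
  s2 <- colMeans(trials)

  k <- choose_k(n)
  cluster <- NULL
  winner <- NA_integer_
  k_used <- NA_integer_
  s1 <- s2
  if (!is.na(k)) {
    # kmeans needs at least k distinct points; collapse k when replicates repeat
    k_eff <- min(k, nrow(unique(trials)))
    if (k_eff >= 2) {
      km <- withr::with_seed(seed,
        stats::kmeans(trials, centers = k_eff, nstart = 10))
      cluster <- km$cluster
      icc <- vapply(seq_len(k_eff), function(cl) {
        intra_class_correlation(trials, which(cluster == cl))
      }, numeric(1))
      # singletons score a vacuous 1.0 and would always win; a cluster must
      # have >= 2 members (real replicate agreement) to represent the entity
      eligible <- which(tabulate(cluster, k_eff) >= 2)
      if (length(eligible) == 0) eligible <- seq_len(k_eff)
      winner <- eligible[which.max(icc[eligible])]  # lowest label on ties
      s1 <- colMeans(trials[cluster == winner, , drop = FALSE])
      k_used <- k_eff
    }
  }

  if (all(abs(s1 - s2) <= 1e-9)) {
    profiles <- matrix(s1, nrow = 1)
    provenance <- "S1"
  } else {
    profiles <- rbind(s1, s2)
    provenance <- c("S1", "S2")
  }
  colnames(profiles) <- colnames(trials)
  rownames(profiles) <- NULL
  structure(
    list(profiles = profiles, provenance = provenance,
         k = k_used, cluster = cluster, winner = winner),
    class = "credible_set"
  )
}

#' Aggregate a trial table into credible-set profiles
#'
#' Applies [select_credible_set()] to every entity of a trial tibble and
#' returns the representatives in tidy form, ready for sample fusion.
#'
#' @param trials Tibble with an `entity_id` column and numeric feature
#'   columns, one row per replicate trial (the [read_trials()] /
#'   [simulate_panel()] dialect).
#' @param seed Integer seed; entity-level k-means runs draw from one seeded
#'   stream so the result is reproducible.
#' @return Tibble with columns `entity_id`, `provenance` (`"S1"`/`"S2"`) and
#'   the feature columns; 1--2 rows per entity.
#' @export
#' @examples
#' panel <- simulate_panel(panel_config(n_landmark = 16, n_drugs = 2,
#'                                      n_genes = 4, seed = 3))
#' aggregate_profiles(panel$gene_trials, seed = 3)
aggregate_profiles <- function(trials, seed = 1L) {
  by_entity <- trials_by_entity(trials)
  feats <- setdiff(names(trials), "entity_id")
  withr::with_seed(seed, {
    rows <- purrr::imap(by_entity, function(m, id) {
      cs <- select_credible_set(m, seed = sample.int(.Machine$integer.max, 1))
      dplyr::bind_cols(
        tibble(entity_id = id, provenance = cs$provenance),
        as_tibble(cs$profiles)
      )
    })
    out <- dplyr::bind_rows(rows)
  })
  names(out) <- c("entity_id", "provenance", feats)
  out
}
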