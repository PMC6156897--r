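#' Configure a synthetic perturbation panel
#'
#' Builds the configuration for [simulate_panel()]. The generator emulates the
#' replicate structure of L1000-style perturbation experiments: each drug and
#' each gene-knockdown entity is measured in several trials, every trial is a
#' Z-score-like profile over a fixed set of landmark features, and a planted
#' signature-sharing mechanism links drugs to their true target genes so that
#' interaction labels are learnable from the profiles alone.
#'
#' Each gene `g` receives a latent unit-norm signature vector. The knockdown
#' mean profile of `g` is the negated signature scaled by `signal_strength`
#' (knockdown suppresses what the gene drives); the mean profile of a drug is
#' the sum of its target genes' signatures, scaled by `signal_strength`.
#' Individual trials add i.i.d. Gaussian noise, and a fraction of trials are
#' replaced by pure noise to mimic failed or outlying experiments.
#'
#' @param n_landmark Number of landmark features per profile (default 978, the
#'   size of the L1000 landmark set; reduce to ~32 for fast experiments).
#' @param n_drugs,n_genes Number of drug and gene-knockdown entities. The
#'   defaults (150 each, with 1--3 targets per drug) give a panel of roughly
#'   300 planted interactions -- a scaled-down mirror of a DrugBank-sized
#'   gold standard (hundreds of drugs and targets, ~2 targets per drug) that
#'   is still large enough to train the classifier.
#' @param targets_per_drug Integer range `c(min, max)`: how many true target
#'   genes each drug gets.
#' @param trials_per_entity Integer range `c(min, max)` of replicate trials per
#'   entity. The default 1--25 exercises every branch of the replicate
#'   clustering rule used downstream.
#' @param signal_strength Nonnegative scale of the planted signatures. At 0 the
#'   panel carries no learnable structure.
#' @param trial_noise_sd Positive standard deviation of per-feature trial noise.
#' @param outlier_fraction Probability in `[0, 1)` that a trial is replaced by
#'   pure noise (mean zero).
#' @param seed Integer seed; the same configuration always yields a
#'   bit-identical panel.
#'
#' @return A `panel_config` list.
#' @seealso [simulate_panel()], [write_panel()]
#' @export
#' @examples
#' cfg <- panel_config(n_landmark = 32, n_drugs = 4, n_genes = 10, seed = 1)
panel_config <- function(n_landmark = 978,
                         n_drugs = 150,
                         n_genes = 150,
                         targets_per_drug = c(1L, 3L),
                         trials_per_entity = c(1L, 25L),
                         signal_strength = 2,
                         trial_noise_sd = 0.5,
                         outlier_fraction = 0.1,
                         seed = 1L) {
  check_range <- function(x, name) {
    if (length(x) == 1L) x <- c(x, x)
    if (length(x) != 2L || any(!is.finite(x)) || any(x < 1) || any(x != floor(x))) {
      abort(paste0("`", name, "` must be one or two positive integers"))
    }
    if (x[1] > x[2]) {
      abort(paste0("`", name, "` has min > max (", x[1], " > ", x[2], ")"))
    }
    as.integer(x)
  }
  targets_per_drug <- check_range(targets_per_drug, "targets_per_drug")
  trials_per_entity <- check_range(trials_per_entity, "trials_per_entity")
  if (n_landmark < 2) abort("`n_landmark` must be at least 2")
  if (n_drugs < 1 || n_genes < 1) abort("`n_drugs` and `n_genes` must be at least 1")
  if (targets_per_drug[2] > n_genes) {
    abort("`targets_per_drug` max exceeds `n_genes`")
  }
  if (signal_strength < 0) abort("`signal_strength` must be nonnegative")
  if (trial_noise_sd <= 0) abort("`trial_noise_sd` must be positive")
  if (outlier_fraction < 0 || outlier_fraction >= 1) {
    abort("`outlier_fraction` must be in [0, 1)")
  }
  structure(
    list(
      n_landmark = as.integer(n_landmark),
      n_drugs = as.integer(n_drugs),
      n_genes = as.integer(n_genes),
      targets_per_drug = targets_per_drug,
      trials_per_entity = trials_per_entity,
      signal_strength = signal_strength,
      trial_noise_sd = trial_noise_sd,
      outlier_fraction = outlier_fraction,
      seed = as.integer(seed)
    ),
    class = "panel_config"
  )
}

#' Simulate a perturbation panel with planted drug-target structure
#'
#' Draws a full synthetic panel under the generative model described in
#' [panel_config()]: latent gene signatures, planted drug-target edges,
#' per-entity replicate trials with Gaussian noise and optional outlier
#' trials.
#'
#' @param config A [panel_config()].
#'
#' @return A `synthetic_panel` list with elements:
#' \describe{
#'   \item{drug_trials, gene_trials}{Tibbles with an `entity_id` column
#'     followed by one column per landmark feature; one row per trial.}
#'   \item{truth_edges}{Tibble of planted `(drug_id, gene_id)` interactions.}
#'   \item{entity_means}{List of two matrices (`drug`, `gene`) holding the
#'     noise-free mean profile of every entity -- the ground truth that trials
#'     scatter around, kept for evaluating aggregation quality.}
#'   \item{feature_ids}{Character vector of landmark feature names.}
#'   \item{config}{The configuration used.}
#' }
#' @export
#' @examples
#' panel <- simulate_panel(panel_config(n_landmark = 16, n_drugs = 3,
#'                                      n_genes = 8, seed = 7))
#' dplyr::count(panel$drug_trials, entity_id)
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  withr::with_seed(config$seed, simulate_panel_impl(config))
}

simulate_panel_impl <- function(cfg) {
  n <- cfg$n_landmark
  feature_ids <- sprintf("L%04d", seq_len(n))
  drug_ids <- sprintf("D%03d", seq_len(cfg$n_drugs))
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))

  # latent unit-norm signature per gene
  sig <- matrix(rnorm(cfg$n_genes * n), nrow = cfg$n_genes)
  sig <- sig / sqrt(rowSums(sig^2))
  rownames(sig) <- gene_ids

  gene_means <- -cfg$signal_strength * sig
  rownames(gene_means) <- gene_ids

  n_targets <- sample_range(cfg$targets_per_drug, cfg$n_drugs)
  targets <- lapply(n_targets, function(k) sort(sample.int(cfg$n_genes, k)))
  drug_means <- t(vapply(
    targets,
    function(idx) cfg$signal_strength * colSums(sig[idx, , drop = FALSE]),
    numeric(n)
  ))
  rownames(drug_means) <- drug_ids

  truth_edges <- tibble(
    drug_id = rep(drug_ids, lengths(targets)),
    gene_id = gene_ids[unlist(targets)]
  )

  # outlier trials are pure noise but at the marginal scale of a real trial
  # (a failed experiment still yields full-magnitude Z-scores), so their
  # per-feature sd matches signal^2/n + noise^2
  outlier_sd <- sqrt(cfg$signal_strength^2 / n + cfg$trial_noise_sd^2)

  draw_trials <- function(means, ids) {
    n_trials <- sample_range(cfg$trials_per_entity, length(ids))
    rows <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      m <- matrix(rnorm(n_trials[i] * n, sd = cfg$trial_noise_sd),
                  nrow = n_trials[i])
      keep <- runif(n_trials[i]) >= cfg$outlier_fraction
      if (any(keep)) {
        m[keep, ] <- m[keep, , drop = FALSE] +
          matrix(means[i, ], nrow = sum(keep), ncol = n, byrow = TRUE)
      }
      if (any(!keep)) {
        m[!keep, ] <- matrix(rnorm(sum(!keep) * n, sd = outlier_sd),
                             nrow = sum(!keep))
      }
      rows[[i]] <- m
    }
    out <- do.call(rbind, rows)
    colnames(out) <- feature_ids
    dplyr::bind_cols(
      tibble(entity_id = rep(ids, n_trials)),
      as_tibble(out)
    )
  }

  structure(
    list(
      drug_trials = draw_trials(drug_means, drug_ids),
      gene_trials = draw_trials(gene_means, gene_ids),
      truth_edges = truth_edges,
      entity_means = list(drug = drug_means, gene = gene_means),
      feature_ids = feature_ids,
      config = cfg
    ),
    class = "synthetic_panel"
  )
}

sample_range <- function(range, n) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Write a synthetic panel to tab-separated files
#'
#' Emits `drug_trials.tsv` and `gene_trials.tsv` (one row per trial, first
#' column `entity_id`, then one column per landmark feature) plus
#' `truth_edges.tsv` (two-column edge list). The files round-trip losslessly
#' through [read_trials()] and [read_edges()].
#'
#' @param panel A `synthetic_panel` from [simulate_panel()].
#' @param directory Output directory; created if absent.
#' @return Invisibly, the paths of the three files written.
#' @export
write_panel <- function(panel, directory) {
  stopifnot(inherits(panel, "synthetic_panel"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory '", directory, "'"))
  }
  paths <- file.path(directory,
                     c("drug_trials.tsv", "gene_trials.tsv", "truth_edges.tsv"))
  readr::write_tsv(panel$drug_trials, paths[1])
  readr::write_tsv(panel$gene_trials, paths[2])
  readr::write_tsv(panel$truth_edges, paths[3])
  invisible(paths)
}
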