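#' Read a trial matrix from TSV
#'
#' Reads a tab-separated trial table in the panel dialect: first column
#' `entity_id`, remaining columns numeric landmark features, one row per
#' replicate trial.
#'
#' @param path Path to a TSV file.
#' @return A tibble with `entity_id` and feature columns.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) abort(paste0("trial file not found: '", path, "'"))
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(entity_id = readr::col_character(),
                                               .default = readr::col_double()))
  if (!"entity_id" %in% names(x)) {
    abort(paste0("'", path, "' has no entity_id column"))
  }
  feats <- as.matrix(x[setdiff(names(x), "entity_id")])
  if (any(!is.finite(feats))) {
    abort(paste0("'", path, "' contains non-finite feature values"))
  }
  x
}

#' Read an interaction edge list from TSV
#'
#' Reads a two-column tab-separated edge list with header
#' `drug_id`/`gene_id`. IDs are whitespace-trimmed and duplicate edges are
#' dropped.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `drug_id` and `gene_id`.
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) abort(paste0("edge file not found: '", path, "'"))
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("drug_id", "gene_id") %in% names(x))) {
    abort(paste0("'", path, "' must have drug_id and gene_id columns"))
  }
  dplyr::distinct(
    tibble(drug_id = trimws(x$drug_id), gene_id = trimws(x$gene_id))
  )
}

# Split a trials tibble into a named list of per-entity numeric matrices,
# preserving first-appearance entity order.
trials_by_entity <- function(trials) {
  stopifnot(is.data.frame(trials), "entity_id" %in% names(trials))
  feats <- setdiff(names(trials), "entity_id")
  m <- as.matrix(trials[feats])
  if (!is.numeric(m) || any(!is.finite(m))) {
    abort("trial features must be finite numeric values")
  }
  ids <- trials$entity_id
  split_idx <- split(seq_len(nrow(m)), factor(ids, levels = unique(ids)))
  lapply(split_idx, function(i) m[i, , drop = FALSE])
}
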