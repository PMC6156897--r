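#' Count ranked predictions confirmed by a reference set
#'
#' Number of ranked (drug, gene) pairs that also appear in a reference
#' interaction edge list. Keys match by exact string equality after
#' whitespace trimming; duplicate reference edges are de-duplicated.
#'
#' @param ranked Ranked prediction tibble from [rank_predictions()] (needs
#'   `drug_id`, `gene_id`).
#' @param ref Reference edge list (`drug_id`, `gene_id`).
#' @param name Name of the reference set, used in error messages.
#' @return Integer overlap count.
#' @export
overlap_count <- function(ranked, ref, name = "reference") {
  if (nrow(ranked) == 0) abort("ranked list is empty")
  ref_keys <- ref_key_set(ref, name)
  sum(pair_key(ranked) %in% ref_keys)
}

ref_key_set <- function(ref, name) {
  stopifnot(all(c("drug_id", "gene_id") %in% names(ref)))
  if (nrow(ref) == 0) abort(paste0("reference set '", name, "' is empty"))
  unique(paste(trimws(ref$drug_id), trimws(ref$gene_id), sep = "\r"))
}

pair_key <- function(x) {
  paste(trimws(x$drug_id), trimws(x$gene_id), sep = "\r")
}

#' Sliding-bin overlap curve along a ranked prediction list
#'
#' Slides a window of `bin_width` consecutive ranked predictions down the
#' list (default 500, sliding by 1) and counts, within each window, how many
#' pairs are confirmed by the reference set. If a ranking is enriched for
#' true interactions at the top, the curve is high for early windows and
#' decays; with `step = bin_width` the windows are disjoint and the counts
#' sum to the overlap of the covered prefix.
#'
#' @param ranked Ranked prediction tibble (in rank order).
#' @param ref Reference edge list (`drug_id`, `gene_id`).
#' @param bin_width Window size in ranks (default 500).
#' @param step Slide increment (default 1).
#' @param name Reference-set name for error messages.
#' @return An `overlap_curve` tibble: `start_rank` (1-based first rank of the
#'   window) and `overlap_count`.
#' @export
sliding_overlap <- function(ranked, ref, bin_width = 500L, step = 1L,
                            name = "reference") {
  if (bin_width < 1 || step < 1) abort("`bin_width` and `step` must be positive")
  n <- nrow(ranked)
  if (bin_width > n) {
    abort(paste0("bin_width (", bin_width, ") exceeds ranked list length (", n, ")"))
  }
  member <- as.integer(pair_key(ranked) %in% ref_key_set(ref, name))
  cum <- c(0L, cumsum(member))
  starts <- seq(1L, n - bin_width + 1L, by = step)
  counts <- cum[starts + bin_width] - cum[starts]
  structure(
    tibble(start_rank = starts, overlap_count = counts),
    bin_width = as.integer(bin_width), step = as.integer(step),
    class = c("overlap_curve", class(tibble()))
  )
}

#' @describeIn sliding_overlap Plot the overlap curve.
#' @param object An `overlap_curve`.
#' @param ... Unused.
#' @export
#' @method autoplot overlap_curve
autoplot.overlap_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$start_rank, y = .data$overlap_count)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "window start rank",
      y = sprintf("confirmed pairs per %d-wide window", attr(object, "bin_width"))
    )
}
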