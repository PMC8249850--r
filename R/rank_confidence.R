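#' Confidence-thresholded, rank-truncating taxonomy assignment
#'
#' Shared assignment procedure used by every classifier in the package.
#' Given a per-read probability vector over the reference classes, the
#' species level is tested first: if the maximum class probability is
#' strictly greater than the confidence threshold, the argmax lineage is
#' reported (ties among equal maxima are broken uniformly at random).
#' Otherwise probabilities are aggregated over classes sharing each
#' genus-level prefix and the test repeated at genus, then family, and so
#' on up to kingdom. If no rank ever exceeds the threshold the read is
#' Unassigned. Classes whose reference lineage is itself truncated
#' participate at their deepest labeled rank.
#'
#' @param probs named numeric vector: class lineage key -> probability
#'   (non-negative, summing to 1 within 1e-6).
#' @param confidence threshold in `[0, 1)`; the comparison is strict
#'   (`>`).
#' @param seed optional integer seed for tie-breaking; when `NULL` the
#'   current RNG stream is used.
#' @return List with elements `lineage` (character vector of prefixed
#'   labels, possibly empty = Unassigned) and `confidence` (the winning
#'   aggregate probability, 0 when Unassigned).
#' @examples
#' p <- c("k__B; p__X; c__C; o__O; f__F; g__G; s__a" = 0.8,
#'        "k__B; p__X; c__C; o__O; f__F; g__G; s__b" = 0.2)
#' assign_with_confidence(p, confidence = 0.7)
#' @export
assign_with_confidence <- function(probs, confidence = 0.7, seed = NULL) {
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      confidence < 0 || confidence >= 1) {
    stop("confidence must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(names(probs)) || any(probs < 0) ||
      abs(sum(probs) - 1) > 1e-6) {
    stop("probs must be a named non-negative vector summing to 1",
         call. = FALSE)
  }
  lineages <- lapply(names(probs), parse_lineage)
  with_seed(seed, {
    for (depth in 7:1) {
      keys <- vapply(lineages, function(l) {
        format_lineage(truncate_lineage(l, depth))
      }, character(1))
      agg <- vapply(split(unname(probs), keys), sum, numeric(1))
      top <- max(agg)
      if (top > confidence) {
        cand <- names(agg)[abs(agg - top) < 1e-12]
        pick <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
        return(list(lineage = parse_lineage(pick), confidence = top))
      }
    }
    list(lineage = character(0), confidence = 0)
  })
}

#' Classify reads with any fitted classifier
#'
#' Computes per-read class probabilities with `predict()` and applies
#' [assign_with_confidence()] to each read.
#'
#' @param model a fitted classifier (`ampli_nb`, `ampli_forest`,
#'   `ampli_cnn`, or `exact_index`).
#' @param reads a [read_set()] or named character vector of sequences.
#' @param confidence threshold in `[0, 1)` (default 0.7).
#' @param seed integer seed governing tie-breaks.
#' @return Data frame with columns `read_id`, `lineage` (formatted,
#'   `"Unassigned"` when empty) and `confidence`.
#' @export
classify_reads <- function(model, reads, confidence = 0.7, seed = 1L) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  probs <- stats::predict(model, reads)
  with_seed(seed, {
    res <- lapply(seq_len(nrow(probs)), function(i) {
      assign_with_confidence(probs[i, ], confidence = confidence, seed = NULL)
    })
    data.frame(
      read_id = rownames(probs),
      lineage = vapply(res, function(r) format_lineage(r$lineage), character(1)),
      confidence = vapply(res, function(r) r$confidence, numeric(1)),
      stringsAsFactors = FALSE)
  })
}
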