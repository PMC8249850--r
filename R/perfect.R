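#' Build an exact-sequence-match index (the "perfect" classifier)
#'
#' The perfect classifier measures the upper bound of classification
#' accuracy achievable for a reference database, amplicon length and
#' weight distribution: it looks reads up by exact (trimmed, case-folded)
#' sequence identity and can only err when two or more species share an
#' identical sequence. For every distinct reference sequence the index
#' stores the list of matching class lineages with weights taken from the
#' class-weight distribution (or equal weights in uniform mode) and
#' renormalized per sequence.
#'
#' @param refdb a [ref_db()] object; sequences should already be trimmed
#'   to the amplicon/length under study.
#' @param weights `class_weights` over the reference classes; defaults to
#'   [uniform_weights()].
#' @return Object of class `exact_index`.
#' @export
build_exact_index <- function(refdb, weights = uniform_weights(refdb)) {
  stopifnot(inherits(refdb, "refdb"))
  keys <- species_keys(refdb)
  if (!setequal(names(weights), keys)) {
    stop("class weights are not bound to this reference database",
         call. = FALSE)
  }
  seq_class <- vapply(refdb$taxonomy, format_lineage, character(1))
  entries <- lapply(split(seq_class, unname(refdb$sequences)), function(cls) {
    cls <- unique(cls)
    w <- as.numeric(weights[cls])
    stats::setNames(w / sum(w), cls)
  })
  structure(list(entries = entries, classes = keys,
                 weight_mode = attr(weights, "mode_tag")),
            class = "exact_index")
}

#' @export
print.exact_index <- function(x, ...) {
  shared <- sum(vapply(x$entries, length, integer(1)) > 1L)
  cat(sprintf(
    "<exact_index> %d distinct sequences (%d shared by >1 class), %s weights\n",
    length(x$entries), shared, x$weight_mode))
  invisible(x)
}

#' Per-sequence ambiguity report of an exact index
#'
#' @param index an [build_exact_index()] result.
#' @return Data frame with one row per distinct sequence: `n_classes`
#'   sharing it and the top class.
#' @export
ambiguity_report <- function(index) {
  stopifnot(inherits(index, "exact_index"))
  data.frame(
    sequence = names(index$entries),
    n_classes = vapply(index$entries, length, integer(1)),
    top_class = vapply(index$entries, function(e) names(e)[which.max(e)],
                       character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Class probabilities from the exact index
#'
#' Each read's probability vector puts the per-sequence normalized taxon
#' weights on the matching classes and zero elsewhere. Reads absent from
#' the index violate the in-sample contract and are a hard error: the
#' classifier is an in-sample accuracy bound, and a silent fallback would
#' corrupt it.
#'
#' @param object an `exact_index`.
#' @param newdata a [read_set()] or named character vector of sequences.
#' @param ... unused.
#' @return Numeric matrix (reads x classes); rows sum to 1.
#' @export
predict.exact_index <- function(object, newdata, ...) {
  if (inherits(newdata, "read_set")) newdata <- newdata$reads
  if (is.null(names(newdata))) {
    names(newdata) <- paste0("read", seq_along(newdata))
  }
  seqs <- toupper(newdata)
  miss <- !(seqs %in% names(object$entries))
  if (any(miss)) {
    stop(sprintf(
      "read '%s' is not an exact match to any reference sequence; the perfect classifier is in-sample only",
      names(seqs)[miss][1]), call. = FALSE)
  }
  out <- matrix(0, length(seqs), length(object$classes),
                dimnames = list(names(seqs), object$classes))
  for (i in seq_along(seqs)) {
    e <- object$entries[[seqs[[i]]]]
    out[i, names(e)] <- e
  }
  out
}

#' Classify one read with the perfect classifier
#'
#' Convenience wrapper handing the per-sequence weight vector to
#' [assign_with_confidence()], with identical thresholding, tie-breaking
#' and rank-aggregation semantics as every other classifier.
#'
#' @param index an `exact_index`.
#' @param sequence one read sequence (must be present in the index).
#' @param confidence threshold in `[0, 1)`.
#' @param seed integer seed for tie-breaks.
#' @return As [assign_with_confidence()].
#' @export
perfect_classify <- function(index, sequence, confidence = 0.7, seed = 1L) {
  p <- predict(index, stats::setNames(sequence, "q"))[1, ]
  assign_with_confidence(p, confidence = confidence, seed = seed)
}
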