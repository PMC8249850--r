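#' Fit a random-forest taxonomy classifier over k-mer bags
#'
#' An ensemble of CART-style trees on k-mer count features. Because tree
#' induction has no prior slot, ecological class weights enter as
#' per-instance training weights proportional to weight(class) divided by
#' the class's training count, which reproduces the prior's effect on the
#' training loss. Tree induction is delegated to \pkg{ranger}; this
#' function fixes the hyperparameter semantics:
#' `max_features = "sqrt"` considers floor(sqrt(p)) features per split,
#' `max_features = "all"` considers all p; `max_depth = NULL` grows every
#' tree until its leaves are pure.
#'
#' @param refdb a [ref_db()] object with at least two classes.
#' @param weights `class_weights` over the reference classes.
#' @param n_estimators number of trees (the study grid used 100 and
#'   1000; default 100).
#' @param max_depth maximum tree depth: 16, 64, or `NULL` for unlimited.
#' @param max_features `"sqrt"` or `"all"`.
#' @param k k-mer length (default 7).
#' @param seed integer seed; fixed seed gives identical fits.
#' @return An object of class `ampli_forest`.
#' @export
fit_forest <- function(refdb, weights = uniform_weights(refdb),
                       n_estimators = 100L, max_depth = NULL,
                       max_features = c("sqrt", "all"), k = 7L, seed = 1L) {
  stopifnot(inherits(refdb, "refdb"))
  max_features <- match.arg(max_features)
  keys <- species_keys(refdb)
  if (length(keys) < 2L) {
    stop("random forest needs at least two classes", call. = FALSE)
  }
  if (!setequal(names(weights), keys)) {
    stop("class weights are not bound to this reference database",
         call. = FALSE)
  }
  x <- kmer_count_matrix(refdb$sequences, k = k)
  y <- factor(vapply(refdb$taxonomy, format_lineage, character(1)),
              levels = keys)
  n_per_class <- table(y)
  case_w <- as.numeric(weights[as.character(y)]) /
    as.numeric(n_per_class[as.character(y)])
  mtry <- if (max_features == "sqrt") max(1L, floor(sqrt(ncol(x)))) else ncol(x)
  rf <- ranger::ranger(
    x = x, y = y, probability = TRUE,
    num.trees = as.integer(n_estimators),
    mtry = mtry,
    min.node.size = 1L,  # nodes are expanded until pure unless max_depth caps growth
    max.depth = if (is.null(max_depth)) NULL else as.integer(max_depth),
    case.weights = case_w,
    seed = as.integer(seed), num.threads = 1L)
  structure(list(
    rf = rf, classes = keys, vocabulary = colnames(x), k = as.integer(k),
    config = list(n_estimators = n_estimators, max_depth = max_depth,
                  max_features = max_features, seed = seed),
    weight_mode = attr(weights, "mode_tag")),
    class = "ampli_forest")
}

#' @export
print.ampli_forest <- function(x, ...) {
  cat(sprintf(
    "<ampli_forest> %d trees, max_depth %s, max_features %s, %d classes, %d-mers, %s weights\n",
    x$config$n_estimators,
    if (is.null(x$config$max_depth)) "unlimited" else x$config$max_depth,
    x$config$max_features, length(x$classes), x$k, x$weight_mode))
  invisible(x)
}

#' Class probabilities from the forest classifier
#'
#' The per-read probability vector is the normalized mean of the trees'
#' leaf class distributions; compose with [assign_with_confidence()] (via
#' [classify_reads()]) for final calls.
#'
#' @param object a fitted `ampli_forest`.
#' @param newdata a [read_set()] or named character vector of sequences.
#' @param ... unused.
#' @return Numeric matrix (reads x classes); rows sum to 1.
#' @export
predict.ampli_forest <- function(object, newdata, ...) {
  if (inherits(newdata, "read_set")) newdata <- newdata$reads
  if (is.null(names(newdata))) {
    names(newdata) <- paste0("read", seq_along(newdata))
  }
  x <- kmer_count_matrix(newdata, k = object$k,
                         vocabulary = object$vocabulary)
  p <- stats::predict(object$rf, data = x, num.threads = 1L)$predictions
  p <- p[, object$classes, drop = FALSE]
  p <- p / rowSums(p)
  rownames(p) <- names(newdata)
  p
}
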