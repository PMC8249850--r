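#' Fit a multinomial naive Bayes taxonomy classifier
#'
#' Multinomial naive Bayes over bags of overlapping k-mers, with class
#' priors set to ecological class weights. For class c and k-mer w the
#' conditional probability is the Laplace-smoothed multinomial estimate
#'
#'   P(w | c) = (n_cw + alpha) / (n_c + alpha * (V + 1))
#'
#' where n_cw is the pooled count of w over the training sequences of c,
#' n_c the total clean k-mer count of c, and V the number of distinct
#' k-mers observed in training. One shared out-of-vocabulary column (the
#' "+ 1") absorbs query k-mers never seen at training, so no posterior is
#' ever exactly zero.
#'
#' @param refdb a [ref_db()] object.
#' @param weights a `class_weights` vector over the reference classes
#'   (defaults to [uniform_weights()]).
#' @param alpha smoothing pseudo-count (> 0, default 0.001).
#' @param k k-mer length (default 7).
#' @return An object of class `ampli_nb` with the log priors, the
#'   per-class log conditional probabilities (classes x V+1 matrix, last
#'   column OOV) and the vocabulary.
#' @export
fit_nb <- function(refdb, weights = uniform_weights(refdb),
                   alpha = 0.001, k = 7L) {
  stopifnot(inherits(refdb, "refdb"))
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  keys <- species_keys(refdb)
  if (!setequal(names(weights), keys)) {
    stop("class weights are not bound to this reference database",
         call. = FALSE)
  }
  seq_class <- vapply(refdb$taxonomy, format_lineage, character(1))
  counts <- kmer_count_matrix(refdb$sequences, k = k)
  vocab <- colnames(counts)
  V <- length(vocab)
  # pooled per-class counts, plus an all-zero OOV column
  cc <- rowsum(counts, group = seq_class)
  cc <- cc[keys, , drop = FALSE]
  zero <- rowSums(cc) == 0
  if (any(zero)) {
    stop("class with zero usable k-mers: ", rownames(cc)[zero][1],
         call. = FALSE)
  }
  cc <- cbind(cc, `<OOV>` = 0)
  log_cond <- log(cc + alpha) - log(rowSums(cc) + alpha * (V + 1))
  structure(list(
    classes = keys,
    log_prior = stats::setNames(log(as.numeric(weights[keys])), keys),
    log_cond = log_cond,
    vocabulary = vocab,
    alpha = alpha, k = as.integer(k),
    weight_mode = attr(weights, "mode_tag")),
    class = "ampli_nb")
}

#' @export
print.ampli_nb <- function(x, ...) {
  cat(sprintf(
    "<ampli_nb> multinomial naive Bayes: %d classes, %d-mer vocabulary of %d, alpha = %g, %s priors\n",
    length(x$classes), x$k, length(x$vocabulary), x$alpha, x$weight_mode))
  invisible(x)
}

#' @method summary ampli_nb
#' @export
summary.ampli_nb <- function(object, ...) {
  cat("Multinomial naive Bayes taxonomy classifier\n")
  cat(sprintf("  classes     : %d\n", length(object$classes)))
  cat(sprintf("  k-mer length: %d (vocabulary %d + OOV)\n",
              object$k, length(object$vocabulary)))
  cat(sprintf("  smoothing   : alpha = %g\n", object$alpha))
  cat(sprintf("  priors      : %s (range %.3g-%.3g)\n", object$weight_mode,
              exp(min(object$log_prior)), exp(max(object$log_prior))))
  invisible(object)
}

#' Posterior class probabilities of the naive Bayes classifier
#'
#' Computed in log space with max-subtraction before exponentiation; an
#' empty bag (read shorter than k or all-ambiguous) yields the prior.
#'
#' @param object a fitted `ampli_nb` model.
#' @param newdata a [read_set()] or named character vector of read
#'   sequences.
#' @param ... unused.
#' @return Numeric matrix (reads x classes); rows sum to 1.
#' @export
predict.ampli_nb <- function(object, newdata, ...) {
  if (inherits(newdata, "read_set")) newdata <- newdata$reads
  if (is.null(names(newdata))) {
    names(newdata) <- paste0("read", seq_along(newdata))
  }
  out <- matrix(NA_real_, nrow = length(newdata),
                ncol = length(object$classes),
                dimnames = list(names(newdata), object$classes))
  for (i in seq_along(newdata)) {
    bag <- kmer_counts(newdata[[i]], k = object$k)
    out[i, ] <- .nb_posterior(object, bag)
  }
  out
}

.nb_posterior <- function(model, bag) {
  known <- names(bag) %in% model$vocabulary
  cnt <- c(as.numeric(bag[known]), sum(bag[!known]))
  cols <- c(names(bag)[known], "<OOV>")
  logp <- model$log_prior + as.numeric(model$log_cond[, cols, drop = FALSE] %*% cnt)
  logp <- logp - max(logp)
  p <- exp(logp)
  p / sum(p)
}
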