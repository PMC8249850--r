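#' Precision, recall and F-measure of taxonomy assignments
#'
#' Micro-averaged over (optionally weighted) reads at the chosen rank.
#' A read counts as a true positive when its assignment reaches the rank
#' and matches the truth's prefix there; as a false positive when it
#' reaches the rank but does not match (truths shallower than the rank
#' cannot be matched, so such assignments are false positives); and as a
#' false negative when the truth has a label at the rank but the
#' assignment is shallower or wrong. A wrong assignment therefore counts
#' in both FP and FN.
#'
#' @param assignments data frame from [classify_reads()] (columns
#'   `read_id`, `lineage`, `confidence`).
#' @param truth named list of true lineages covering every read id.
#' @param rank evaluation rank (default `"species"`).
#' @param read_weights optional named numeric vector of per-read weights
#'   (e.g. community abundances); default 1 per read.
#' @return List with `precision`, `recall`, `f_measure`, the weighted
#'   `tp`/`fp`/`fn` tallies, and `flag` (`"no_assignments"` when
#'   precision is reported as 0 because nothing was assigned at the
#'   rank).
#' @export
evaluate_assignments <- function(assignments, truth, rank = "species",
                                 read_weights = NULL) {
  depth <- rank_depth(rank)
  ids <- assignments$read_id
  miss <- setdiff(ids, names(truth))
  if (length(miss)) {
    stop("truth missing for reads: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  truth_depth <- vapply(truth[ids], length, integer(1))
  if (all(truth_depth < depth)) {
    stop(sprintf("no truth lineage reaches rank '%s'", rank), call. = FALSE)
  }
  w <- if (is.null(read_weights)) {
    stats::setNames(rep(1, length(ids)), ids)
  } else read_weights[ids]
  tp <- fp <- fn <- 0
  for (i in seq_along(ids)) {
    assigned <- parse_lineage(assignments$lineage[i])
    tr <- truth[[ids[i]]]
    deep_enough <- length(assigned) >= depth
    match_at_rank <- deep_enough && length(tr) >= depth &&
      identical(assigned[seq_len(depth)], tr[seq_len(depth)])
    if (match_at_rank) {
      tp <- tp + w[i]
    } else {
      if (deep_enough) fp <- fp + w[i]
      if (length(tr) >= depth) fn <- fn + w[i]
    }
  }
  flag <- NULL
  precision <- if (tp + fp > 0) tp / (tp + fp) else { flag <- "no_assignments"; 0 }
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = unname(precision), recall = unname(recall),
       f_measure = unname(f), tp = unname(tp), fp = unname(fp),
       fn = unname(fn), flag = flag)
}

#' Species-level confusion matrix with an unassigned/truncated category
#'
#' Rows are truth classes, columns predicted classes; assignments that do
#' not reach species depth fall into the `"unassigned/truncated"` column.
#' The matrix is square (the extra category also exists as an empty truth
#' row) so it can be handed to [mcc_score()].
#'
#' @inheritParams evaluate_assignments
#' @return Square integer matrix.
#' @export
confusion_matrix <- function(assignments, truth) {
  ids <- assignments$read_id
  other <- "unassigned/truncated"
  truth_key <- vapply(truth[ids], format_lineage, character(1))
  pred_key <- vapply(seq_along(ids), function(i) {
    l <- parse_lineage(assignments$lineage[i])
    if (length(l) >= 7L) format_lineage(l) else other
  }, character(1))
  classes <- sort(unique(c(truth_key, setdiff(pred_key, other))))
  lv <- c(classes, other)
  as.matrix(table(factor(truth_key, levels = lv),
                  factor(pred_key, levels = lv)))
}

#' Multiclass Matthews correlation coefficient
#'
#' Covariance form over the full confusion matrix:
#' `(c*s - sum(p*t)) / sqrt((s^2 - sum(p^2)) * (s^2 - sum(t^2)))` with
#' `c` the trace, `s` the total, `t` the row (truth) sums and `p` the
#' column (prediction) sums. Degenerate matrices (all mass in one row or
#' column) have zero denominator and are reported as 0 with a
#' `"degenerate"` flag attribute.
#'
#' @param cm square confusion matrix (truth rows x predicted columns).
#' @return MCC in `[-1, 1]`; attribute `flag` set when degenerate.
#' @export
mcc_score <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square", call. = FALSE)
  s <- sum(cm)
  if (s <= 0) stop("empty confusion matrix", call. = FALSE)
  c_tr <- sum(diag(cm))
  t_k <- rowSums(cm)
  p_k <- colSums(cm)
  denom2 <- (s^2 - sum(p_k^2)) * (s^2 - sum(t_k^2))
  if (denom2 <= 0) {
    return(structure(0, flag = "degenerate"))
  }
  (c_tr * s - sum(p_k * t_k)) / sqrt(denom2)
}

.subset_weights <- function(weights, keys) {
  w <- as.numeric(weights[keys])
  names(w) <- keys
  .new_class_weights(w, attr(weights, "mode_tag"))
}

.fit_classifier <- function(spec, refdb, weights, seed) {
  method <- spec$method
  args <- spec[setdiff(names(spec), "method")]
  switch(method,
    nb = do.call(fit_nb, c(list(refdb = refdb, weights = weights), args)),
    rf = do.call(fit_forest, c(list(refdb = refdb, weights = weights,
                                    seed = seed), args)),
    cnn = do.call(fit_cnn, c(list(refdb = refdb, weights = weights,
                                  seed = seed), args)),
    perfect = do.call(build_exact_index,
                      c(list(refdb = refdb, weights = weights), args)),
    stop("unknown classifier method: ", method, call. = FALSE))
}

#' Community-weighted cross-validation of a classifier
#'
#' Unique reference sequences are partitioned into `folds` folds,
#' stratified by class where a class has at least `folds` sequences. Per
#' fold, the classifier is trained on the complement and tested on reads
#' drawn from the held-out sequences according to the community weights
#' (class sampled by weight among held-out classes, then a uniform
#' held-out sequence of that class, trimmed to `read_length`). The truth
#' for a read whose class is absent from training is truncated to its
#' deepest ancestor present among the training lineages before scoring.
#' The perfect classifier is in-sample by its contract: it is indexed on
#' the full reference but evaluated on the same frozen folds.
#'
#' @param refdb a [ref_db()] object.
#' @param weights `class_weights` over the reference classes.
#' @param classifier list describing the classifier: `method` one of
#'   `"nb"`, `"rf"`, `"cnn"`, `"perfect"`, plus arguments passed to the
#'   fit function (e.g. `list(method = "nb", alpha = 0.001)`).
#' @param folds number of folds (default 5).
#' @param confidence assignment threshold (default 0.7).
#' @param reads_per_fold test reads sampled per fold (default 50).
#' @param read_length read trim length in nt (default 150).
#' @param seed integer seed; fold assignment and read draws are
#'   deterministic given the seed.
#' @return List of per-fold results, each with `fold`, `metrics` (a data
#'   frame of precision/recall/F at every rank the truths reach),
#'   `mcc` (species-level), and `n_reads`.
#' @export
crossvalidate <- function(refdb, weights = uniform_weights(refdb),
                          classifier = list(method = "nb"), folds = 5L,
                          confidence = 0.7, reads_per_fold = 50L,
                          read_length = 150L, seed = 1L) {
  stopifnot(inherits(refdb, "refdb"))
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  ids <- names(refdb$sequences)
  cls <- vapply(refdb$taxonomy, format_lineage, character(1))

  fold_of <- with_seed(seed, {
    f <- integer(length(ids)); names(f) <- ids
    for (key in unique(cls)) {
      members <- ids[cls == key]
      if (length(members) >= folds) {
        f[members] <- sample(rep_len(seq_len(folds), length(members)))
      } else {
        f[members] <- sample.int(folds, length(members), replace = TRUE)
      }
    }
    f
  })

  lapply(seq_len(folds), function(fi) {
    test_ids <- ids[fold_of == fi]
    train_ids <- setdiff(ids, test_ids)
    if (length(test_ids) == 0L || length(train_ids) == 0L) {
      stop("empty fold; use fewer folds for this reference", call. = FALSE)
    }
    in_sample <- identical(classifier$method, "perfect")
    fit_ids <- if (in_sample) ids else train_ids
    train_db <- ref_db(refdb$sequences[fit_ids], refdb$taxonomy[fit_ids])
    if (in_sample) {
      train_db <- ref_db(substr(train_db$sequences, 1L, read_length),
                         train_db$taxonomy)
    }
    w_train <- .subset_weights(weights, species_keys(train_db))
    model <- .fit_classifier(classifier, train_db, w_train, seed + fi)

    held_cls <- unique(cls[test_ids])
    w_test <- as.numeric(weights[held_cls]); w_test <- w_test / sum(w_test)
    reads <- with_seed(seed + 1000L + fi, {
      pick_cls <- sample(held_cls, reads_per_fold, replace = TRUE,
                         prob = w_test)
      vapply(pick_cls, function(key) {
        pool <- test_ids[cls[test_ids] == key]
        if (length(pool) == 1L) pool else sample(pool, 1L)
      }, character(1))
    })
    read_seqs <- stats::setNames(
      substr(refdb$sequences[reads], 1L, read_length),
      paste0("f", fi, "r", seq_along(reads)))

    train_prefixes <- unique(unlist(lapply(
      unique(cls[fit_ids]), function(key) {
        l <- parse_lineage(key)
        vapply(seq_along(l), function(d) format_lineage(l[seq_len(d)]),
               character(1))
      })))
    truth <- lapply(reads, function(id) {
      l <- refdb$taxonomy[[id]]
      d <- length(l)
      while (d > 0L && !(format_lineage(l[seq_len(d)]) %in% train_prefixes)) {
        d <- d - 1L
      }
      l[seq_len(d)]
    })
    names(truth) <- names(read_seqs)

    asg <- classify_reads(model, read_seqs, confidence = confidence,
                          seed = seed + 2000L + fi)
    max_depth <- max(vapply(truth, length, integer(1)))
    metrics <- do.call(rbind, lapply(.rank_names[seq_len(max_depth)],
                                     function(r) {
      m <- evaluate_assignments(asg, truth, rank = r)
      data.frame(rank = r, precision = m$precision, recall = m$recall,
                 f_measure = m$f_measure, stringsAsFactors = FALSE)
    }))
    list(fold = fi, metrics = metrics,
         mcc = as.numeric(mcc_score(confusion_matrix(asg, truth))),
         n_reads = length(read_seqs))
  })
}

#' Species-level F-measure per fold from [crossvalidate()] output
#' @param results list of fold results.
#' @param rank rank to extract (default `"species"`).
#' @return Numeric vector, one F-measure per fold.
#' @export
cv_f_measures <- function(results, rank = "species") {
  vapply(results, function(r) {
    row <- r$metrics[r$metrics$rank == rank, ]
    if (nrow(row) == 0L) NA_real_ else row$f_measure
  }, numeric(1))
}

#' Paired classifier comparisons with Hommel-corrected p-values
#'
#' Two-tailed Wilcoxon tests across a family of comparisons: the
#' signed-rank test for paired scores (same test sets) and the rank-sum
#' test where the sample sets differ, followed by Hommel correction for
#' multiple testing across the family.
#'
#' @param comparisons list of comparisons, each a list with elements
#'   `a` and `b` (numeric score vectors), `mode` (`"signed-rank"` or
#'   `"rank-sum"`), and optionally `name`.
#' @param alpha family-wise significance level recorded in the output
#'   (default 0.05).
#' @return Data frame with columns `name`, `mode`, `statistic`, `p`,
#'   `p_adj`, `significant`, `flag` (`"degenerate"` when all paired
#'   differences are zero; such comparisons get p = 1).
#' @export
compare_classifiers <- function(comparisons, alpha = 0.05) {
  stopifnot(is.list(comparisons), length(comparisons) >= 1L)
  rows <- lapply(seq_along(comparisons), function(i) {
    cmp <- comparisons[[i]]
    mode <- match.arg(cmp$mode %||% "signed-rank",
                      c("signed-rank", "rank-sum"))
    a <- cmp$a; b <- cmp$b
    if (length(a) < 2L || length(b) < 2L) {
      stop("each group needs at least 2 observations", call. = FALSE)
    }
    flag <- NA_character_
    if (mode == "signed-rank") {
      if (length(a) != length(b)) {
        stop("paired comparison requires equal lengths", call. = FALSE)
      }
      if (all(a - b == 0)) {
        return(data.frame(name = cmp$name %||% paste0("cmp", i),
                          mode = mode, statistic = NA_real_, p = 1,
                          flag = "degenerate", stringsAsFactors = FALSE))
      }
      ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                                alternative = "two.sided"))
    } else {
      ht <- suppressWarnings(stats::wilcox.test(a, b, paired = FALSE,
                                                alternative = "two.sided"))
    }
    data.frame(name = cmp$name %||% paste0("cmp", i), mode = mode,
               statistic = unname(ht$statistic), p = ht$p.value,
               flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "hommel")
  out$significant <- out$p_adj < alpha
  out[, c("name", "mode", "statistic", "p", "p_adj", "significant", "flag")]
}
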