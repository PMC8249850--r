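#' Taxonomic class weights
#'
#' Class weights are ecological priors: the probability that a read drawn
#' from the target environment belongs to each reference class
#' (species-level lineage). They enter the naive Bayes classifier as the
#' prior, the forest and network classifiers as instance weights, and the
#' exact-match classifier as per-sequence taxon weights. Uniform weights
#' encode the assumption that every species is equally likely to be
#' observed.
#'
#' @name class_weights
NULL

.new_class_weights <- function(w, mode) {
  if (any(w <= 0)) stop("all class weights must be > 0", call. = FALSE)
  w <- w / sum(w)
  structure(w, mode_tag = mode, class = c("class_weights", class(w)))
}

#' @export
print.class_weights <- function(x, ...) {
  cat(sprintf("<class_weights> %d classes, mode '%s'\n",
              length(x), attr(x, "mode_tag")))
  invisible(x)
}

#' Uniform class weights for a reference database
#'
#' Each distinct class lineage gets weight 1/S regardless of how many
#' reference sequences it has.
#'
#' @param refdb a [ref_db()] object with at least one class.
#' @return A `class_weights` vector named by lineage key, summing to 1.
#' @examples
#' \dontrun{uniform_weights(db)}
#' @export
uniform_weights <- function(refdb) {
  stopifnot(inherits(refdb, "refdb"))
  keys <- species_keys(refdb)
  if (length(keys) == 0L) stop("reference database has no classes", call. = FALSE)
  w <- rep(1 / length(keys), length(keys))
  names(w) <- keys
  .new_class_weights(w, "uniform")
}

#' Assemble class weights from observed sample compositions
#'
#' Per-species counts are pooled (summed) across samples; reference
#' classes absent from every sample receive the `floor` weight so that no
#' class has a zero prior; the vector is then renormalized to sum to 1.
#' Species observed in samples but absent from the reference are dropped
#' with a warning.
#'
#' @param samples list of named numeric vectors (lineage key -> count),
#'   one per sample.
#' @param refdb a [ref_db()] object defining the class set.
#' @param floor weight given to unobserved reference classes before
#'   renormalization (default `1e-6`).
#' @return A `class_weights` vector over the reference classes.
#' @export
weights_from_compositions <- function(samples, refdb, floor = 1e-6) {
  stopifnot(inherits(refdb, "refdb"), is.list(samples), length(samples) > 0L)
  keys <- species_keys(refdb)
  pooled <- stats::setNames(numeric(length(keys)), keys)
  unknown <- character(0)
  for (s in samples) {
    if (any(s < 0)) stop("negative count in composition table", call. = FALSE)
    hit <- names(s) %in% keys
    unknown <- union(unknown, names(s)[!hit])
    s <- s[hit]
    pooled[names(s)] <- pooled[names(s)] + s
  }
  if (length(unknown)) {
    warning("dropping species absent from reference: ",
            paste(utils::head(unknown, 5), collapse = "; "), call. = FALSE)
  }
  if (all(pooled == 0)) stop("all composition counts are zero", call. = FALSE)
  pooled <- pooled / sum(pooled)
  zero <- pooled == 0
  if (any(zero)) {
    if (floor <= 0) {
      stop("classes unobserved in samples need a positive `floor`: ",
           paste(utils::head(names(pooled)[zero], 5), collapse = "; "),
           call. = FALSE)
    }
    pooled[zero] <- floor
  }
  .new_class_weights(pooled, "weighted")
}

#' Read per-sample composition tables from TSV
#'
#' Columns: sample id, lineage, count (tab-separated, with or without a
#' header row).
#'
#' @param path TSV path.
#' @return List of named count vectors, one per sample.
#' @export
read_compositions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sample", "lineage", "count"),
                          colClasses = c("character", "character", "character"),
                          skip = 0)
  if (suppressWarnings(is.na(as.numeric(df$count[1])))) df <- df[-1, , drop = FALSE]
  df$count <- as.numeric(df$count)
  lapply(split(df, df$sample), function(d) {
    stats::setNames(d$count, d$lineage)
  })
}

#' Write a class-weight table to TSV
#' @param weights a `class_weights` vector.
#' @param path output path.
#' @export
write_weights <- function(weights, path) {
  utils::write.table(
    data.frame(lineage = names(weights), weight = as.numeric(weights)),
    file = path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a class-weight table written by [write_weights()]
#' @param path TSV path.
#' @param mode mode tag to attach (`"weighted"` or `"uniform"`).
#' @return A `class_weights` vector.
#' @export
read_weights <- function(path, mode = "weighted") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "numeric"))
  .new_class_weights(stats::setNames(df[[2]], df[[1]]), mode)
}
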