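#' K-mer feature extraction
#'
#' Two views of a DNA sequence as overlapping k-mers (default k = 7):
#' an unordered count bag for the naive Bayes and forest classifiers, and
#' an ordered "sentence" of tokens for the embedding/network classifier.
#' Windows containing characters other than A/C/G/T are skipped in the
#' bag and replaced by a reserved out-of-vocabulary token in the
#' sentence, so sentence geometry is always `L - k + 1`.
#'
#' @name kmer_features
NULL

#' Reserved out-of-vocabulary token used in k-mer sentences
#' @export
OOV_TOKEN <- "<OOV>"

.kmer_windows <- function(sequence, k) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < k) return(list(tokens = character(0), valid = logical(0)))
  n <- L - k + 1L
  tokens <- substring(sequence, seq_len(n), seq_len(n) + k - 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  ok <- chars %in% c("A", "C", "G", "T")
  # window i is clean iff all k positions i..i+k-1 are A/C/G/T
  cs <- cumsum(c(0L, ok))
  valid <- (cs[seq_len(n) + k] - cs[seq_len(n)]) == k
  list(tokens = tokens, valid = valid)
}

#' Count overlapping k-mers in a sequence
#'
#' @param sequence DNA string.
#' @param k word length (default 7).
#' @return Named integer vector of counts over clean k-mers (the "bag"),
#'   with attribute `skipped` = number of windows containing non-ACGT
#'   characters. A sequence shorter than `k` yields an empty bag.
#' @examples
#' kmer_counts("ACGTACGT", k = 7)
#' @export
kmer_counts <- function(sequence, k = 7L) {
  if (!is.numeric(k) || k < 1L) stop("k must be >= 1", call. = FALSE)
  w <- .kmer_windows(sequence, as.integer(k))
  bag <- table(w$tokens[w$valid])
  out <- stats::setNames(as.integer(bag), names(bag))
  attr(out, "skipped") <- sum(!w$valid)
  out
}

#' Convert a sequence into an ordered k-mer sentence
#'
#' Token i is the window starting at offset i; windows containing
#' non-ACGT characters become [OOV_TOKEN] so positional geometry is
#' preserved: a clean L nt sequence yields exactly `L - k + 1` tokens
#' (144 tokens for 150 nt at k = 7).
#'
#' @inheritParams kmer_counts
#' @return Character vector of tokens with attribute `k`.
#' @export
kmer_sentence <- function(sequence, k = 7L) {
  if (!is.numeric(k) || k < 1L) stop("k must be >= 1", call. = FALSE)
  k <- as.integer(k)
  if (nchar(sequence) < k) {
    stop(sprintf("sequence of length %d is shorter than k = %d",
                 nchar(sequence), k), call. = FALSE)
  }
  w <- .kmer_windows(sequence, k)
  tokens <- w$tokens
  tokens[!w$valid] <- OOV_TOKEN
  attr(tokens, "k") <- k
  tokens
}

#' K-mer count matrix for a set of sequences
#'
#' Rows are sequences, columns the union vocabulary (or a fixed
#' vocabulary if supplied); entries are raw window counts. Used to build
#' training matrices for the bag-of-words classifiers.
#'
#' @param sequences named character vector of sequences.
#' @param k word length.
#' @param vocabulary optional fixed set of k-mers; k-mers outside it are
#'   dropped.
#' @return Integer matrix (sequences x k-mers).
#' @export
kmer_count_matrix <- function(sequences, k = 7L, vocabulary = NULL) {
  bags <- lapply(sequences, kmer_counts, k = k)
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(unlist(lapply(bags, names), use.names = FALSE)))
  }
  m <- matrix(0L, nrow = length(bags), ncol = length(vocabulary),
              dimnames = list(names(sequences), vocabulary))
  for (i in seq_along(bags)) {
    b <- bags[[i]]
    hit <- names(b) %in% vocabulary
    m[i, names(b)[hit]] <- as.integer(b[hit])
  }
  m
}
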