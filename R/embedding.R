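#' Train a CBOW k-mer embedding
#'
#' Continuous-bag-of-words word2vec over k-mer sentences: each token is
#' predicted from the mean input vector of its context window, trained by
#' stochastic gradient descent with negative sampling (negatives drawn
#' from the unigram distribution raised to 3/4). Vectors default to 300
#' components with a context window of 5 tokens on each side. Training is
#' deterministic under a fixed seed (single worker, fixed visit order).
#'
#' The embedding is trained on reference sentences only, never on query
#' reads, to avoid test leakage.
#'
#' @param sentences list of k-mer sentences from [kmer_sentence()].
#' @param dim embedding dimension (default 300).
#' @param window context half-width in tokens (default 5).
#' @param epochs passes over the corpus (default 5).
#' @param negative negative samples per position (default 5).
#' @param lr initial learning rate, decayed linearly to lr/10.
#' @param seed integer seed.
#' @return Object of class `kmer_embedding`: `vectors` is a
#'   (vocabulary + OOV) x dim matrix with token rownames, including a row
#'   for [OOV_TOKEN].
#' @export
train_embedding <- function(sentences, dim = 300L, window = 5L,
                            epochs = 5L, negative = 5L, lr = 0.025,
                            seed = 1L) {
  if (!is.list(sentences) || length(sentences) == 0L) {
    stop("need at least one sentence", call. = FALSE)
  }
  k <- attr(sentences[[1]], "k") %||% unique(nchar(setdiff(
    unlist(sentences, use.names = FALSE), OOV_TOKEN)))[1]
  toks <- unlist(sentences, use.names = FALSE)
  vocab <- sort(unique(toks))
  vocab <- union(vocab, OOV_TOKEN)
  V <- length(vocab)
  idx <- stats::setNames(seq_len(V), vocab)
  freq <- table(factor(toks, levels = vocab))
  noise <- as.numeric(freq)^0.75
  noise[noise == 0] <- min(noise[noise > 0]) * 1e-3
  noise <- noise / sum(noise)

  sids <- lapply(sentences, function(s) unname(idx[s]))
  positions <- sum(vapply(sids, length, integer(1)))
  total <- positions * epochs

  with_seed(seed, {
    w_in <- matrix(stats::runif(V * dim, -0.5 / dim, 0.5 / dim), V, dim)
    w_out <- matrix(0, V, dim)
    step <- 0L
    for (ep in seq_len(epochs)) {
      for (s in sids) {
        n <- length(s)
        if (n < 2L) { step <- step + n; next }
        for (t in seq_len(n)) {
          step <- step + 1L
          ctx <- s[max(1L, t - window):min(n, t + window)][-min(t, window + 1L)]
          if (length(ctx) == 0L) next
          eta <- lr * max(0.1, 1 - step / total)
          h <- colMeans(w_in[ctx, , drop = FALSE])
          targets <- c(s[t], sample.int(V, negative, replace = TRUE,
                                        prob = noise))
          labels <- c(1, numeric(negative))
          e <- numeric(dim)
          for (j in seq_along(targets)) {
            v <- w_out[targets[j], ]
            g <- (1 / (1 + exp(-sum(h * v))) - labels[j]) * eta
            e <- e + g * v
            w_out[targets[j], ] <- v - g * h
          }
          w_in[ctx, ] <- w_in[ctx, , drop = FALSE] -
            matrix(e / length(ctx), length(ctx), dim, byrow = TRUE)
        }
      }
    }
    rownames(w_in) <- vocab
    structure(list(vectors = w_in, dim = as.integer(dim),
                   window = as.integer(window), k = as.integer(k),
                   corpus = sprintf("%d sentences, %d positions",
                                    length(sentences), positions)),
              class = "kmer_embedding")
  })
}

#' @export
print.kmer_embedding <- function(x, ...) {
  cat(sprintf("<kmer_embedding> CBOW, %d tokens x %d dims, window %d (%s)\n",
              nrow(x$vectors), x$dim, x$window, x$corpus))
  invisible(x)
}

#' Embed a k-mer sentence as a numeric matrix
#'
#' Row i is the embedding vector of token i; tokens absent from the
#' table (and [OOV_TOKEN] itself) map to the OOV row, so a 150 nt read
#' at k = 7 always yields a 144 x dim matrix.
#'
#' @param sentence a [kmer_sentence()].
#' @param table a [train_embedding()] result.
#' @return Numeric matrix (tokens x dim).
#' @export
embed_read <- function(sentence, table) {
  stopifnot(inherits(table, "kmer_embedding"))
  real <- setdiff(unique(sentence), OOV_TOKEN)
  if (length(real) && any(nchar(real) != table$k)) {
    stop(sprintf("sentence tokens have length %d but the embedding was trained on %d-mers",
                 nchar(real[1]), table$k), call. = FALSE)
  }
  tok <- ifelse(sentence %in% rownames(table$vectors), sentence, OOV_TOKEN)
  m <- table$vectors[tok, , drop = FALSE]
  rownames(m) <- NULL
  m
}
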