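#' Fit a one-dimensional convolutional taxonomy classifier
#'
#' Two small architectures over fixed-length reads:
#'
#' * Architecture I: reads are converted to k-mer sentences, embedded
#'   with a CBOW [kmer_embedding] (one row per token), and passed through
#'   a single 1-D convolution (`filters` filters of width `kernel_size`
#'   over the token axis, embedding dimensions as input channels), ReLU,
#'   global max pooling, and a fully connected softmax layer over the
#'   reference classes.
#' * Architecture II: the embedding is replaced by per-nucleotide one-hot
#'   encoding (read_length x 4); the rest of the stack is identical.
#'
#' Training minimizes class-weighted cross-entropy (instance weights
#' proportional to class weight over class count) with the Adam optimizer
#' at its conventional defaults, for a fixed number of epochs. Global max
#' pooling makes the pre-softmax features invariant to where a motif
#' occurs along the read.
#'
#' @param refdb a [ref_db()] object (training sequences are trimmed to
#'   `read_length`; all must be at least that long).
#' @param weights `class_weights` over the reference classes.
#' @param arch `"I"` (embedded k-mer sentences) or `"II"` (one-hot
#'   nucleotides).
#' @param embedding a [train_embedding()] table for architecture I; when
#'   `NULL` one is trained on the reference sentences.
#' @param filters number of convolution filters (study grid 64-4096;
#'   small values suit desk-scale data).
#' @param kernel_size convolution width in tokens (grid 3, 5, 7, 14).
#' @param epochs training epochs (5 or 10 in the study grid).
#' @param batch_size minibatch size (default 128).
#' @param lr Adam learning rate (default 0.001).
#' @param read_length fixed read length in nt (default 150).
#' @param k k-mer length for architecture I (default 7).
#' @param embed_dim embedding dimension when training a table here
#'   (default 300).
#' @param seed integer seed (initialization, shuffling, embedding).
#' @return Object of class `ampli_cnn` with the learned tensors and the
#'   per-epoch mean training loss in `$loss_history`.
#' @export
fit_cnn <- function(refdb, weights = uniform_weights(refdb),
                    arch = c("I", "II"), embedding = NULL,
                    filters = 8L, kernel_size = 3L, epochs = 10L,
                    batch_size = 128L, lr = 0.001, read_length = 150L,
                    k = 7L, embed_dim = 300L, seed = 1L) {
  stopifnot(inherits(refdb, "refdb"))
  arch <- match.arg(arch)
  keys <- species_keys(refdb)
  if (length(keys) < 2L) stop("need at least two classes", call. = FALSE)
  if (!setequal(names(weights), keys)) {
    stop("class weights are not bound to this reference database",
         call. = FALSE)
  }
  if (any(nchar(refdb$sequences) < read_length)) {
    stop("all training sequences must be at least read_length nt",
         call. = FALSE)
  }
  seqs <- substr(refdb$sequences, 1L, read_length)
  y <- match(vapply(refdb$taxonomy, format_lineage, character(1)), keys)

  if (arch == "I" && is.null(embedding)) {
    sentences <- lapply(seqs, kmer_sentence, k = k)
    embedding <- train_embedding(sentences, dim = embed_dim, window = 5L,
                                 seed = seed)
  }
  xs <- lapply(seqs, .cnn_input, arch = arch, embedding = embedding, k = k)

  n_class <- tabulate(y, nbins = length(keys))
  inst_w <- as.numeric(weights[keys])[y] / n_class[y]
  inst_w <- inst_w / mean(inst_w)

  params <- with_seed(seed, .cnn_init(
    channels = ncol(xs[[1]]), filters = as.integer(filters),
    kernel = as.integer(kernel_size), n_class = length(keys)))
  trained <- with_seed(seed + 1L, .cnn_train(
    params, xs, y, inst_w, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), lr = lr))

  structure(list(
    params = trained$params, loss_history = trained$loss,
    classes = keys, arch = arch, embedding = embedding,
    k = as.integer(k), read_length = as.integer(read_length),
    config = list(filters = filters, kernel_size = kernel_size,
                  epochs = epochs, batch_size = batch_size, lr = lr,
                  seed = seed),
    weight_mode = attr(weights, "mode_tag")),
    class = "ampli_cnn")
}

#' @export
print.ampli_cnn <- function(x, ...) {
  cat(sprintf(
    "<ampli_cnn> architecture %s: %d filters x width %d, %d classes, %d epochs (final loss %.4f), %s weights\n",
    x$arch, x$config$filters, x$config$kernel_size, length(x$classes),
    x$config$epochs, utils::tail(x$loss_history, 1), x$weight_mode))
  invisible(x)
}

# input matrix for one read: tokens x channels
.cnn_input <- function(seq, arch, embedding, k) {
  if (arch == "I") {
    embed_read(kmer_sentence(seq, k = k), embedding)
  } else {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    m <- matrix(0, length(chars), 4L,
                dimnames = list(NULL, c("A", "C", "G", "T")))
    hit <- chars %in% colnames(m)
    m[cbind(which(hit), match(chars[hit], colnames(m)))] <- 1
    m
  }
}

.cnn_init <- function(channels, filters, kernel, n_class) {
  fan_in <- kernel * channels
  list(
    W = matrix(stats::rnorm(fan_in * filters, 0, sqrt(2 / fan_in)),
               fan_in, filters),
    b = numeric(filters),
    U = matrix(stats::rnorm(filters * n_class, 0, sqrt(1 / filters)),
               filters, n_class),
    c = numeric(n_class),
    kernel = kernel)
}

# unroll a (tokens x channels) input into conv windows (rows) x (kernel*channels)
.im2col <- function(x, kernel) {
  t_out <- nrow(x) - kernel + 1L
  if (t_out < 1L) {
    stop("read shorter than the convolution kernel", call. = FALSE)
  }
  cols <- lapply(seq_len(kernel), function(j) {
    x[j:(j + t_out - 1L), , drop = FALSE]
  })
  do.call(cbind, cols)
}

# forward pass; returns softmax probabilities and the cached intermediates
.cnn_forward <- function(params, x) {
  xc <- .im2col(x, params$kernel)
  z <- sweep(xc %*% params$W, 2L, params$b, "+")
  a <- pmax(z, 0)
  arg <- max.col(t(a), ties.method = "first")
  g <- a[cbind(arg, seq_len(ncol(a)))]
  logits <- as.numeric(g %*% params$U + params$c)
  logits <- logits - max(logits)
  p <- exp(logits); p <- p / sum(p)
  list(p = p, g = g, arg = arg, z = z, xc = xc)
}

.cnn_train <- function(params, xs, y, inst_w, epochs, batch_size, lr) {
  n <- length(xs)
  shapes <- lapply(params[c("W", "b", "U", "c")], function(p) p * 0)
  m <- shapes; v <- shapes
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0L
  loss_hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      batch <- ord[start:min(start + batch_size - 1L, n)]
      grads <- lapply(shapes, identity)
      for (i in batch) {
        fw <- .cnn_forward(params, xs[[i]])
        w_i <- inst_w[i]
        ep_loss <- ep_loss - w_i * log(max(fw$p[y[i]], 1e-12))
        dlog <- fw$p * w_i
        dlog[y[i]] <- dlog[y[i]] - w_i
        grads$U <- grads$U + outer(fw$g, dlog)
        grads$c <- grads$c + dlog
        dg <- as.numeric(params$U %*% dlog)
        active <- fw$z[cbind(fw$arg, seq_along(dg))] > 0
        dz <- ifelse(active, dg, 0)
        grads$b <- grads$b + dz
        grads$W <- grads$W + t(fw$xc[fw$arg, , drop = FALSE] * dz)
      }
      t_step <- t_step + 1L
      for (nm in names(shapes)) {
        g <- grads[[nm]] / length(batch)
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g^2
        mhat <- m[[nm]] / (1 - beta1^t_step)
        vhat <- v[[nm]] / (1 - beta2^t_step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    loss_hist[ep] <- ep_loss / n
  }
  list(params = params, loss = loss_hist)
}

#' Class probabilities from the convolutional classifier
#'
#' Softmax outputs of the trained network, deterministic under fixed
#' weights. Reads must be at least `read_length` nt; longer reads are
#' trimmed to the training geometry.
#'
#' @param object a fitted `ampli_cnn`.
#' @param newdata a [read_set()] or named character vector of sequences.
#' @param ... unused.
#' @return Numeric matrix (reads x classes); rows sum to 1.
#' @export
predict.ampli_cnn <- function(object, newdata, ...) {
  if (inherits(newdata, "read_set")) newdata <- newdata$reads
  if (is.null(names(newdata))) {
    names(newdata) <- paste0("read", seq_along(newdata))
  }
  if (any(nchar(newdata) < object$read_length)) {
    stop("reads shorter than the network's fixed read length",
         call. = FALSE)
  }
  seqs <- substr(newdata, 1L, object$read_length)
  out <- matrix(NA_real_, length(seqs), length(object$classes),
                dimnames = list(names(newdata), object$classes))
  for (i in seq_along(seqs)) {
    x <- .cnn_input(seqs[[i]], object$arch, object$embedding, object$k)
    out[i, ] <- .cnn_forward(object$params, x)$p
  }
  out
}
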