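# Shared in-code fixtures for the test suite.

# full 7-rank lineage with defaults, deepest ranks first in the arg list
mk_lineage <- function(s, g = "G1", f = "F1", o = "O1", cl = "C1",
                       p = "P1", k = "K1") {
  c(paste0("k__", k), paste0("p__", p), paste0("c__", cl),
    paste0("o__", o), paste0("f__", f), paste0("g__", g),
    paste0("s__", s))
}

lin_key <- function(...) format_lineage(mk_lineage(...))

# tiny hand-set reference: two genera in one family, sequences chosen so
# k = 3 bags are easy to enumerate by hand
toy_refdb <- function() {
  seqs <- c(r1 = "AAAACCCC", r2 = "AAAAGGGG",
            r3 = "TTTTGGGG", r4 = "TTTTCCCC")
  tax <- list(r1 = mk_lineage("a", g = "G1"),
              r2 = mk_lineage("b", g = "G1"),
              r3 = mk_lineage("c", g = "G2"),
              r4 = mk_lineage("d", g = "G2"))
  ref_db(seqs, tax)
}

# random 150 nt sequence with a motif planted at a given position
planted_read <- function(motif, pos, len = 150) {
  bg <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = "")
  paste0(substr(bg, 1, pos - 1), motif,
         substr(bg, pos + nchar(motif), len))
}

# two-class motif toy for the network classifier: disjoint planted motifs
motif_refdb <- function(n_per_class = 20, seed = 1) {
  withr::with_seed(seed, {
    a <- vapply(seq_len(n_per_class), function(i) {
      planted_read("ACGTACGTACGT", sample(1:130, 1))
    }, character(1))
    b <- vapply(seq_len(n_per_class), function(i) {
      planted_read("TTGCATTGCATT", sample(1:130, 1))
    }, character(1))
    seqs <- c(a, b)
    names(seqs) <- paste0("r", seq_along(seqs))
    tax <- c(lapply(seq_len(n_per_class), function(i) mk_lineage("a")),
             lapply(seq_len(n_per_class), function(i) mk_lineage("b")))
    names(tax) <- names(seqs)
    ref_db(seqs, tax)
  })
}

# toy benchmark regime for the network classifier (declared config:
# small batches and a larger step size suit tens-of-reads corpora)
cnn_toy_args <- function() {
  list(filters = 8L, kernel_size = 3L, epochs = 10L, batch_size = 8L,
       lr = 0.05, embed_dim = 16L)
}
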