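# Independent brute-force Bayes oracle in exact integer arithmetic.
# With an integer pseudo-count, every class score is a ratio of integer
# products; doubles represent these exactly for the tiny fixtures used
# (all intermediates < 2^53), so the comparison is exact up to one final
# division per class.
brute_bayes <- function(class_counts, prior, query_counts, alpha) {
  vocab <- sort(unique(unlist(lapply(class_counts, names))))
  V <- length(vocab) + 1L  # shared OOV column
  scores <- vapply(names(class_counts), function(cl) {
    cc <- class_counts[[cl]]
    num <- 1; den <- 1
    total <- sum(cc)
    for (w in names(query_counts)) {
      n_cw <- if (w %in% vocab && w %in% names(cc)) cc[[w]] else 0
      if (!(w %in% vocab)) n_cw <- 0  # OOV column has zero counts
      for (r in seq_len(query_counts[[w]])) {
        num <- num * (n_cw + alpha)
        den <- den * (total + alpha * V)
      }
    }
    prior[[cl]] * num / den
  }, numeric(1))
  scores / sum(scores)
}

nb_toy_db <- function() {
  # k = 3 bags: r1 -> AAA,AAC,ACC,CCC ; r2 -> AAA,AAG,AGG,GGG ;
  # r3 -> TTT,TTG,TGG,GGG
  ref_db(c(r1 = "AAAACCC", r2 = "AAAAGGG", r3 = "TTTTGGG"),
         list(r1 = mk_lineage("a"), r2 = mk_lineage("b"),
              r3 = mk_lineage("c", g = "G2")))
}

test_that("a single-class model classifies everything to it with posterior 1", {
  db <- ref_db(c(r1 = "AAAACCCC"), list(r1 = mk_lineage("a")))
  m <- fit_nb(db, k = 3)
  p <- predict(m, c(q = "AAAA"))
  expect_equal(as.numeric(p), 1)
})

test_that("disjoint k-mer classes are recovered and identical classes return the prior", {
  db <- toy_refdb()
  m <- fit_nb(db, k = 3)
  p <- predict(m, c(q = "AAAACC"))  # only class-a k-mers
  expect_equal(colnames(p)[which.max(p)], lin_key("a"))

  # identical training sequences: posterior equals prior
  db2 <- ref_db(c(r1 = "AAAACCCC", r2 = "AAAACCCC"),
                list(r1 = mk_lineage("a"), r2 = mk_lineage("b")))
  w <- ampliclass:::.new_class_weights(
    setNames(c(0.9, 0.1), c(lin_key("a"), lin_key("b"))), "weighted")
  m2 <- fit_nb(db2, w, k = 3)
  p2 <- predict(m2, c(q = "AAAACC"))
  expect_equal(as.numeric(p2[, lin_key("a")]), 0.9, tolerance = 1e-9)
  expect_equal(as.numeric(p2[, lin_key("b")]), 0.1, tolerance = 1e-9)
})

test_that("per-class conditional probabilities sum to 1 and empty bags return the prior", {
  db <- nb_toy_db()
  m <- fit_nb(db, k = 3, alpha = 0.001)
  linear <- exp(m$log_cond)
  expect_equal(unname(rowSums(linear)), rep(1, 3), tolerance = 1e-9)
  expect_equal(sum(exp(m$log_prior)), 1, tolerance = 1e-9)

  p <- predict(m, c(q = "AC"))  # shorter than k: no evidence
  expect_equal(as.numeric(p), as.numeric(exp(m$log_prior)), tolerance = 1e-12)
})

test_that("posteriors match the exact brute-force Bayes oracle", {
  db <- nb_toy_db()
  class_counts <- list(
    c(AAA = 2, AAC = 1, ACC = 1, CCC = 1),
    c(AAA = 2, AAG = 1, AGG = 1, GGG = 1),
    c(TTT = 2, TTG = 1, TGG = 1, GGG = 1))
  names(class_counts) <- c(lin_key("a"), lin_key("b"), lin_key("c", g = "G2"))
  queries <- list(c(q = "AAAAC"), c(q = "GGGTTT"), c(q = "AAACCCGGG"),
                  c(q = "ACGTACG"))
  for (alpha in c(1, 2)) {
    m <- fit_nb(db, alpha = alpha, k = 3)
    prior <- setNames(rep(1 / 3, 3), names(class_counts))
    for (q in queries) {
      got <- predict(m, q)[1, ]
      bag <- kmer_counts(q[[1]], k = 3)
      want <- brute_bayes(class_counts, prior, as.list(bag), alpha)
      expect_equal(got[names(want)], want, tolerance = 1e-9)
    }
  }
})

test_that("doubling bag counts sharpens the posterior toward the same argmax", {
  db <- nb_toy_db()
  m <- fit_nb(db, k = 3)
  p1 <- predict(m, c(q = "AAAAC"))[1, ]
  p2 <- predict(m, c(q = "AAAACAAAAC"))[1, ]  # roughly doubled evidence
  expect_equal(which.max(p1), which.max(p2))
  expect_gt(max(p2), max(p1))
})

test_that("posterior is invariant to relabeling symmetric classes", {
  db <- ref_db(c(r1 = "AAAACCCC", r2 = "TTTTGGGG"),
               list(r1 = mk_lineage("a"), r2 = mk_lineage("b")))
  m <- fit_nb(db, k = 3)
  pa <- predict(m, c(q = "AAAA"))[1, lin_key("a")]
  db_swapped <- ref_db(c(r1 = "TTTTGGGG", r2 = "AAAACCCC"),
                       list(r1 = mk_lineage("a"), r2 = mk_lineage("b")))
  ms <- fit_nb(db_swapped, k = 3)
  pb <- predict(ms, c(q = "AAAA"))[1, lin_key("b")]
  expect_equal(unname(pa), unname(pb), tolerance = 1e-12)
})

test_that("fit validation: alpha, weight binding, zero-k-mer classes", {
  db <- toy_refdb()
  expect_error(fit_nb(db, alpha = 0), "alpha")
  w_bad <- ampliclass:::.new_class_weights(
    setNames(1, lin_key("other")), "weighted")
  expect_error(fit_nb(db, w_bad), "not bound")
  db_short <- ref_db(c(r1 = "AAAACCCC", r2 = "AC"),
                     list(r1 = mk_lineage("a"), r2 = mk_lineage("b")))
  expect_error(fit_nb(db_short, k = 3), "zero usable")
})
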