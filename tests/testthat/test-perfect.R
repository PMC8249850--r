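shared_db <- function() {
  # r1/r2 share one sequence across two species of one genus
  ref_db(c(r1 = "AAAACCCCGGGG", r2 = "AAAACCCCGGGG", r3 = "TTTTGGGGAAAA"),
         list(r1 = mk_lineage("a", g = "G1"),
              r2 = mk_lineage("b", g = "G1"),
              r3 = mk_lineage("c", g = "G2")))
}

test_that("unique sequences index as singletons with weight 1", {
  db <- toy_refdb()
  idx <- build_exact_index(db)
  expect_true(all(vapply(idx$entries, length, integer(1)) == 1L))
  expect_true(all(vapply(idx$entries, sum, numeric(1)) == 1))
  rep <- ambiguity_report(idx)
  expect_equal(sum(rep$n_classes > 1), 0L)
})

test_that("shared sequences get per-sequence renormalized taxon weights", {
  db <- shared_db()
  idx_u <- build_exact_index(db, uniform_weights(db))
  e <- idx_u$entries[["AAAACCCCGGGG"]]
  expect_equal(sort(unname(e)), c(0.5, 0.5))

  w <- ampliclass:::.new_class_weights(
    setNames(c(0.09, 0.01, 0.90),
             c(lin_key("a", g = "G1"), lin_key("b", g = "G1"),
               lin_key("c", g = "G2"))), "weighted")
  idx_w <- build_exact_index(db, w)
  e2 <- idx_w$entries[["AAAACCCCGGGG"]]
  expect_equal(unname(e2[lin_key("a", g = "G1")]), 0.9, tolerance = 1e-12)
  expect_equal(unname(e2[lin_key("b", g = "G1")]), 0.1, tolerance = 1e-12)
  expect_equal(sum(e2), 1, tolerance = 1e-9)
})

test_that("classification follows the thresholded, rank-aggregating procedure", {
  db <- shared_db()
  # unique sequence: its own species at achieved confidence 1
  a <- perfect_classify(build_exact_index(db), "TTTTGGGGAAAA", 0.7)
  expect_equal(a$lineage, mk_lineage("c", g = "G2"))
  expect_equal(a$confidence, 1)

  # 0.5/0.5 within one genus at confidence 0.7: the genus, achieved 1.0
  b <- perfect_classify(build_exact_index(db), "AAAACCCCGGGG", 0.7)
  expect_equal(b$lineage, mk_lineage("a", g = "G1")[1:6])
  expect_equal(b$confidence, 1)

  # 0.9/0.1: the dominant species clears 0.7 on its own
  w <- ampliclass:::.new_class_weights(
    setNames(c(0.09, 0.01, 0.90),
             c(lin_key("a", g = "G1"), lin_key("b", g = "G1"),
               lin_key("c", g = "G2"))), "weighted")
  d <- perfect_classify(build_exact_index(db, w), "AAAACCCCGGGG", 0.7)
  expect_equal(d$lineage, mk_lineage("a", g = "G1"))
  expect_equal(d$confidence, 0.9, tolerance = 1e-12)
})

test_that("out-of-index queries violate the in-sample contract loudly", {
  idx <- build_exact_index(toy_refdb())
  expect_error(predict(idx, c(q = "GGGGGGGG")), "in-sample")
})

test_that("lookup is case-folded exact matching", {
  idx <- build_exact_index(toy_refdb())
  a <- perfect_classify(idx, "aaaacccc", 0.5)
  expect_equal(a$lineage, mk_lineage("a"))
})

test_that("with unique references the in-sample F-measure is 1 at any confidence", {
  db <- toy_refdb()
  for (mode in c("uniform", "weighted")) {
    w <- if (mode == "uniform") uniform_weights(db) else
      ampliclass:::.new_class_weights(
        setNames(c(0.4, 0.3, 0.2, 0.1), species_keys(db)), "weighted")
    idx <- build_exact_index(db, w)
    asg <- classify_reads(idx, db$sequences, confidence = 0.95, seed = 1)
    names(db$taxonomy) <- names(db$sequences)
    truth <- db$taxonomy
    names(truth) <- asg$read_id
    expect_equal(evaluate_assignments(asg, truth)$f_measure, 1)
  }
})

test_that("community-matched weights never underperform uniform weights in expectation", {
  deltas <- vapply(1:5, function(s) {
    cfg <- synth_config(branching = c(1L, 2L, 1L, 1L, 2L, 3L, 2L),
                        p_share = 0.5, concentration = 0.1,
                        n_samples = 3L, reads_per_sample = 150L,
                        error_rate = 0, read_length = 250L, seed = s)
    db <- simulate_reference(cfg)
    comms <- simulate_communities(db, cfg)
    reads <- simulate_reads(db, comms, cfg)
    w_true <- weights_from_compositions(comms, db)
    f_of <- function(w) {
      idx <- build_exact_index(db, w)
      asg <- classify_reads(idx, reads, confidence = 0.5, seed = s)
      truth <- reads$truth
      evaluate_assignments(asg, truth)$f_measure
    }
    f_of(w_true) - f_of(uniform_weights(db))
  }, numeric(1))
  expect_gte(mean(deltas), 0)
})
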