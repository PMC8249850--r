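mk_asg <- function(ids, lineages, conf = 0.9) {
  data.frame(read_id = ids,
             lineage = vapply(lineages, format_lineage, character(1)),
             confidence = conf, stringsAsFactors = FALSE)
}

test_that("all-correct and all-unassigned tallies hit the boundary values", {
  truth <- list(r1 = mk_lineage("a"), r2 = mk_lineage("b"))
  perfect <- mk_asg(c("r1", "r2"), list(mk_lineage("a"), mk_lineage("b")))
  m <- evaluate_assignments(perfect, truth)
  expect_equal(c(m$precision, m$recall, m$f_measure), c(1, 1, 1))

  none <- mk_asg(c("r1", "r2"), list(character(0), character(0)), conf = 0)
  m0 <- evaluate_assignments(none, truth)
  expect_equal(m0$recall, 0)
  expect_equal(m0$precision, 0)
  expect_equal(m0$flag, "no_assignments")
})

test_that("the mixed hand tally reproduces P = 0.75, R = 0.6, F ~ 0.667", {
  truth <- setNames(lapply(1:10, function(i) mk_lineage(paste0("t", i))),
                    paste0("r", 1:10))
  lineages <- c(
    lapply(1:6, function(i) mk_lineage(paste0("t", i))),      # 6 correct
    lapply(7:8, function(i) mk_lineage("wrong")),             # 2 wrong species
    lapply(9:10, function(i) mk_lineage("t9")[1:6]))          # 2 truncated
  asg <- mk_asg(paste0("r", 1:10), lineages)
  m <- evaluate_assignments(asg, truth, rank = "species")
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f_measure, 2 * 0.75 * 0.6 / 1.35, tolerance = 1e-12)
})

test_that("uniform read weights equal the unweighted tally; weights rescale it", {
  truth <- list(r1 = mk_lineage("a"), r2 = mk_lineage("b"),
                r3 = mk_lineage("c"))
  asg <- mk_asg(c("r1", "r2", "r3"),
                list(mk_lineage("a"), mk_lineage("x"), mk_lineage("c")))
  plain <- evaluate_assignments(asg, truth)
  unif <- evaluate_assignments(asg, truth,
                               read_weights = setNames(rep(2, 3),
                                                       c("r1", "r2", "r3")))
  expect_equal(plain$precision, unif$precision)
  expect_equal(plain$recall, unif$recall)

  skew <- evaluate_assignments(asg, truth,
                               read_weights = setNames(c(8, 1, 1),
                                                       c("r1", "r2", "r3")))
  expect_equal(skew$recall, 9 / 10)
})

test_that("rank deeper than any truth label errors; shallower ranks score prefixes", {
  truth <- list(r1 = mk_lineage("a")[1:6])
  asg <- mk_asg("r1", list(mk_lineage("a")[1:6]))
  expect_error(evaluate_assignments(asg, truth, rank = "species"),
               "species")
  expect_equal(evaluate_assignments(asg, truth, rank = "genus")$f_measure, 1)
})

test_that("multiclass MCC equals the covariance-form oracle on random matrices", {
  mcc_oracle <- function(cm) {
    s <- sum(cm); c0 <- sum(diag(cm))
    t <- rowSums(cm); p <- colSums(cm)
    num <- c0 * s - sum(p * t)
    den <- sqrt(s^2 - sum(p^2)) * sqrt(s^2 - sum(t^2))
    if (den == 0) 0 else num / den
  }
  withr::with_seed(14, {
    for (i in 1:100) {
      n <- sample(2:5, 1)
      cm <- matrix(rpois(n * n, lambda = 3), n, n)
      if (sum(cm) == 0) cm[1, 1] <- 1
      expect_equal(as.numeric(mcc_score(cm)), mcc_oracle(cm),
                   tolerance = 1e-12)
    }
  })
})

test_that("MCC is 1 for diagonal matrices, ~0 for independence, flagged when degenerate", {
  expect_equal(as.numeric(mcc_score(diag(c(3, 5, 2)))), 1)
  u <- matrix(4, 3, 3)
  expect_equal(as.numeric(mcc_score(u)), 0)
  one_cell <- matrix(0, 2, 2); one_cell[1, 1] <- 7
  r <- mcc_score(one_cell)
  expect_equal(as.numeric(r), 0)
  expect_equal(attr(r, "flag"), "degenerate")
})

test_that("the confusion matrix is square with an unassigned/truncated category", {
  truth <- list(r1 = mk_lineage("a"), r2 = mk_lineage("b"),
                r3 = mk_lineage("c"))
  asg <- mk_asg(c("r1", "r2", "r3"),
                list(mk_lineage("a"), mk_lineage("b")[1:4], character(0)))
  cm <- confusion_matrix(asg, truth)
  expect_equal(nrow(cm), ncol(cm))
  expect_true("unassigned/truncated" %in% colnames(cm))
  expect_equal(unname(cm[lin_key("a"), lin_key("a")]), 1L)
  expect_equal(unname(cm[lin_key("b"), "unassigned/truncated"]), 1L)
})

test_that("signed-rank p-values match exact enumeration over sign assignments", {
  # oracle: enumerate all 2^n sign assignments of the ranked |differences|
  exact_signed_rank_p <- function(x, y) {
    d <- x - y
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- expand.grid(rep(list(c(0, 1)), n))
    w_all <- as.matrix(signs) %*% r
    mu <- n * (n + 1) / 4
    if (w_obs > mu) {
      p <- 2 * mean(w_all >= w_obs)
    } else {
      p <- 2 * mean(w_all <= w_obs)
    }
    min(p, 1)
  }
  withr::with_seed(77, {
    for (i in 1:5) {
      n <- sample(6:10, 1)
      x <- round(runif(n), 3)
      y <- round(x + rnorm(n, sd = 0.2), 4)  # distinct |d|, no zeros w.h.p.
      if (any(x == y) || anyDuplicated(abs(x - y))) next
      res <- compare_classifiers(list(list(a = x, b = y,
                                           mode = "signed-rank")))
      expect_equal(res$p, exact_signed_rank_p(x, y), tolerance = 1e-12)
    }
  })
})

test_that("Hommel adjustment is the identity for one comparison and tempers many", {
  x <- c(0.1, 0.2, 0.3, 0.45, 0.9)
  y <- c(0.15, 0.35, 0.33, 0.5, 0.95)
  one <- compare_classifiers(list(list(a = x, b = y, mode = "signed-rank")))
  expect_equal(one$p_adj, one$p)

  fam <- compare_classifiers(list(
    list(a = x, b = y, mode = "signed-rank", name = "A"),
    list(a = x, b = rev(y), mode = "rank-sum", name = "B"),
    list(a = y, b = x, mode = "signed-rank", name = "C")))
  expect_equal(fam$p_adj, stats::p.adjust(fam$p, method = "hommel"))
  expect_true(all(fam$p_adj >= fam$p))
})

test_that("identical paired samples are a flagged degenerate comparison with p = 1", {
  x <- c(0.5, 0.6, 0.7)
  res <- compare_classifiers(list(list(a = x, b = x, mode = "signed-rank")))
  expect_equal(res$p, 1)
  expect_equal(res$flag, "degenerate")
  expect_error(compare_classifiers(list(list(a = 1, b = 2))), "at least 2")
  expect_error(compare_classifiers(list(list(a = 1:3, b = 1:4,
                                             mode = "signed-rank"))),
               "equal lengths")
})
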