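test_that("tenfold partitions are stratified with near-equal fold sizes", {
  y <- rep(c(1, 2), each = 50)
  part <- make_partition(y, scheme = "tenfold", seed = 4)
  expect_equal(part$n_folds, 10L)
  sizes <- table(part$fold_of)
  expect_true(all(sizes == 10))
  per_class <- table(part$fold_of, y)
  expect_true(all(per_class == 5))      # 5 + 5 per fold
  ## determinism
  expect_identical(part, make_partition(y, scheme = "tenfold", seed = 4))
  expect_false(identical(part$fold_of,
                         make_partition(y, scheme = "tenfold", seed = 5)$fold_of))
})

test_that("unbalanced tenfold fold sizes differ by at most one", {
  set.seed(6)
  y <- c(rep(1, 47), rep(2, 38))
  part <- make_partition(y, scheme = "tenfold", seed = 1)
  sizes <- tabulate(part$fold_of, 10)
  expect_lte(diff(range(sizes)), 1L)
  per_class <- table(factor(part$fold_of, 1:10), y)
  expect_true(all(apply(per_class, 2, function(s) diff(range(s))) <= 1))
})

test_that("leave-one-record-out gives one fold per record and never splits one", {
  set.seed(7)
  for (i in 1:5) {
    n_rec <- sample(3:12, 1)
    rec_ids <- paste0("r", sample(seq_len(n_rec), 60, replace = TRUE))
    y <- sample(1:2, 60, replace = TRUE)
    part <- make_partition(y, rec_ids, scheme = "loro")
    expect_equal(part$n_folds, length(unique(rec_ids)))
    ## group integrity: each record id maps to exactly one fold
    expect_true(all(tapply(part$fold_of, rec_ids,
                           function(f) length(unique(f))) == 1))
  }
  expect_error(make_partition(1:4, rep("r1", 4), scheme = "loro"),
               "at least 2 distinct records")
  expect_error(make_partition(1:4, scheme = "loro"), "requires record ids")
})

test_that("mode fusion takes the per-sample majority of three branches", {
  expect_equal(fuse_mode(c(1, 1), c(1, 2), c(2, 2)), c(1, 2))
  t1 <- c(1, 2, 1, 2)
  expect_equal(fuse_mode(t1, t1, t1), t1)
  ## one perfect branch, two wrong on disjoint single samples
  truth <- c(1, 1, 2, 2)
  t2 <- c(2, 1, 2, 2)   # wrong on sample 1
  t3 <- c(1, 1, 1, 2)   # wrong on sample 3
  expect_equal(fuse_mode(truth, t2, t3), truth)
  expect_error(fuse_mode(c(1, 2), c(1, 2), c(1)), "dimension error")
})

test_that("greedy_final dominates every branch and breaks ties in order", {
  truth <- c(1, 1, 2, 2, 1)
  t1 <- c(1, 1, 2, 2, 2)
  t2 <- c(2, 1, 2, 2, 2)
  t3 <- c(1, 2, 2, 2, 2)
  vot <- fuse_mode(t1, t2, t3)
  g <- greedy_final(t1, t2, t3, vot, truth)
  expect_gte(max(g$accuracies), g$accuracies["t1"])
  expect_equal(100 * mean(g$predictions == truth), max(g$accuracies))
  ## all equal: t1 wins the tie
  g2 <- greedy_final(t1, t1, t1, t1, truth)
  expect_equal(g2$which, "t1")
  ## vot strictly best
  g3 <- greedy_final(t2, t2, t2, truth, truth)
  expect_equal(g3$which, "vot")
})

test_that("metrics follow the confusion-count formulas in percent", {
  perfect <- compute_metrics(rep(c(1, 2), c(10, 5)), rep(c(1, 2), c(10, 5)),
                             positive_class = 1)
  expect_equal(perfect$tp, 10); expect_equal(perfect$tn, 5)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$geometric_mean, 100)

  ## geometric-mean identity on the percent scale
  set.seed(8)
  for (i in 1:20) {
    y <- sample(1:2, 50, replace = TRUE)
    if (length(unique(y)) < 2) next
    p <- sample(1:2, 50, replace = TRUE)
    m <- compute_metrics(p, y, positive_class = 1)
    expect_equal(m$geometric_mean^2, m$sensitivity * m$specificity,
                 tolerance = 1e-9)
    expect_equal(m$tp + m$fp + m$tn + m$fn, 50)
  }
  expect_error(compute_metrics(rep(1, 5), rep(1, 5)), "both classes")
})

test_that("the pipeline report is internally consistent on a small dataset", {
  recs <- small_dataset(seed = 71)
  rep <- run_pipeline(recs, run_config(cv_scheme = "loro", inca_start = 14,
                                       inca_stop = 30, seed = 71))
  expect_s3_class(rep, "soxfe_report")
  expect_equal(rep$n_segments, 24L)
  expect_length(rep$vot, 24L)
  ## greedy dominance of the final outcome
  accs <- vapply(rep$metrics, function(m) m$accuracy, 0)
  expect_equal(unname(accs["fot"]), max(accs))
  ## branch DLob strings have two symbols per selected feature
  for (nm in names(rep$branches)) {
    b <- rep$branches[[nm]]
    expect_length(b$dlob$string, 2L * b$selection$n_selected)
  }
  ## every candidate pool holds 238 outcomes
  expect_true(all(vapply(rep$branches,
                         function(b) length(b$outcomes$accuracies), 0L) == 238L))
})
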