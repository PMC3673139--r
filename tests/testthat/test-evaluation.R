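test_that("confusion matrices count actual x predicted pairs", {
  actual <- rep(activity_labels(), each = 30)
  cm <- confusion_matrix(actual, actual)
  expect_equal(unname(diag(cm)), rep(30L, 7))
  expect_equal(sum(cm), 210L)

  empty <- confusion_matrix(character(0), character(0))
  expect_equal(sum(empty), 0L)
  expect_equal(dim(empty), c(7L, 7L))

  expect_error(confusion_matrix("A1", "A9", labels = activity_labels()),
               "unknown label")
  expect_error(confusion_matrix(c("A1", "A2"), "A1"), "equal length")
})

test_that("reference tables rebuild from their label pairs and score as printed", {
  t3 <- reference_confusion("soccer_blackbox")
  pairs_actual <- rep(rownames(t3), times = rowSums(t3))
  pairs_pred <- unlist(lapply(seq_len(7), function(i)
    rep(colnames(t3), times = t3[i, ])))
  expect_equal(unclass(confusion_matrix(pairs_actual, pairs_pred)),
               unclass(t3))

  expect_equal(round(macro_f_measure(t3), 3), 0.627)
  expect_equal(round(macro_f_measure(reference_confusion("hockey_blackbox")), 3),
               0.659)
  expect_equal(round(macro_f_measure(reference_confusion("hockey_tuned")), 3),
               0.823)
  # the tuned soccer table is defective as printed: row A1 sums to 28
  t6 <- reference_confusion("soccer_tuned")
  expect_true(attr(t6, "defective"))
  expect_equal(unname(rowSums(t6)["A1"]), 28L)
})

test_that("per-class precision and recall match hand-computed baseline values", {
  t3 <- reference_confusion("soccer_blackbox")
  pc <- precision_recall_f1(t3)
  a4 <- pc[pc$label == "A4", ]
  expect_equal(a4$precision, 1)
  expect_equal(a4$recall, 1)
  expect_equal(a4$f1, 1)
  a1 <- pc[pc$label == "A1", ]
  expect_equal(a1$recall, 1)            # 30/30
  expect_equal(a1$precision, 30 / 40)   # column sum of A1 is 40

  # class with no predictions and no instances scores (0, 0, 0)
  cm <- confusion_matrix(c("A1", "A2"), c("A1", "A2"),
                         labels = activity_labels())
  pc0 <- precision_recall_f1(cm)
  expect_equal(unlist(pc0[pc0$label == "A7", -1], use.names = FALSE),
               c(0, 0, 0))
  expect_equal(macro_f_measure(diag(5) * 10), 1)
})

test_that("probability MAE matches its closed forms", {
  labels <- rep(c("A1", "A2"), each = 7)
  onehot <- diag(7)[rep(1:2, each = 7), ]
  colnames(onehot) <- activity_labels()
  expect_equal(mean_absolute_error(onehot, labels), 0)

  uniform <- matrix(1 / 7, 14, 7, dimnames = list(NULL, activity_labels()))
  expect_equal(mean_absolute_error(uniform, labels), 12 / 49,
               tolerance = 1e-12)

  wrong <- diag(7)[rep(3, 14), ]
  colnames(wrong) <- activity_labels()
  expect_equal(mean_absolute_error(wrong, labels), 2 / 7, tolerance = 1e-12)

  bad <- uniform
  bad[1, 1] <- 0.5
  expect_error(mean_absolute_error(bad, labels), "sum to 1")
})

test_that("repeated holdout is deterministic, bounded by its reps, and exact on separable data", {
  blobs <- make_blobs(9, k = 7, p = 6, sep = 9, seed = 51)
  r1 <- repeated_holdout(blobs$x, blobs$y, spec = "naive_bayes", reps = 3,
                         seed = 8)
  r2 <- repeated_holdout(blobs$x, blobs$y, spec = "naive_bayes", reps = 3,
                         seed = 8)
  expect_equal(r1$macro_f, r2$macro_f)
  expect_identical(unclass(r1$confusion), unclass(r2$confusion))

  expect_equal(r1$macro_f, 1)              # separable: perfect every rep
  expect_true(all(r1$per_rep_macro_f == 1))
  expect_gte(r1$macro_f, min(r1$per_rep_macro_f))
  expect_lte(r1$macro_f, max(r1$per_rep_macro_f))
  # macro F equals the mean of averaged per-class F1
  expect_equal(r1$macro_f, mean(r1$per_class$f1), tolerance = 1e-12)

  single <- repeated_holdout(blobs$x, blobs$y, spec = "naive_bayes",
                             reps = 1, seed = 8)
  expect_length(single$per_rep_macro_f, 1L)

  tiny <- make_blobs(1, k = 2, p = 3, seed = 52)
  expect_error(repeated_holdout(tiny$x, tiny$y, reps = 1),
               "fewer than 2 instances")
})

test_that("stratified k-fold covers the dataset with balanced folds", {
  blobs <- make_blobs(10, k = 5, p = 6, sep = 9, seed = 53)
  r <- kfold_cv(blobs$x, blobs$y, spec = "naive_bayes", k = 5, seed = 2)
  expect_equal(r$macro_f, 1)
  # the summed confusion uses every instance exactly once
  expect_equal(sum(r$confusion), length(blobs$y))
  expect_equal(unname(rowSums(r$confusion)), rep(10L, 5))
  expect_error(kfold_cv(blobs$x, blobs$y, k = 11), "fewer instances")
})
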