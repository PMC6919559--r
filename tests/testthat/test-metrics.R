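# IoU, object matching, per-image scoring and dataset aggregation.

test_that("iou matches pixel-count enumeration and is symmetric", {
  a <- matrix(FALSE, 10, 10); a[3:6, 3:6] <- TRUE       # 16 px
  inner <- matrix(FALSE, 10, 10); inner[4:5, 3:6] <- TRUE  # 8 px inside a
  expect_identical(iou(a, a), 1)
  expect_identical(iou(inner, a), 0.5)
  disj <- matrix(FALSE, 10, 10); disj[9, 9] <- TRUE
  expect_identical(iou(a, disj), 0)
  expect_identical(iou(a * 0 > 0, a * 0 > 0), 0)        # both empty
  expect_error(iou(a, matrix(FALSE, 9, 10)), "shape")
  for (s in 1:10) {
    x <- matrix(runif(64) < 0.3, 8, 8)
    y <- matrix(runif(64) < 0.3, 8, 8)
    expect_identical(iou(x, y), iou(y, x))
  }
})

test_that("iou_matrix equals the dense all-pairs oracle", {
  m <- random_mask(20, 20, 4, seed = 5)
  expect_equal(iou_matrix(m, m)$values, diag(4))
  for (s in 1:10) {
    t <- random_mask(24, 24, 5, seed = s)
    p <- jittered_prediction(t, seed = s + 100)
    expect_equal(iou_matrix(t, p)$values, dense_iou_oracle(t, p))
  }
  expect_error(iou_matrix(m, label_mask(matrix(0L, 5, 5))), "shape")
})

test_that("greedy matching resolves conflicts like the exhaustive matcher", {
  # one target overlapping two preds and vice versa; cardinality-2 optimum
  m <- manual_iou_matrix(matrix(c(0.6, 0, 0.55, 0.58), 2, 2,
                                dimnames = NULL))  # (a,x)=.6 (a,y)=.55 (b,y)=.58
  r <- match_at_threshold(m, 0.5)
  expect_equal(r$tp, 2)
  expect_equal(r$pairs$target, c(1, 2))
  expect_equal(r$pairs$pred, c(1, 2))

  single <- match_at_threshold(manual_iou_matrix(matrix(1, 1, 1)), 0.5)
  expect_equal(single$pairs$iou, 1)
  expect_equal(c(single$tp, single$fp, single$fn), c(1, 0, 0))

  none <- match_at_threshold(manual_iou_matrix(matrix(0, 3, 0)), 0.3)
  expect_equal(c(none$tp, none$fp, none$fn), c(0, 0, 3))
})

test_that("matching is strict by default and inclusive on request", {
  m <- manual_iou_matrix(matrix(0.5, 1, 1))
  expect_equal(match_at_threshold(m, 0.5)$tp, 0)
  expect_equal(match_at_threshold(m, 0.5, inclusive = TRUE)$tp, 1)
})

test_that("confusion counts are conserved at every threshold", {
  for (s in 1:10) {
    t <- random_mask(24, 24, sample(0:6, 1), seed = s)
    p <- jittered_prediction(t, seed = s + 50)
    m <- iou_matrix(t, p)
    for (th in default_thresholds()) {
      r <- match_at_threshold(m, th)
      expect_equal(r$tp + r$fn, t$n_objects)
      expect_equal(r$tp + r$fp, p$n_objects)
      expect_equal(r$tp, nrow(r$pairs))
      expect_false(anyDuplicated(r$pairs$target) > 0)
      expect_false(anyDuplicated(r$pairs$pred) > 0)
      expect_equal(r$tn, 0L)
    }
  }
})

test_that("above 0.5 IoU no object can exceed the threshold with two partners", {
  for (s in 1:10) {
    t <- random_mask(24, 24, 5, seed = s)
    p <- jittered_prediction(t, seed = s + 77, shift = 1L)
    v <- iou_matrix(t, p)$values
    expect_true(all(rowSums(v > 0.5) <= 1))
    expect_true(all(colSums(v > 0.5) <= 1))
  }
})

test_that("precision, recall and F1 follow the stated conventions", {
  expect_equal(precision_recall_f1(2, 0, 0), c(precision = 1, recall = 1, f1 = 1))
  expect_equal(precision_recall_f1(1, 1, 1),
               c(precision = 0.5, recall = 0.5, f1 = 0.5))
  expect_equal(precision_recall_f1(0, 0, 0), c(precision = 1, recall = 1, f1 = 1))
  expect_equal(precision_recall_f1(0, 2, 0)[["precision"]], 0)
  expect_equal(precision_recall_f1(0, 0, 3)[["recall"]], 0)
})

test_that("a perfect prediction scores 1 and a missed-everything image scores 0", {
  m <- random_mask(20, 20, 4, seed = 2)
  rep <- image_score(m, m)
  expect_equal(rep$score, 1)
  expect_true(all(rep$by_threshold$f1 == 1))
  empty <- label_mask(matrix(0L, 20, 20))
  expect_equal(image_score(m, empty)$score, 0)
  expect_equal(image_score(empty, empty)$score, 1)  # all-empty convention
})

test_that("an object at IoU exactly 0.5 scores S = 8/18 under the strict rule", {
  target <- matrix(0L, 8, 8); target[3:6, 3:6] <- 1L          # 16 px
  pred <- matrix(0L, 8, 8); pred[4:5, 3:6] <- 1L              # 8 px inside
  rep <- image_score(label_mask(target), label_mask(pred))
  expect_equal(iou(target > 0, pred > 0), 0.5)
  expect_equal(rep$score, 8 / 18)
  expect_equal(rep$by_threshold$term, c(rep(1, 8), rep(0, 10)))
})

test_that("S never exceeds the mean F1 and both stay in [0, 1]", {
  for (s in 1:8) {
    t <- random_mask(24, 24, sample(1:6, 1), seed = s)
    p <- jittered_prediction(t, seed = s + 31)
    rep <- image_score(t, p)
    mean_f1 <- mean(rep$by_threshold$f1)
    expect_gte(rep$score, 0)
    expect_lte(rep$score, mean_f1 + 1e-12)
    expect_lte(mean_f1, 1)
    expect_true(all(diff(rep$by_threshold$tp) <= 0))
    expect_true(all(diff(rep$by_threshold$f1) <= 1e-12))
  }
})

test_that("dataset aggregation averages images and pools objects at 0.7", {
  m1 <- random_mask(20, 20, 3, seed = 11)
  m2 <- random_mask(20, 20, 2, seed = 12)
  perfect <- list(list(target = m1, pred = m1, group = "a"),
                  list(target = m2, pred = m2, group = "b"))
  rep <- evaluate_dataset(perfect)
  expect_equal(rep$mean_score, 1)
  expect_equal(rep$average_f1, 1)
  expect_equal(rep$missed_at_07, 0)
  expect_equal(rep$extra_at_07, 0)

  one <- label_mask({ z <- matrix(0L, 20, 20); z[5, 5] <- 1L; z })
  nothing <- label_mask(matrix(0L, 20, 20))
  half <- evaluate_dataset(list(list(target = m1, pred = m1),
                                list(target = one, pred = nothing)))
  expect_equal(half$mean_score, 0.5)
  expect_equal(half$recall_at_07 + half$missed_at_07, 100)
  expect_equal(half$recall_at_07, 100 * 3 / 4)  # pooled: 3 of 4 objects found

  expect_error(evaluate_dataset(list()), "at least one")
})

test_that("group breakdown computes each group on its own subset", {
  m1 <- random_mask(20, 20, 3, seed = 21)
  one <- label_mask({ z <- matrix(0L, 20, 20); z[5, 5] <- 1L; z })
  nothing <- label_mask(matrix(0L, 20, 20))
  rep <- evaluate_dataset(list(
    list(target = m1, pred = m1, group = "fluor"),
    list(target = one, pred = nothing, group = "tissue")))
  bg <- rep$by_group[order(rep$by_group$group), ]
  expect_equal(bg$mean_score, c(1, 0))
  expect_equal(bg$missed_at_07, c(0, 100))
  expect_true(all(abs(bg$recall_at_07 + bg$missed_at_07 - 100) < 1e-12))
})

test_that("the F1 curve is flat at 1 for perfect input and never increases", {
  m <- random_mask(20, 20, 4, seed = 31)
  expect_true(all(f1_curve(list(list(target = m, pred = m)))$mean_f1 == 1))

  # single object pair at IoU 0.75: 1 below the threshold, 0 at and above
  t <- matrix(0L, 8, 8); t[1:4, 1:4] <- 1L       # 16 px
  p <- matrix(0L, 8, 8); p[1:4, 1:3] <- 1L       # 12 px inside: IoU = 0.75
  crv <- f1_curve(list(list(target = label_mask(t), pred = label_mask(p))))
  expect_equal(crv$mean_f1, ifelse(crv$t < 0.75, 1, 0))

  for (s in 1:20) {
    tm <- random_mask(24, 24, sample(1:5, 1), seed = s)
    pm <- jittered_prediction(tm, seed = s + 400)
    crv <- f1_curve(list(list(target = tm, pred = pm)))
    expect_true(all(diff(crv$mean_f1) <= 1e-12))
  }
})

test_that("threshold specs parse in integer hundredths", {
  expect_identical(parse_thresholds("0.10:0.95:0.05"), default_thresholds())
  expect_equal(length(default_thresholds()), 18)
  expect_error(parse_thresholds("0.5:0.1:0.1"))
})
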