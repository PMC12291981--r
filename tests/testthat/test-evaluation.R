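test_that("match_detections handles perfect, double-claimed and empty cases", {
  gts <- boxes(c(0, 10), c(0, 10), c(5, 15), c(5, 15))
  # perfect one-to-one at IoU 1
  d <- detections(gts, score = c(0.9, 0.8))
  m <- match_detections(d, gts)
  expect_equal(c(m$tp, m$fp, m$fn), c(2L, 0L, 0L))

  # two detections on one ground truth: higher confidence wins, other is FP
  one <- boxes(0, 0, 4, 4)
  d2 <- detections(boxes(c(0, 0.2), c(0, 0), c(4, 4.2), c(4, 4)), c(0.6, 0.9))
  m2 <- match_detections(d2, one)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1L, 1L, 0L))
  expect_equal(m2$is_tp, c(TRUE, FALSE)) # descending-confidence order

  m0 <- match_detections(empty_dets(), gts)
  expect_equal(c(m0$tp, m0$fp, m0$fn), c(0L, 0L, 2L))
})

test_that("match_detections agrees with the exhaustive greedy reference", {
  withr::with_seed(404, {
    for (case in 1:100) {
      nd <- sample(0:15, 1)
      ng <- sample(1:10, 1)
      d <- if (nd == 0) empty_dets() else random_detections(nd, field = 30)
      g <- random_boxes(ng, field = 30)
      thr <- runif(1, 0.3, 0.7)
      m <- match_detections(d, g, thr)
      ref <- ref_match_counts(det_mat(d), d$score, det_mat(g), thr)
      expect_equal(c(m$tp, m$fp, m$fn), unname(as.integer(ref)))
      # structural identities hold on every matching
      expect_equal(m$tp + m$fn, ng)
      expect_equal(m$tp + m$fp, nd)
    }
  })
})

test_that("precision, recall and F1 follow their definitions and flag undefined cases", {
  r <- precision_recall_f1(list(tp = 9, fp = 1, fn = 1))
  expect_equal(c(r$precision, r$recall, r$f1), c(0.9, 0.9, 0.9))

  perfect <- precision_recall_f1(list(tp = 5, fp = 0, fn = 0))
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))

  degen <- precision_recall_f1(list(tp = 0, fp = 3, fn = 2))
  expect_equal(c(degen$precision, degen$recall), c(0, 0))
  expect_equal(degen$f1, 0)
  expect_false(degen$defined_f1)

  nodet <- precision_recall_f1(list(tp = 0, fp = 0, fn = 2))
  expect_true(is.na(nodet$precision))
  expect_false(nodet$defined_precision)
  expect_true(nodet$defined_recall)
})

test_that("average_precision integrates the precision envelope", {
  gts <- boxes(c(0, 100), c(0, 100), c(10, 110), c(10, 110))
  # ranked outcomes TP, FP, TP over 2 ground truths
  d <- detections(boxes(c(0, 50, 100), c(0, 50, 100), c(10, 60, 110), c(10, 60, 110)),
                  score = c(0.9, 0.8, 0.7))
  pr <- average_precision(d, gts)
  expect_equal(pr$recall, c(0.5, 0.5, 1))
  expect_equal(pr$precision, c(1, 0.5, 2 / 3))
  expect_equal(pr$ap, 0.5 * 1 + 0.5 * (2 / 3))

  # all detections true positives covering all ground truths
  dall <- detections(gts, score = c(0.9, 0.8))
  expect_equal(average_precision(dall, gts)$ap, 1)

  # no true positives at all
  dmiss <- detections(boxes(500, 500, 510, 510), 0.9)
  expect_equal(average_precision(dmiss, gts)$ap, 0)

  expect_error(average_precision(dall, boxes(numeric(0), numeric(0),
                                             numeric(0), numeric(0))),
               "undefined")
})

test_that("AP is invariant to order-preserving confidence rescaling and FP duplicates never help", {
  withr::with_seed(505, {
    for (case in 1:20) {
      g <- random_boxes(sample(2:8, 1), field = 40)
      d <- random_detections(sample(3:15, 1), field = 40)
      ap <- average_precision(d, g)$ap
      d2 <- d
      d2$score <- d2$score * 0.5 # order-preserving
      expect_equal(average_precision(d2, g)$ap, ap, tolerance = 1e-12)
      # append a duplicate low-confidence detection far from everything
      d3 <- rbind(d, detections(boxes(900, 900, 910, 910), min(d$score) / 2))
      expect_lte(average_precision(d3, g)$ap, ap + 1e-12)
      m <- match_detections(d, g)
      m3 <- match_detections(d3, g)
      p <- precision_recall_f1(m)$precision
      p3 <- precision_recall_f1(m3)$precision
      expect_lte(p3, p + 1e-12)
    }
  })
})

test_that("counting_metrics implements the relative-accuracy, MAE and RMSE formulas", {
  perfect <- counting_metrics(count_pairs(c(12, 20, 28), c(12, 20, 28)))
  expect_equal(perfect$average_accuracy, 1)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$rmse, 0)

  # three-scene worked example: true 27/10/22, predicted 26/10/22
  rep3 <- counting_metrics(count_pairs(c(27, 10, 22), c(26, 10, 22)))
  expect_equal(rep3$average_accuracy, (1 - 1 / 27 + 1 + 1) / 3)
  expect_equal(rep3$mae, 1 / 3)
  expect_equal(rep3$rmse, 1 / sqrt(3))

  miss <- counting_metrics(count_pairs(10, 0))
  expect_equal(miss$average_accuracy, 0)
  expect_equal(miss$mae, 10)
  expect_equal(miss$rmse, 10)

  expect_error(counting_metrics(count_pairs(0, 3)), "positive")
})

test_that("rmse dominates mae and accuracy can go negative on gross errors", {
  withr::with_seed(606, {
    for (case in 1:50) {
      m <- sample(1:20, 1)
      a <- sample(8:30, m, replace = TRUE)
      b <- pmax(0, a + sample(-10:10, m, replace = TRUE))
      r <- counting_metrics(count_pairs(a, b))
      expect_gte(r$rmse, r$mae - 1e-12)
      expect_lte(r$average_accuracy, 1)
    }
  })
  neg <- counting_metrics(count_pairs(8, 25))
  expect_lt(neg$average_accuracy, 0)
})
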