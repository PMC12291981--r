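test_that("hard_nms keeps singletons and suppresses exact duplicates", {
  d1 <- detections(boxes(0, 0, 2, 2), 0.7)
  expect_equal(hard_nms(d1, 0.5)$score, 0.7)
  dup <- detections(boxes(c(0, 0), c(0, 0), c(2, 2), c(2, 2)), c(0.9, 0.8))
  kept <- hard_nms(dup, 0.5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$score, 0.9)
  expect_equal(nrow(hard_nms(empty_dets(), 0.5)), 0)
})

test_that("hard_nms matches the brute-force greedy reference on random instances", {
  withr::with_seed(101, {
    for (case in 1:100) {
      n <- sample(1:50, 1)
      d <- random_detections(n, field = 60)
      thr <- runif(1, 0.2, 0.7)
      got <- hard_nms(d, thr)
      ref_idx <- ref_hard_nms_idx(det_mat(d), d$score, thr)
      expect_equal(det_mat(got), det_mat(d)[ref_idx, , drop = FALSE],
                   ignore_attr = TRUE)
      expect_equal(got$score, d$score[ref_idx])
    }
  })
})

test_that("soft_nms applies the Gaussian decay of overlapping scores", {
  # disjoint boxes: decay factor exp(0) = 1, scores unchanged
  far <- detections(boxes(c(0, 50), c(0, 50), c(2, 52), c(2, 52)), c(0.9, 0.6))
  out <- soft_nms(far, soft_nms_params(0.5, 0))
  expect_equal(out$score, c(0.9, 0.6))

  # IoU exactly 0.5 with the kept box: decay exp(-0.25/0.5) = exp(-0.5)
  d <- detections(boxes(c(0, 2 / 3), c(0, 0), c(2, 2 + 2 / 3), c(1, 1)), c(1, 1))
  out <- soft_nms(d, soft_nms_params(sigma = 0.5, keep_floor = 0))
  expect_equal(sort(out$score), sort(c(1, exp(-0.5))), tolerance = 1e-12)

  # exact duplicate: decay exp(-1/0.5) = exp(-2)
  dup <- detections(boxes(c(0, 0), c(0, 0), c(2, 2), c(2, 2)), c(0.9, 0.8))
  out <- soft_nms(dup, soft_nms_params(0.5, 0))
  expect_equal(out$score, c(0.9, 0.8 * exp(-2)), tolerance = 1e-12)

  # keep_floor discards the decayed duplicate
  out <- soft_nms(dup, soft_nms_params(0.5, 0.25))
  expect_equal(out$score, 0.9)
})

test_that("soft_nms limiting behavior brackets hard NMS", {
  withr::with_seed(202, {
    for (case in 1:20) {
      d <- grid_detections(sample(5:30, 1))
      # sigma -> infinity: identity on scores
      out <- soft_nms(d, soft_nms_params(sigma = 1e9, keep_floor = 0))
      expect_equal(sort(out$score), sort(d$score), tolerance = 1e-6)
      expect_equal(nrow(out), nrow(d))
      # sigma -> 0 with a positive floor: equivalent to hard NMS with
      # threshold -> 0 (any positive overlap suppresses)
      out0 <- soft_nms(d, soft_nms_params(sigma = 1e-6, keep_floor = 0.01))
      ref_idx <- ref_hard_nms_idx(det_mat(d), d$score, 1e-9)
      expect_equal(det_mat(out0), det_mat(d)[ref_idx, , drop = FALSE],
                   ignore_attr = TRUE)
    }
  })
})

test_that("soft_nms decay is monotone in overlap with the suppressing box", {
  # one kept anchor and one probe at a time, at increasing overlap
  anchor <- boxes(0, 0, 10, 10)
  decayed <- vapply(seq(9, 0, by = -1), function(shift) {
    probe <- boxes(shift, 0, shift + 10, 10)
    d <- detections(boxes(c(0, shift), c(0, 0), c(10, shift + 10), c(10, 10)),
                    score = c(1, 0.5))
    out <- soft_nms(d, soft_nms_params(0.5, 0))
    min(out$score)
  }, numeric(1))
  # shift decreasing means IoU with the anchor increasing
  expect_true(all(diff(decayed) <= 1e-12))
  expect_equal(decayed[1], 0.5 * exp(-scalar_iou(c(9, 0, 19, 10), c(0, 0, 10, 10))^2 / 0.5))
})

test_that("both suppressors return subsets with only-reduced scores", {
  withr::with_seed(303, {
    for (case in 1:20) {
      d <- random_detections(sample(2:40, 1), field = 50)
      key <- paste(d$x_min, d$y_min, d$x_max, d$y_max)
      h <- hard_nms(d, 0.4)
      expect_true(all(paste(h$x_min, h$y_min, h$x_max, h$y_max) %in% key))
      expect_equal(h$score, d$score[match(paste(h$x_min, h$y_min, h$x_max, h$y_max), key)])
      s <- soft_nms(d, soft_nms_params(0.5, 0))
      pos <- match(paste(s$x_min, s$y_min, s$x_max, s$y_max), key)
      expect_true(all(s$score <= d$score[pos] + 1e-12))
      expect_equal(nrow(s), nrow(d)) # keep_floor 0 retains everything
    }
  })
})

test_that("density tiers have exact boundaries and clamp out-of-range counts", {
  expect_equal(classify_density(10)$name, "LOW")
  expect_equal(classify_density(15)$name, "LOW")
  expect_equal(classify_density(16)$name, "MEDIUM")
  expect_equal(classify_density(23)$name, "MEDIUM")
  expect_equal(classify_density(24)$name, "HIGH")
  expect_equal(classify_density(30)$name, "HIGH")
  # counts outside the taxonomy clamp to the nearest tier
  expect_equal(classify_density(3)$name, "LOW")
  expect_equal(classify_density(0)$name, "LOW")
  expect_equal(classify_density(45)$name, "HIGH")
  # strategies attached to the tiers
  expect_equal(classify_density(10)$iou_threshold, 0.5)
  expect_equal(classify_density(20)$iou_threshold, 0.4)
  expect_equal(classify_density(25)$strategy, "soft_nms")
  expect_equal(classify_density(25)$sigma, 0.5)
})

test_that("density_aware_count routes by raw count and enumerates retained detections", {
  # 10 well-separated boxes: LOW tier, nothing suppressed
  x <- seq(0, 540, by = 60)[1:10]
  d <- detections(boxes(x, 0, x + 40, 40), score = rep(0.95, 10))
  res <- density_aware_count(d)
  expect_equal(res$tier$name, "LOW")
  expect_equal(res$count, 10L)

  # 27 moderately overlapping boxes: HIGH tier, Soft-NMS path
  withr::with_seed(9, {
    x <- runif(27, 0, 500)
    d27 <- detections(boxes(x, 0, x + 120, 60), score = runif(27, 0.5, 1))
  })
  res27 <- density_aware_count(d27)
  expect_equal(res27$tier$name, "HIGH")
  expect_equal(res27$tier$strategy, "soft_nms")

  # two exact duplicates per true box, 12 true boxes: raw count 24 picks
  # the HIGH tier and suppression recovers exactly 12
  x <- seq(0, 550, by = 50)[1:12]
  true_b <- boxes(x, 0, x + 40, 40)
  dd <- detections(boxes(rep(true_b$x_min, 2), rep(true_b$y_min, 2),
                         rep(true_b$x_max, 2), rep(true_b$y_max, 2)),
                   score = c(rep(0.9, 12), rep(0.7, 12)))
  resd <- density_aware_count(dd)
  expect_equal(resd$initial_count, 24L)
  expect_equal(resd$tier$name, "HIGH")
  expect_equal(resd$count, 12L)

  # empty input
  res0 <- density_aware_count(empty_dets())
  expect_equal(res0$count, 0L)
  expect_equal(res0$tier$name, "LOW")
})
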