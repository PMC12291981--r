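#' Density categories of crowded-pen scenes
#'
#' The simulator reproduces the density taxonomy of overhead pig-pen
#' imagery: sparse scenes hold 8-12 animals, low-medium 13-18, medium-high
#' 19-25 and high-density 26-30, occurring with relative frequencies
#' 20/30/35/15 percent.
#'
#' @return A data frame with columns `category`, `min_count`, `max_count`,
#'   `proportion`.
#' @export
density_categories <- function() {
  data.frame(
    category = c("sparse", "low_medium", "medium_high", "high"),
    min_count = c(8L, 13L, 19L, 26L),
    max_count = c(12L, 18L, 25L, 30L),
    proportion = c(0.20, 0.30, 0.35, 0.15)
  )
}

#' Draw scene density categories at the taxonomy's frequencies
#'
#' @param n Number of draws.
#' @param seed Integer seed; every source of randomness in the simulator
#'   is driven by an explicit seed.
#' @return A character vector of category names.
#' @export
sample_density_category <- function(n, seed) {
  cats <- density_categories()
  withr::with_seed(seed, {
    sample(cats$category, n, replace = TRUE, prob = cats$proportion)
  })
}

#' Scene simulation configuration
#'
#' @param canvas Image size in pixels, `c(width, height)`; default 640 x
#'   640, the working resolution of overhead pen monitoring.
#' @param density_category One of `"sparse"`, `"low_medium"`,
#'   `"medium_high"`, `"high"` (see [density_categories()]).
#' @param max_pairwise_iou Ceiling on the IoU between any two placed
#'   boxes, in \[0, 0.9\]. 0 forces mutually disjoint animals; crowded
#'   pens where animals pile up reach pairwise overlaps around 0.5.
#'   Default 0.3, a moderately crowded pen.
#' @param width_meanlog,width_sdlog Log-normal parameters of box width in
#'   pixels. The default (meanlog `log(110)`, sdlog 0.2) gives bodies
#'   around 110 px wide on a 640 px canvas, so up to 30 fit with room to
#'   overlap.
#' @param aspect_meanlog,aspect_sdlog Log-normal parameters of the
#'   height/width ratio; the default prior (meanlog `log(0.6)`, sdlog
#'   0.15) is landscape-oriented, as pigs viewed from overhead are longer
#'   than they are wide.
#' @param max_attempts Placement attempts per box before the sampler
#'   reports the configuration infeasible.
#' @param seed Integer seed; the same config (including seed) yields a
#'   byte-identical scene.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(canvas = c(640, 640),
                       density_category = "sparse",
                       max_pairwise_iou = 0.3,
                       width_meanlog = log(110), width_sdlog = 0.2,
                       aspect_meanlog = log(0.6), aspect_sdlog = 0.15,
                       max_attempts = 1000,
                       seed = 1L) {
  cats <- density_categories()
  density_category <- match.arg(density_category, cats$category)
  stopifnot(length(canvas) == 2, all(canvas > 0),
            max_pairwise_iou >= 0, max_pairwise_iou <= 0.9,
            max_attempts >= 1)
  structure(list(
    canvas = as.numeric(canvas),
    density_category = density_category,
    max_pairwise_iou = max_pairwise_iou,
    width_meanlog = width_meanlog, width_sdlog = width_sdlog,
    aspect_meanlog = aspect_meanlog, aspect_sdlog = aspect_sdlog,
    max_attempts = as.integer(max_attempts),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Sample a ground-truth scene
#'
#' Draws the animal count uniformly from the configured category's range,
#' then places boxes by rejection sampling: each box's width and aspect
#' ratio come from the configured log-normal priors, its position is
#' uniform inside the canvas, and a placement is accepted only if its IoU
#' with every already-placed box is at most `max_pairwise_iou`. If a box
#' cannot be placed within `max_attempts` tries the sampler fails
#' explicitly rather than silently returning a short scene (the true count
#' is the quantity under study).
#'
#' @param config A [sim_config()].
#' @param scene_id Identifier stored in the scene.
#' @return A list of class `gt_scene` with fields `scene_id`, `canvas`,
#'   `boxes` (a box data frame), and `a` (the true count, `nrow(boxes)`).
#' @export
sample_scene <- function(config, scene_id = "scene-1") {
  stopifnot(inherits(config, "sim_config"))
  cats <- density_categories()
  row <- cats[cats$category == config$density_category, ]
  withr::with_seed(config$seed, {
    a <- sample(row$min_count:row$max_count, 1)
    placed <- matrix(numeric(0), ncol = 4,
                     dimnames = list(NULL, c("x_min", "y_min", "x_max", "y_max")))
    for (i in seq_len(a)) {
      ok <- FALSE
      for (attempt in seq_len(config$max_attempts)) {
        w <- stats::rlnorm(1, config$width_meanlog, config$width_sdlog)
        h <- w * stats::rlnorm(1, config$aspect_meanlog, config$aspect_sdlog)
        w <- min(w, config$canvas[1] * 0.95)
        h <- min(h, config$canvas[2] * 0.95)
        cx <- stats::runif(1, w / 2, config$canvas[1] - w / 2)
        cy <- stats::runif(1, h / 2, config$canvas[2] - h / 2)
        cand <- c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
        if (nrow(placed) == 0 ||
            max(pairwise_iou_vec(placed, cand)) <= config$max_pairwise_iou) {
          placed <- rbind(placed, cand)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop(sprintf(
          "could not place box %d of %d within %d attempts (canvas %gx%g, max pairwise IoU %g)",
          i, a, config$max_attempts, config$canvas[1], config$canvas[2],
          config$max_pairwise_iou
        ))
      }
    }
  })
  b <- boxes(placed[, 1], placed[, 2], placed[, 3], placed[, 4])
  structure(list(scene_id = scene_id, canvas = config$canvas,
                 boxes = b, a = as.integer(nrow(b))),
            class = "gt_scene")
}

# IoU of one candidate box (length-4 vector) against a matrix of boxes
pairwise_iou_vec <- function(placed, cand) {
  ix <- pmax(placed[, 1], cand[1])
  iy <- pmax(placed[, 2], cand[2])
  ax <- pmin(placed[, 3], cand[3])
  ay <- pmin(placed[, 4], cand[4])
  inter <- pmax(0, ax - ix) * pmax(0, ay - iy)
  area_p <- (placed[, 3] - placed[, 1]) * (placed[, 4] - placed[, 2])
  area_c <- (cand[3] - cand[1]) * (cand[4] - cand[2])
  inter / (area_p + area_c - inter)
}

#' Detector-noise configuration
#'
#' Emulates an imperfect single-class detector applied to a ground-truth
#' scene: misses, localization jitter, confidence variation, duplicate
#' proposals and false positives. The defaults describe a strong modern
#' detector on this task: 95% per-animal detection probability, 5%
#' center/size jitter, confidences around 0.8, a 10% chance of a duplicate
#' proposal, and on average half a false positive per scene at low
#' confidence.
#'
#' @param p_detect Per-true-box detection probability.
#' @param center_jitter Standard deviation of center displacement, as a
#'   fraction of the box's width/height.
#' @param size_jitter Standard deviation of the multiplicative size
#'   perturbation (log scale approximated by `1 + N(0, size_jitter)`,
#'   truncated to stay positive).
#' @param conf_mean,conf_sd Mean and spread of true-detection confidence;
#'   sampled normal, clipped to \[0, 1\].
#' @param duplicate_prob Probability that a detected box also emits a
#'   second, independently jittered proposal at lower confidence.
#' @param duplicate_conf_scale Factor (< 1) applied to a duplicate's
#'   confidence so it ranks below its parent.
#' @param fp_rate Poisson mean of false positives per scene, placed
#'   uniformly with sizes from the same prior as true boxes.
#' @param fp_conf_mean,fp_conf_sd Confidence distribution of false
#'   positives (lower than true detections).
#' @param seed Integer seed.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(p_detect = 0.95,
                         center_jitter = 0.05, size_jitter = 0.05,
                         conf_mean = 0.8, conf_sd = 0.1,
                         duplicate_prob = 0.1, duplicate_conf_scale = 0.8,
                         fp_rate = 0.5, fp_conf_mean = 0.35, fp_conf_sd = 0.1,
                         seed = 1L) {
  probs <- c(p_detect, duplicate_prob)
  stopifnot(all(probs >= 0), all(probs <= 1),
            center_jitter >= 0, size_jitter >= 0,
            conf_sd >= 0, fp_rate >= 0, fp_conf_sd >= 0,
            duplicate_conf_scale > 0, duplicate_conf_scale <= 1)
  structure(list(
    p_detect = p_detect,
    center_jitter = center_jitter, size_jitter = size_jitter,
    conf_mean = conf_mean, conf_sd = conf_sd,
    duplicate_prob = duplicate_prob,
    duplicate_conf_scale = duplicate_conf_scale,
    fp_rate = fp_rate, fp_conf_mean = fp_conf_mean, fp_conf_sd = fp_conf_sd,
    seed = as.integer(seed)
  ), class = "noise_config")
}

#' Noise-free detector configuration
#'
#' Convenience wrapper: every animal detected, no jitter, no duplicates,
#' no false positives, fixed confidence. Under this config the simulated
#' detections are exactly the ground-truth boxes, which is the closure
#' case used throughout the test-suite.
#'
#' @param conf Fixed confidence assigned to every detection.
#' @param seed Integer seed (unused randomness, kept for interface
#'   uniformity).
#' @return A `noise_config`.
#' @export
zero_noise_config <- function(conf = 0.9, seed = 1L) {
  noise_config(p_detect = 1, center_jitter = 0, size_jitter = 0,
               conf_mean = conf, conf_sd = 0,
               duplicate_prob = 0, fp_rate = 0, seed = seed)
}

#' Simulate detector output on a ground-truth scene
#'
#' Each true box is independently detected with probability `p_detect`;
#' detected boxes are jittered in center and size, and assigned a clipped
#' confidence. With probability `duplicate_prob` a detected box also emits
#' a second jittered proposal at `duplicate_conf_scale` times its
#' confidence. False positives are added at a per-scene Poisson rate with
#' sizes drawn from the scene's box-size prior and low confidence.
#' Deterministic for a fixed `noise$seed`.
#'
#' @param scene A `gt_scene` (see [sample_scene()]).
#' @param noise A [noise_config()].
#' @return A detections data frame.
#' @export
simulate_detector <- function(scene, noise) {
  stopifnot(inherits(scene, "gt_scene"), inherits(noise, "noise_config"))
  gt <- scene$boxes
  withr::with_seed(noise$seed, {
    rows <- list()
    for (i in seq_len(nrow(gt))) {
      if (stats::runif(1) > noise$p_detect) next
      base <- as.numeric(gt[i, c("x_min", "y_min", "x_max", "y_max")])
      conf <- clip01(stats::rnorm(1, noise$conf_mean, noise$conf_sd))
      rows[[length(rows) + 1]] <- c(jitter_box(base, noise, scene$canvas), conf)
      if (stats::runif(1) < noise$duplicate_prob) {
        dup_conf <- clip01(conf * noise$duplicate_conf_scale)
        rows[[length(rows) + 1]] <- c(jitter_box(base, noise, scene$canvas), dup_conf)
      }
    }
    n_fp <- stats::rpois(1, noise$fp_rate)
    for (k in seq_len(n_fp)) {
      w <- stats::rlnorm(1, log(110), 0.2)
      h <- w * stats::rlnorm(1, log(0.6), 0.15)
      w <- min(w, scene$canvas[1] * 0.95)
      h <- min(h, scene$canvas[2] * 0.95)
      cx <- stats::runif(1, w / 2, scene$canvas[1] - w / 2)
      cy <- stats::runif(1, h / 2, scene$canvas[2] - h / 2)
      conf <- clip01(stats::rnorm(1, noise$fp_conf_mean, noise$fp_conf_sd))
      rows[[length(rows) + 1]] <- c(cx - w / 2, cy - h / 2,
                                    cx + w / 2, cy + h / 2, conf)
    }
  })
  if (length(rows) == 0) return(empty_detections())
  m <- do.call(rbind, rows)
  detections(boxes(m[, 1], m[, 2], m[, 3], m[, 4]), score = m[, 5])
}

jitter_box <- function(b, noise, canvas) {
  w <- b[3] - b[1]
  h <- b[4] - b[2]
  cx <- (b[1] + b[3]) / 2 + stats::rnorm(1, 0, noise$center_jitter) * w
  cy <- (b[2] + b[4]) / 2 + stats::rnorm(1, 0, noise$center_jitter) * h
  sw <- w * max(0.1, 1 + stats::rnorm(1, 0, noise$size_jitter))
  sh <- h * max(0.1, 1 + stats::rnorm(1, 0, noise$size_jitter))
  c(cx - sw / 2, cy - sh / 2, cx + sw / 2, cy + sh / 2)
}

clip01 <- function(x) pmin(1, pmax(0, x))
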