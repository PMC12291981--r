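#' Reference survey of crowded-pen imagery: density distribution
#'
#' Composition of the 8000-image multi-source overhead pig-pen survey from
#' which the simulator's density taxonomy and category frequencies are
#' drawn: how many images fall in each density category. The
#' `proportion`s of [density_categories()] are these image counts divided
#' by the survey total.
#'
#' @return A data frame with columns `category`, `min_count`, `max_count`,
#'   `n_images`.
#' @seealso [reference_split_summary()] for the train/validation/test
#'   composition of the same survey.
#' @export
reference_density_distribution <- function() {
  cbind(
    density_categories()[c("category", "min_count", "max_count")],
    n_images = c(1600L, 2400L, 2800L, 1200L)
  )
}

#' Reference survey of crowded-pen imagery: split composition
#'
#' Per-split image and animal totals of the reference survey (raw counts,
#' before any augmentation): number of images, total animals across all
#' images of the split, the maximum seen in a single image, and the mean
#' per image.
#'
#' @return A data frame with columns `set`, `n_images`, `total_animals`,
#'   `max_in_image`, `mean_per_image`.
#' @export
reference_split_summary <- function() {
  data.frame(
    set = c("train", "validation", "test"),
    n_images = c(4800L, 1600L, 1600L),
    total_animals = c(86400L, 30400L, 33600L),
    max_in_image = c(30L, 29L, 30L),
    mean_per_image = c(18, 19, 21)
  )
}
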