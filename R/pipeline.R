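#' Full single-image feature pipeline
#'
#' Convenience wrapper chaining artifact removal (optional), geometric
#' normalization to 500 x 400, the five-level dual-tree decomposition and
#' texture-feature extraction.
#'
#' @param image intensity matrix.
#' @param meta one-row metadata (clinical triple).
#' @param config a [feature_config()].
#' @param rois optional list of [roi_rect()] for [remove_artifacts()].
#' @param normalize run [normalize_geometry()] first (default TRUE).
#' @return Named feature vector (see [extract_features()]).
#' @export
image_features <- function(image, meta, config = feature_config(),
                           rois = list(), normalize = TRUE) {
  if (length(rois)) image <- remove_artifacts(image, rois)
  if (normalize) image <- normalize_geometry(image)
  s <- dtcwt_forward(image, levels = config$levels)
  extract_features(s, meta, config)
}

#' Feature table of an in-memory image set
#'
#' @param images list of intensity matrices.
#' @param meta metadata data frame (one row per image) with clinical,
#'   label and subject columns.
#' @inheritParams image_features
#' @param progress print a dot every 25 images.
#' @return A [feature_table()].
#' @export
extract_feature_table <- function(images, meta, config = feature_config(),
                                  normalize = TRUE, progress = FALSE) {
  stopifnot(length(images) == nrow(meta))
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    rows[[i]] <- image_features(images[[i]], meta[i, ], config,
                                normalize = normalize)
    if (progress && i %% 25L == 0L) cat(".")
  }
  if (progress) cat("\n")
  m <- do.call(rbind, rows)
  rownames(m) <- NULL
  feature_table(m, labels = meta$class_label, groups = meta$subject_id)
}

#' Streamed phantom-cohort feature table
#'
#' Renders a synthetic cohort with [generate_cohort()] and converts every
#' frame to its feature vector as soon as it is rendered, so arbitrarily
#' large cohorts never hold all images in memory.
#'
#' @inheritParams generate_cohort
#' @param config a [feature_config()].
#' @param progress print a dot every 25 frames.
#' @return A [feature_table()].
#' @export
phantom_feature_table <- function(n_subjects_per_class = 4,
                                  videos_per_subject = 6,
                                  frames_per_video = 5, seed = 1,
                                  height = 520, width = 420,
                                  specs = default_phantom_specs(),
                                  config = feature_config(),
                                  progress = FALSE) {
  count <- 0L
  coh <- generate_cohort(
    n_subjects_per_class, videos_per_subject, frames_per_video,
    seed = seed, height = height, width = width, specs = specs,
    frame_fun = function(img, row) {
      count <<- count + 1L
      if (progress && count %% 25L == 0L) cat(".")
      image_features(img, row, config)
    })
  if (progress) cat("\n")
  m <- do.call(rbind, coh$images)
  rownames(m) <- NULL
  feature_table(m, labels = coh$meta$class_label,
                groups = coh$meta$subject_id)
}
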