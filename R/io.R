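MANIFEST_COLUMNS <- c("subject_id", "video_id", "frame_index", "path",
                      "class_label", "lung_region", "ga_weeks",
                      "cgats_weeks", "dol_days")

#' Write a cohort to disk as 8-bit PNGs plus a manifest CSV
#'
#' @param images list of intensity matrices (0-255 scale).
#' @param meta metadata data frame as produced by [generate_cohort()].
#' @param dir output directory (created if needed); images land in
#'   `dir/images/`.
#' @param provenance optional named list (seed, generator settings)
#'   stored as JSON next to the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(images, meta, dir, provenance = NULL) {
  stopifnot(length(images) == nrow(meta))
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- sprintf("images/%s_f%03d.png", meta$video_id, meta$frame_index)
  for (i in seq_along(images))
    png::writePNG(pmin(pmax(images[[i]], 0), 255) / 255,
                  file.path(dir, paths[i]))
  man <- cbind(meta[c("subject_id", "video_id", "frame_index")],
               path = paths,
               meta[c("class_label", "lung_region", "ga_weeks",
                      "cgats_weeks", "dol_days")])
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(provenance))
    jsonlite::write_json(provenance, file.path(dir, "provenance.json"),
                         auto_unbox = TRUE)
  invisible(file.path(dir, "manifest.csv"))
}

#' Load a data set from a manifest CSV
#'
#' Validates the schema (required columns, the six-class enum, unique
#' subject/video/frame triples, resolvable image paths, CGATS >= GA) and
#' reports violations with their row numbers.
#'
#' @param manifest_path manifest CSV; image paths are resolved relative
#'   to its directory.
#' @return List with `images` (intensity matrices on the 0-255 scale) and
#'   `meta` (data frame without the path column).
#' @export
load_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  missing <- setdiff(MANIFEST_COLUMNS, names(man))
  if (length(missing))
    stop("manifest lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- which(!man$class_label %in% LUS_CLASSES)
  if (length(bad))
    stop(sprintf("row %d: unknown class label '%s'", bad[1],
                 man$class_label[bad[1]]), call. = FALSE)
  bad <- which(!man$lung_region %in% LUS_REGIONS)
  if (length(bad))
    stop(sprintf("row %d: unknown lung region '%s'", bad[1],
                 man$lung_region[bad[1]]), call. = FALSE)
  bad <- which(man$frame_index < 0 | man$dol_days < 0 |
                 man$cgats_weeks < man$ga_weeks)
  if (length(bad))
    stop(sprintf("row %d: inconsistent clinical/frame fields", bad[1]),
         call. = FALSE)
  key <- paste(man$subject_id, man$video_id, man$frame_index)
  if (anyDuplicated(key))
    stop(sprintf("row %d: duplicate subject/video/frame triple",
                 anyDuplicated(key)), call. = FALSE)
  base <- dirname(manifest_path)
  images <- lapply(seq_len(nrow(man)), function(i) {
    p <- file.path(base, man$path[i])
    if (!file.exists(p))
      stop(sprintf("row %d: image file missing: %s", i, man$path[i]),
           call. = FALSE)
    img <- png::readPNG(p)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img * 255
  })
  list(images = images, meta = man[setdiff(names(man), "path")])
}

#' Per-class patients/videos/images summary of a data set
#'
#' @param meta metadata data frame with `class_label`, `subject_id`,
#'   `video_id` columns.
#' @return Data frame with one row per class plus a `Total` row.
#' @export
summarize_dataset <- function(meta) {
  if (!nrow(meta)) stop("empty metadata")
  per <- lapply(LUS_CLASSES, function(cl) {
    m <- meta[meta$class_label == cl, , drop = FALSE]
    data.frame(class = cl, patients = length(unique(m$subject_id)),
               videos = length(unique(m$video_id)), images = nrow(m))
  })
  tab <- do.call(rbind, per)
  tab <- tab[tab$images > 0 | tab$class %in% meta$class_label, ]
  rbind(tab, data.frame(class = "Total", patients = sum(tab$patients),
                        videos = sum(tab$videos),
                        images = sum(tab$images)))
}

#' Write a feature table to CSV
#'
#' One row per image; identity columns (`subject_id`, `class_label`)
#' first, then all feature columns including the clinical triple.
#'
#' @param t a [feature_table()].
#' @param path output CSV.
#' @export
write_feature_table <- function(t, path) {
  df <- data.frame(subject_id = t$groups,
                   class_label = as.character(t$labels),
                   t$matrix, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  need <- c("subject_id", "class_label", CLINICAL_FEATURES)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("feature CSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  feat <- setdiff(names(df), c("subject_id", "class_label"))
  m <- as.matrix(df[feat])
  if (!is.numeric(m)) stop("non-numeric feature columns in CSV")
  feature_table(m, labels = df$class_label, groups = df$subject_id)
}

#' Read preprocessing ROIs from a YAML file
#'
#' The file maps video ids to lists of `[row_start, row_end, col_start,
#' col_end]` rectangles (0-based, half-open), the semi-automatic overlay
#' regions marked once per video.
#'
#' @param path YAML file.
#' @return Named list of lists of [roi_rect()] objects.
#' @export
read_roi_file <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(video) {
    lapply(video, function(r) roi_rect(r[[1]], r[[2]], r[[3]], r[[4]]))
  })
}
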