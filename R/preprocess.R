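#' Rectangular region of interest
#'
#' 0-based, half-open `[start, end)` bounds on each axis, matching the
#' row-major, origin-top-left raster convention used throughout.
#'
#' @param row_start,row_end,col_start,col_end integer bounds with
#'   `0 <= start < end`.
#' @return An object of class `"roi_rect"`.
#' @export
roi_rect <- function(row_start, row_end, col_start, col_end) {
  v <- vapply(list(row_start, row_end, col_start, col_end), as.integer,
              integer(1))
  if (v[1] < 0 || v[3] < 0 || v[1] >= v[2] || v[3] >= v[4])
    stop("ROI bounds must satisfy 0 <= start < end", call. = FALSE)
  structure(list(row_start = v[1], row_end = v[2],
                 col_start = v[3], col_end = v[4]), class = "roi_rect")
}

# Binary 3x3 dilation of a logical matrix (edges clipped).
.dilate3x3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(h, h + dr)
    rt <- max(1, 1 - dr):min(h, h - dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    ct <- max(1, 1 - dc):min(w, w - dc)
    out[rt, ct] <- out[rt, ct] | m[rs, cs]
  }
  out
}

#' Remove bright overlay artifacts inside regions of interest
#'
#' Within each ROI, pixels whose intensity exceeds half of the ROI maximum
#' are selected, their 8-connected neighbours (clipped to the ROI) are added
#' to the selection, and every selected pixel is replaced by the ROI median
#' intensity. The median is computed over the original (pre-replacement) ROI
#' values, using the lower median for even counts so replacement values are
#' attained 8-bit intensities. Pixels outside all ROIs are untouched; an
#' empty ROI list is the identity.
#'
#' @param image numeric intensity matrix.
#' @param rois list of [roi_rect()] objects (may be empty).
#' @return Matrix of the same dimensions with artifacts suppressed.
#' @export
remove_artifacts <- function(image, rois = list()) {
  assert_gray_image(image)
  if (inherits(rois, "roi_rect")) rois <- list(rois)
  out <- image
  for (roi in rois) {
    if (!inherits(roi, "roi_rect")) stop("rois must be roi_rect objects")
    if (roi$row_end > nrow(image) || roi$col_end > ncol(image))
      stop("ROI exceeds image bounds", call. = FALSE)
    ri <- (roi$row_start + 1L):roi$row_end
    ci <- (roi$col_start + 1L):roi$col_end
    sub <- image[ri, ci, drop = FALSE]
    sel <- sub > 0.5 * max(sub)
    if (!any(sel)) next
    sel <- .dilate3x3(sel)
    repl <- out[ri, ci, drop = FALSE]
    repl[sel] <- lower_median(sub)
    out[ri, ci] <- repl
  }
  out
}

#' Normalize frame geometry to the canonical 500 x 400 raster
#'
#' Resamples the input to 520 rows by 420 columns with bilinear
#' interpolation, then trims ten rows/columns from every side, yielding
#' exactly 500 x 400. The trim discards non-ultrasound border pixels that
#' survive resampling in clinical frames.
#'
#' @param image numeric intensity matrix (at least 2 x 2).
#' @return 500 x 400 numeric matrix.
#' @export
normalize_geometry <- function(image) {
  assert_gray_image(image)
  if (nrow(image) < 2 || ncol(image) < 2)
    stop("image too small to resample", call. = FALSE)
  r <- EBImage::resize(image, w = 520, h = 420, filter = "bilinear")
  r <- EBImage::imageData(r)
  r[11:510, 11:410]
}
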