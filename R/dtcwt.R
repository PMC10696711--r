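# Filter banks.
#
# Level 1 uses the near-symmetric biorthogonal pair with a 5-tap scaling
# filter and 7-tap wavelet filter; the pair satisfies the halfband
# (perfect-reconstruction) identity exactly. Levels >= 2 use the standard
# orthonormal 14-tap quarter-shift pair: the second tree's filters are the
# time reverse of the first tree's, so their group delays differ by half a
# sample at the doubled rate, which is what makes the combined complex
# subbands nearly shift invariant.
NS_H0 <- c(-0.05, 0.25, 0.6, 0.25, -0.05)
NS_G0 <- c(-3, -15, 73, 170, 73, -15, -3) / 280
NS_H1 <- NS_G0 * c(1, -1, 1, -1, 1, -1, 1)

QS_H0A <- c(0.00325314, -0.00388321, 0.03466035, -0.03887280,
            -0.11720389, 0.27529538, 0.75614564, 0.56881042,
            0.01186609, -0.10671180, 0.02382538, 0.01702522,
            -0.00543948, -0.00455690)
QS_H0B <- rev(QS_H0A)
# The published taps carry eight decimals; re-centre the highpass filters so
# their DC gain is exactly zero (constant inputs then annihilate to rounding).
QS_H1A <- rep(c(1, -1), 7) * QS_H0B
QS_H1A <- QS_H1A - mean(QS_H1A)
QS_H1B <- rep(c(1, -1), 7) * QS_H0A
QS_H1B <- QS_H1B - mean(QS_H1B)

# Same-size correlation filtering along columns with symmetric (edge
# repeating) extension; h is applied to each column vector. The compiled
# kernel folds indices as often as necessary, so rasters smaller than the
# filter are handled too.
.filt_cols <- function(X, h) cpp_filt_cols(X, h, FALSE)

.filt_rows <- function(X, h) cpp_filt_rows(X, h, FALSE)

# Filter then decimate by two (keep odd output indices).
.dec_cols <- function(X, h) cpp_filt_cols(X, h, TRUE)
.dec_rows <- function(X, h) cpp_filt_rows(X, h, TRUE)

# Pad odd-sized rasters by replicating the final row/column.
.pad_even <- function(X) {
  if (nrow(X) %% 2L == 1L) X <- rbind(X, X[nrow(X), ])
  if (ncol(X) %% 2L == 1L) X <- cbind(X, X[, ncol(X)])
  X
}

# Orthonormal mapping from the four real trees of one detail type to two
# complex subbands.
.tree_pair <- function(u) {
  list(((u$aa - u$bb) + 1i * (u$ab + u$ba)) / sqrt(2),
       ((u$aa + u$bb) + 1i * (u$ab - u$ba)) / sqrt(2))
}

# Orientation labels in the documented subband order.
DTCWT_ORIENTATIONS <- c("D15p", "D45p", "D75p", "D75n", "D45n", "D15n")

# Map detail-type/tree-pair outputs onto the +15,+45,+75,-75,-45,-15 order.
# "LH" = low-pass vertical / high-pass horizontal responds to near-vertical
# structure (+/-75 deg); "HL" to near-horizontal (+/-15 deg); "HH" to the
# diagonals (+/-45 deg). The assignment of each pair member to the positive
# or negative angle was fixed empirically with oriented-line probes.
.assemble_oriented <- function(lh, hl, hh) {
  out <- list(hl[[1]], hh[[1]], lh[[1]], lh[[2]], hh[[2]], hl[[2]])
  names(out) <- DTCWT_ORIENTATIONS
  out
}

#' Five-level 2D dual-tree complex wavelet decomposition
#'
#' Decomposes a grayscale image with two parallel filter-bank trees; their
#' cross-combinations yield, per level, six complex oriented subbands at
#' approximately +15, +45, +75, -75, -45 and -15 degrees, together with a
#' real low-pass raster. Level one uses the near-symmetric biorthogonal
#' 5/7 pair applied without decimation (the two trees are the even/odd
#' polyphase components); levels two and up use the orthonormal 14-tap
#' quarter-shift pair with the second tree's filters time-reversed. Level
#' one outputs are scaled by sqrt(2) per dimension so the bank is
#' approximately energy preserving. Boundaries are handled by symmetric
#' extension, and odd-sized rasters are padded by one replicated row or
#' column before each split.
#'
#' The per-level low-pass raster `M_j` is the average of the four trees'
#' scaling-coefficient rasters at level `j`, captured during the recursion
#' so that global low-pass features (for example the mean of the
#' second-level low-pass band) exist at every depth.
#'
#' @param image numeric intensity matrix with both dimensions
#'   `>= 2^levels`.
#' @param levels decomposition depth (default 5).
#' @return Object of class `"dtcwt_subbands"`: a list with `levels`,
#'   `lowpass` (list `M_1..M_J` of real rasters, `M_j` roughly
#'   `dim(image) / 2^j`), `oriented` (per level, a named list of six
#'   complex matrices in the order `r paste(DTCWT_ORIENTATIONS, collapse=", ")`)
#'   and `filter_id`.
#' @examples
#' s <- dtcwt_forward(matrix(rexp(64 * 64), 64), levels = 3)
#' vapply(s$oriented, length, integer(1))  # six subbands per level
#' @export
dtcwt_forward <- function(image, levels = 5) {
  assert_gray_image(image)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  if (min(dim(image)) < 2^levels)
    stop("image dimensions must be >= 2^levels for the requested depth",
         call. = FALSE)
  s2 <- sqrt(2)
  h0 <- NS_H0 * s2
  h1 <- NS_H1 * s2

  X <- .pad_even(image)
  Lo <- .filt_cols(X, h0)
  Hi <- .filt_cols(X, h1)
  bands <- list(LL = .filt_rows(Lo, h0), LH = .filt_rows(Lo, h1),
                HL = .filt_rows(Hi, h0), HH = .filt_rows(Hi, h1))
  pp <- function(M, r, c)
    M[seq(r, nrow(M), 2L), seq(c, ncol(M), 2L), drop = FALSE]
  split4 <- function(M) list(aa = pp(M, 1, 1), ab = pp(M, 1, 2),
                             ba = pp(M, 2, 1), bb = pp(M, 2, 2))

  oriented <- vector("list", levels)
  lowpass <- vector("list", levels)
  tr <- lapply(bands, split4)
  oriented[[1]] <- .assemble_oriented(.tree_pair(tr$LH), .tree_pair(tr$HL),
                                      .tree_pair(tr$HH))
  LLt <- tr$LL
  lowpass[[1]] <- (LLt$aa + LLt$ab + LLt$ba + LLt$bb) / 4

  if (levels > 1L) {
    for (j in 2:levels) {
      LLt <- lapply(LLt, .pad_even)
      newLL <- lh <- hl <- hh <- list()
      for (t in names(LLt)) {
        rt <- substr(t, 1, 1)
        ct <- substr(t, 2, 2)
        h0r <- if (rt == "a") QS_H0A else QS_H0B
        h1r <- if (rt == "a") QS_H1A else QS_H1B
        h0c <- if (ct == "a") QS_H0A else QS_H0B
        h1c <- if (ct == "a") QS_H1A else QS_H1B
        Lo <- .dec_cols(LLt[[t]], h0r)
        Hi <- .dec_cols(LLt[[t]], h1r)
        newLL[[t]] <- .dec_rows(Lo, h0c)
        lh[[t]] <- .dec_rows(Lo, h1c)
        hl[[t]] <- .dec_rows(Hi, h0c)
        hh[[t]] <- .dec_rows(Hi, h1c)
      }
      LLt <- newLL
      oriented[[j]] <- .assemble_oriented(.tree_pair(lh), .tree_pair(hl),
                                          .tree_pair(hh))
      lowpass[[j]] <- (LLt$aa + LLt$ab + LLt$ba + LLt$bb) / 4
    }
  }
  structure(list(levels = levels, lowpass = lowpass, oriented = oriented,
                 filter_id = "nearsym5_7/qshift14"),
            class = "dtcwt_subbands")
}

#' Real-valued rasters from a dual-tree decomposition
#'
#' Returns, in a stable documented order, the `J` low-pass rasters
#' unchanged followed by the element-wise complex magnitudes of the `6 J`
#' oriented subbands. Names follow
#' `{M|D15p|D45p|D75p|D75n|D45n|D15n}{level}`: all low-pass rasters first
#' (`M1..MJ`), then level 1's six orientations, then level 2's, and so on.
#' Magnitude rasters are non-negative by construction; magnitudes rather
#' than real/imaginary parts are used downstream because the magnitude is
#' the near-shift-invariant quantity of the transform.
#'
#' @param s a `"dtcwt_subbands"` object from [dtcwt_forward()].
#' @return Named list of real matrices of length `7 * s$levels`.
#' @export
magnitude_subimages <- function(s) {
  if (!inherits(s, "dtcwt_subbands")) stop("`s` must be a dtcwt_subbands")
  out <- s$lowpass
  names(out) <- paste0("M", seq_len(s$levels))
  for (j in seq_len(s$levels)) {
    m <- lapply(s$oriented[[j]], Mod)
    names(m) <- paste0(DTCWT_ORIENTATIONS, j)
    out <- c(out, m)
  }
  out
}

#' Plain critically-sampled 2D discrete wavelet transform
#'
#' Single-tree separable DWT with the same 5/7 biorthogonal pair at every
#' level (filter + decimate by two). This transform is shift-variant and
#' serves only as the baseline against which the dual-tree transform's
#' shift invariance is measured; it is not used for feature extraction.
#'
#' @param image numeric intensity matrix.
#' @param levels decomposition depth.
#' @return List with per-level `detail` (list of `LH`, `HL`, `HH`
#'   matrices) and the final `lowpass`.
#' @export
dwt_forward <- function(image, levels = 2) {
  assert_gray_image(image)
  if (min(dim(image)) < 2^levels)
    stop("image dimensions must be >= 2^levels", call. = FALSE)
  h0 <- NS_H0 * sqrt(2)
  h1 <- NS_H1 * sqrt(2)
  LL <- image
  detail <- vector("list", levels)
  for (j in seq_len(levels)) {
    LL <- .pad_even(LL)
    Lo <- .dec_cols(LL, h0)
    Hi <- .dec_cols(LL, h1)
    detail[[j]] <- list(LH = .dec_rows(Lo, h1), HL = .dec_rows(Hi, h0),
                        HH = .dec_rows(Hi, h1))
    LL <- .dec_rows(Lo, h0)
  }
  list(detail = detail, lowpass = LL, levels = levels)
}

#' Shift sensitivity of subband magnitude energies
#'
#' Translates the image circularly along rows by `shift_px` pixels and
#' measures the relative change of the per-subband magnitude energies at
#' decomposition level `level`. The metric is
#' `||E_shifted - E_original|| / (0.5 (||E_shifted|| + ||E_original||))`,
#' where `E` collects the L2 norms of each subband's magnitudes; it is 0
#' for a perfectly shift-invariant representation and bounded by 2. Used
#' as a property probe: the dual-tree transform should score well below
#' the critically-sampled DWT on the same image and shift.
#'
#' @param image numeric intensity matrix.
#' @param shift_px integer translation in pixels (>= 0).
#' @param transform `"dtcwt"` or `"dwt"`.
#' @param level decomposition level probed (default 2).
#' @return Single non-negative number in `[0, 2]`.
#' @export
shift_variance_metric <- function(image, shift_px,
                                  transform = c("dtcwt", "dwt"), level = 2) {
  transform <- match.arg(transform)
  shift_px <- as.integer(shift_px)
  if (shift_px < 0) stop("shift_px must be >= 0")
  energies <- function(img) {
    if (transform == "dtcwt") {
      s <- dtcwt_forward(img, levels = level)
      vapply(s$oriented[[level]], function(z) sqrt(sum(Mod(z)^2)), numeric(1))
    } else {
      d <- dwt_forward(img, levels = level)
      vapply(d$detail[[level]], function(b) sqrt(sum(b^2)), numeric(1))
    }
  }
  shifted <- if (shift_px == 0) image else
    image[c((shift_px + 1L):nrow(image), seq_len(shift_px)), , drop = FALSE]
  e0 <- energies(image)
  es <- energies(shifted)
  denom <- 0.5 * (sqrt(sum(e0^2)) + sqrt(sum(es^2)))
  if (denom == 0) return(0)
  sqrt(sum((es - e0)^2)) / denom
}

#' Serialize decomposition rasters to a directory
#'
#' Writes every raster from [magnitude_subimages()] as a 32-bit
#' little-endian float file (`<name>.f32`) plus a JSON index with names and
#' dimensions, enabling a lossless (to float precision) name -> raster ->
#' name round trip.
#'
#' @param s a `"dtcwt_subbands"` object.
#' @param dir output directory (created if missing).
#' @return Invisibly, the index as a list.
#' @export
write_subbands <- function(s, dir) {
  rasters <- magnitude_subimages(s)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  index <- lapply(rasters, dim)
  for (nm in names(rasters)) {
    con <- file(file.path(dir, paste0(nm, ".f32")), "wb")
    writeBin(as.numeric(rasters[[nm]]), con, size = 4, endian = "little")
    close(con)
  }
  jsonlite::write_json(index, file.path(dir, "index.json"), auto_unbox = FALSE)
  invisible(index)
}

#' Read back rasters written by [write_subbands()]
#' @param dir directory containing `index.json` and `.f32` rasters.
#' @return Named list of real matrices in index order.
#' @export
read_subbands <- function(dir) {
  index <- jsonlite::read_json(file.path(dir, "index.json"),
                               simplifyVector = TRUE)
  out <- lapply(names(index), function(nm) {
    d <- as.integer(index[[nm]])
    con <- file(file.path(dir, paste0(nm, ".f32")), "rb")
    v <- readBin(con, numeric(), n = prod(d), size = 4, endian = "little")
    close(con)
    matrix(v, d[1], d[2])
  })
  names(out) <- names(index)
  out
}
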