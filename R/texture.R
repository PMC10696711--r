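#' Split a raster into its top half, bottom half and full extent
#'
#' The top half of an LUS sub-image carries pleural-line content and the
#' bottom half carries A-line/B-line content, so texture features are
#' computed per half. The split uses the floor convention: top gets rows
#' `1..floor(H/2)`, bottom the rest.
#'
#' @param raster numeric matrix with at least 2 rows.
#' @return Named list `top`, `bottom`, `full`.
#' @export
split_rois <- function(raster) {
  if (nrow(raster) < 2L) stop("raster must have at least 2 rows")
  h <- nrow(raster) %/% 2L
  list(top = raster[seq_len(h), , drop = FALSE],
       bottom = raster[(h + 1L):nrow(raster), , drop = FALSE],
       full = raster)
}

#' First-order statistical features of a region
#'
#' Mean, population standard deviation, skewness, excess kurtosis and
#' Shannon entropy of the intensity raster. Skewness and kurtosis are the
#' standardized third/fourth central moments (kurtosis with the normal
#' baseline of 3 subtracted); when the region is constant (zero SD) both
#' are returned as 0 and the `degenerate` attribute is set. Entropy treats
#' the region as a distribution: intensities are divided by their total
#' and `-sum(p log2 p)` is returned with `0 log2 0 := 0` (an all-zero
#' region yields 0).
#'
#' @param roi non-empty numeric matrix or vector.
#' @return Named numeric vector
#'   `mean, sd, skewness, kurtosis, entropy`.
#' @export
statistical_features <- function(roi) {
  x <- as.numeric(roi)
  if (!length(x)) stop("empty ROI")
  n <- length(x)
  m <- mean(x)
  v <- sum((x - m)^2) / n
  s <- sqrt(v)
  if (s > 0) {
    skew <- sum((x - m)^3) / (n * s^3)
    kurt <- sum((x - m)^4) / (n * s^4) - 3
    degen <- FALSE
  } else {
    skew <- kurt <- 0
    degen <- TRUE
  }
  tot <- sum(x)
  ent <- if (tot > 0) entropy_bits(x / tot) else 0
  structure(c(mean = m, sd = s, skewness = skew, kurtosis = kurt,
              entropy = ent), degenerate = degen)
}

#' Quantize a region to L grey levels
#'
#' Equal-width binning spanning `[min(roi), max(roi)]` into `L` levels
#' (default 8, producing 8 x 8 co-occurrence matrices downstream). A
#' constant region maps entirely to level 1.
#'
#' @param roi non-empty numeric matrix.
#' @param L number of grey levels (>= 2).
#' @return Object of class `"quantized_image"`: list with integer matrix
#'   `levels` (values in `1..L`), `L`, and the `L - 1` interior
#'   `bin_edges`.
#' @export
quantize <- function(roi, L = 8) {
  if (!length(roi)) stop("empty ROI")
  L <- as.integer(L)
  if (L < 2L) stop("L must be >= 2")
  lo <- min(roi)
  hi <- max(roi)
  # ranges at rounding-noise scale are degenerate, not texture
  if (hi - lo <= 1e-12 * max(abs(hi), abs(lo), 1)) {
    lev <- matrix(1L, nrow(roi), ncol(roi))
    edges <- rep(NA_real_, L - 1L)
  } else {
    edges <- lo + (seq_len(L - 1L) / L) * (hi - lo)
    lev <- matrix(pmin(L, findInterval(roi, edges) + 1L),
                  nrow(roi), ncol(roi))
  }
  storage.mode(lev) <- "integer"
  structure(list(levels = lev, L = L, bin_edges = edges),
            class = "quantized_image")
}

#' Grey-level co-occurrence matrix for one offset
#'
#' Directional (non-symmetric) counting: the pair `(q[i, j], q[i + dr,
#' j + dc])` is tallied for every in-bounds pixel, so the count total is
#' `(H - |dr|) (W - |dc|)`. The canonical offset set used by the pipeline
#' is `(0,1), (1,0), (0,2), (2,0), (1,1), (2,2)`.
#'
#' @param q a `"quantized_image"`.
#' @param offset integer pair `c(drow, dcol)`.
#' @return Object of class `"glc_matrix"`: list with integer `counts`
#'   (`L x L`), `normalized` (sums to 1), and `offset`.
#' @export
glcm <- function(q, offset) {
  stopifnot(inherits(q, "quantized_image"), length(offset) == 2L)
  dr <- as.integer(offset[1])
  dc <- as.integer(offset[2])
  lev <- q$levels
  H <- nrow(lev)
  W <- ncol(lev)
  if (H <= abs(dr) || W <= abs(dc))
    stop("region smaller than the offset: no pixel pairs", call. = FALSE)
  counts <- cpp_glcm_counts(lev, q$L, dr, dc)
  structure(list(counts = counts, normalized = counts / sum(counts),
                 offset = c(dr, dc)), class = "glc_matrix")
}

#' Haralick-style features of a co-occurrence matrix
#'
#' Contrast, correlation, energy, homogeneity and entropy computed on the
#' normalized matrix. Correlation uses the mean and population variance of
#' the quantized region itself (not the matrix marginals); a zero-variance
#' region returns correlation 0 with the `degenerate` attribute set. The
#' textbook marginal-mean form is available with
#' `correlation = "marginal"`. Entropy uses `0 log2 0 := 0`.
#'
#' @param m a `"glc_matrix"`.
#' @param q the `"quantized_image"` the matrix came from (needed for the
#'   image-level correlation moments).
#' @param correlation `"image"` (default) or `"marginal"`.
#' @return Named numeric vector
#'   `contrast, correlation, energy, homogeneity, entropy`.
#' @export
glcm_features <- function(m, q, correlation = c("image", "marginal")) {
  correlation <- match.arg(correlation)
  P <- m$normalized
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  contrast <- sum((i - j)^2 * P)
  energy <- sum(P^2)
  homogeneity <- sum(P / (1 + (i - j)^2))
  entropy <- entropy_bits(P)
  degen <- FALSE
  if (correlation == "image") {
    x <- as.numeric(q$levels)
    u <- mean(x)
    s2 <- sum((x - u)^2) / length(x)
    if (s2 > 0) corr <- sum((i - u) * (j - u) * P) / s2
    else { corr <- 0; degen <- TRUE }
  } else {
    ui <- sum(i * P); uj <- sum(j * P)
    si <- sqrt(sum((i - ui)^2 * P)); sj <- sqrt(sum((j - uj)^2 * P))
    if (si > 0 && sj > 0) corr <- sum((i - ui) * (j - uj) * P) / (si * sj)
    else { corr <- 0; degen <- TRUE }
  }
  structure(c(contrast = contrast, correlation = corr, energy = energy,
              homogeneity = homogeneity, entropy = entropy),
            degenerate = degen)
}

#' Grey-level run-length matrix for one direction
#'
#' Counts maximal runs of equal grey level along all parallel lines of the
#' region in the given direction (0, 45, 90 or 135 degrees). Every pixel
#' belongs to exactly one maximal run per direction, so
#' `sum(j * R[i, j]) = N`, the pixel count.
#'
#' @param q a `"quantized_image"`.
#' @param direction one of 0, 45, 90, 135 (degrees).
#' @return Object of class `"glrl_matrix"`: list with integer matrix
#'   `runs` (`L x Jmax`, grey level by run length), `direction` and
#'   `n_pixels`.
#' @export
glrlm <- function(q, direction) {
  stopifnot(inherits(q, "quantized_image"))
  if (!direction %in% c(0, 45, 90, 135))
    stop("direction must be one of 0, 45, 90, 135")
  lev <- q$levels
  r <- cpp_runs(lev, as.integer(direction))
  vals <- r$vals
  lens <- r$lens
  jmax <- switch(as.character(direction),
                 "0" = ncol(lev), "90" = nrow(lev),
                 min(nrow(lev), ncol(lev)))
  jmax <- max(jmax, if (length(lens)) max(lens) else 1L)
  runs <- matrix(tabulate((vals - 1L) * jmax + lens, nbins = q$L * jmax),
                 q$L, jmax, byrow = TRUE)
  structure(list(runs = runs, direction = direction,
                 n_pixels = length(lev)), class = "glrl_matrix")
}

GLRLM_FEATURES <- c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
                    "srlge", "srhge", "lrlge", "lrhge")

# Run-length features straight from the (grey level, run length) pairs;
# algebraically identical to glrlm_features() on the assembled matrix but
# without materializing it.
.glrlm_feats_from_runs <- function(vals, lens, L, n_pixels) {
  nr <- length(vals)
  v2 <- as.numeric(vals)^2
  l2 <- as.numeric(lens)^2
  out <- c(sum(1 / l2), sum(l2), sum(tabulate(vals, L)^2),
           sum(tabulate(lens)^2), nr * nr / n_pixels, sum(1 / v2),
           sum(v2), sum(1 / (v2 * l2)), sum(v2 / l2), sum(l2 / v2),
           sum(v2 * l2)) / nr
  names(out) <- GLRLM_FEATURES
  out
}

#' Run-length texture features
#'
#' The eleven classical run-length statistics: short/long run emphasis
#' (SRE, LRE), grey-level and run-length non-uniformity (GLN, RLN), run
#' percentage (RP), low/high grey-level run emphasis (LGRE, HGRE), and
#' the four joint emphases (SRLGE, SRHGE, LRLGE, LRHGE). All denominators
#' are the total run count except RP, which divides by the region's pixel
#' count.
#'
#' @param r a `"glrl_matrix"`.
#' @return Named numeric vector of the 11 features.
#' @export
glrlm_features <- function(r) {
  R <- r$runs
  nr <- sum(R)
  if (nr == 0) stop("run-length matrix holds no runs")
  i2 <- matrix(seq_len(nrow(R))^2, nrow(R), ncol(R))
  j2 <- matrix(rep(seq_len(ncol(R))^2, each = nrow(R)), nrow(R), ncol(R))
  out <- c(
    sre = sum(R / j2) / nr,
    lre = sum(R * j2) / nr,
    gln = sum(rowSums(R)^2) / nr,
    rln = sum(colSums(R)^2) / nr,
    rp = nr / r$n_pixels,
    lgre = sum(R / i2) / nr,
    hgre = sum(R * i2) / nr,
    srlge = sum(R / (i2 * j2)) / nr,
    srhge = sum(R * i2 / j2) / nr,
    lrlge = sum(R * j2 / i2) / nr,
    lrhge = sum(R * i2 * j2) / nr
  )
  names(out) <- GLRLM_FEATURES
  out
}

# Lookup table mapping each 8-bit neighbourhood code to one of 10 bins:
# uniform rotation classes by number of ones (bins 1..9 for 0..8 ones),
# non-uniform patterns in bin 10.
.lbp_lut <- local({
  lut <- integer(256)
  for (code in 0:255) {
    bits <- as.integer(intToBits(code))[1:8]
    trans <- sum(bits != bits[c(2:8, 1)])
    lut[code + 1L] <- if (trans <= 2L) sum(bits) + 1L else 10L
  }
  lut
})

#' Rotation-invariant uniform local binary pattern histogram
#'
#' Each interior pixel's 8 neighbours (radius 1, the 3 x 3 ring) are
#' thresholded against the centre (neighbour >= centre maps to 1) and the
#' resulting circular pattern is classified as one of the 9 uniform
#' rotation classes (at most two 0-1/1-0 transitions; the class is the
#' number of ones) or the single non-uniform catch-all, giving a 10-bin
#' histogram normalized to sum 1. A constant region therefore puts all
#' mass in the all-ones uniform bin.
#'
#' @param roi numeric matrix, at least 3 x 3.
#' @return Numeric vector of length 10
#'   (`u0..u8` then `nonuniform`), summing to 1.
#' @export
lbp_histogram <- function(roi) {
  H <- nrow(roi); W <- ncol(roi)
  if (is.null(H) || H < 3L || W < 3L) stop("ROI must be at least 3 x 3")
  if (!is.double(roi)) storage.mode(roi) <- "double"
  bins <- cpp_lbp_hist(roi, .lbp_lut)
  h <- bins / sum(bins)
  names(h) <- c(paste0("u", 0:8), "nonuni")
  h
}

GLCM_OFFSETS <- list(c(0, 1), c(1, 0), c(0, 2), c(2, 0), c(1, 1), c(2, 2))
GLRLM_DIRECTIONS <- c(0, 45, 90, 135)

#' Feature-extraction configuration
#'
#' @param levels decomposition depth of the dual-tree transform.
#' @param L_quant grey levels for GLCM/GLRLM quantization.
#' @param glcm_offsets list of integer offset pairs.
#' @param glrlm_directions run directions in degrees.
#' @param average_glcm average GLCM features over offsets (and GLRLM over
#'   directions) instead of emitting them per offset/direction.
#' @param glcm_correlation `"image"` or `"marginal"` (see
#'   [glcm_features()]).
#' @param entropy `"sumnorm"` (region normalized to unit sum) or
#'   `"histogram"` (256-bin histogram entropy).
#' @return List of class `"feature_config"`.
#' @export
feature_config <- function(levels = 5, L_quant = 8,
                           glcm_offsets = GLCM_OFFSETS,
                           glrlm_directions = GLRLM_DIRECTIONS,
                           average_glcm = FALSE,
                           glcm_correlation = "image",
                           entropy = c("sumnorm", "histogram")) {
  structure(list(levels = levels, L_quant = L_quant,
                 glcm_offsets = glcm_offsets,
                 glrlm_directions = glrlm_directions,
                 average_glcm = isTRUE(average_glcm),
                 glcm_correlation = glcm_correlation,
                 entropy = match.arg(entropy)),
            class = "feature_config")
}

# All texture features of one region raster, in deterministic order.
.region_features <- function(roi, config) {
  stat <- statistical_features(roi)
  if (config$entropy == "histogram") {
    h <- tabulate(pmin(256L, floor(roi) + 1L), nbins = 256L)
    stat["entropy"] <- entropy_bits(h / sum(h))
  }
  names(stat) <- paste0("stat_", names(stat))
  q <- quantize(pmax(roi, 0), config$L_quant)
  drs <- vapply(config$glcm_offsets, `[`, numeric(1), 1)
  dcs <- vapply(config$glcm_offsets, `[`, numeric(1), 2)
  GL <- cpp_glcm_feats(q$levels, q$L, as.integer(drs), as.integer(dcs),
                       config$glcm_correlation == "image")
  RL <- cpp_glrlm_feats(q$levels, q$L,
                        as.integer(config$glrlm_directions))
  glcm_names <- c("contrast", "correlation", "energy", "homogeneity",
                  "entropy")
  if (config$average_glcm) {
    g <- rowMeans(GL)
    names(g) <- paste0("glcm_", glcm_names)
    r <- rowMeans(RL)
    names(r) <- paste0("glrlm_", GLRLM_FEATURES)
  } else {
    g <- as.numeric(GL)
    names(g) <- as.character(outer(
      glcm_names, sprintf("o%d%d", drs, dcs),
      function(a, b) sprintf("glcm_%s_%s", a, b)))
    r <- as.numeric(RL)
    names(r) <- as.character(outer(
      GLRLM_FEATURES, config$glrlm_directions,
      function(a, b) sprintf("glrlm_%s_d%d", a, b)))
  }
  lbp <- lbp_histogram(roi)
  names(lbp) <- paste0("lbp_", names(lbp))
  c(stat, g, r, lbp)
}

#' Extract the named feature vector of one decomposed image
#'
#' For every raster from [magnitude_subimages()] (the `J` low-pass bands
#' and the `6 J` oriented magnitude bands) and every region -- top and
#' bottom halves for all rasters, plus the full extent for low-pass bands
#' so that global low-pass summaries such as the mean of the second-level
#' low-pass band exist -- the full texture block is computed: 5
#' statistical, 5 GLCM features for each offset, 11 GLRLM features for
#' each direction, and the 10 LBP bins. Low-pass rasters are clipped at 0
#' before quantization-based families. The three clinical covariates are
#' appended last and are never subject to feature selection. Feature names
#' follow `{band}{level}_{region}_{family}_{stat}[_{offset|direction}]`,
#' e.g. `M2_full_stat_mean` or `D45p1_top_glcm_contrast_o01`.
#'
#' @param s a `"dtcwt_subbands"` object.
#' @param meta one-row data frame (or list) with `ga_weeks`,
#'   `cgats_weeks`, `dol_days`.
#' @param config a [feature_config()].
#' @return Named numeric vector; deterministic order and length for a
#'   given configuration.
#' @export
extract_features <- function(s, meta, config = feature_config()) {
  rasters <- magnitude_subimages(s)
  is_lowpass <- grepl("^M", names(rasters))
  out <- vector("list", length(rasters))
  for (k in seq_along(rasters)) {
    nm <- names(rasters)[k]
    rois <- split_rois(rasters[[k]])
    regions <- if (is_lowpass[k]) c("top", "bottom", "full")
               else c("top", "bottom")
    feats <- unlist(lapply(regions, function(rg) {
      v <- .region_features(rois[[rg]], config)
      names(v) <- paste(nm, rg, names(v), sep = "_")
      v
    }))
    out[[k]] <- feats
  }
  v <- unlist(out)
  clin <- c(ga_weeks = as.numeric(meta$ga_weeks),
            cgats_weeks = as.numeric(meta$cgats_weeks),
            dol_days = as.numeric(meta$dol_days))
  c(v, clin)
}

#' Names of the clinical covariate features
#' @export
CLINICAL_FEATURES <- c("ga_weeks", "cgats_weeks", "dol_days")
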