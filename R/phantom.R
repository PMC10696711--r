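#' Synthetic lung-ultrasound phantom specification
#'
#' A `PhantomSpec` bundles the morphology mixture and the clinical-covariate
#' sampling model that define one synthetic pathology class. The defaults in
#' [default_phantom_specs()] follow the canonical morphology-by-pathology
#' grid used in neonatal LUS reading: A-lines with a thin regular pleura for
#' aerated lungs (Normal, PTX), separate B-lines and a double lung point for
#' TTN, a thick irregular pleura with coalescent B-lines for RDS/CLD, and a
#' hypoechoic consolidation with a bright irregular rim for CON.
#'
#' @param class_label one of `r paste(LUS_CLASSES, collapse=", ")`.
#' @param pleura pleural line appearance: `"normal"`, `"thick"` or
#'   `"irregular"`.
#' @param pleura_thickness pleural band thickness in pixels (> 0).
#' @param pleura_gain peak pleural intensity on the 8-bit scale.
#' @param aline_count number of A-line reverberation echoes (>= 0).
#' @param aline_spacing vertical spacing between A-lines in pixels (> 0).
#' @param aline_decay per-echo brightness decay factor in (0, 1].
#' @param bline_mode `"none"`, `"separate"`, `"coalescent"` or `"mixed"`.
#' @param bline_count number of separate B-lines (ignored for `"none"`).
#' @param bline_width B-line full width in pixels (> 0).
#' @param bline_gain peak B-line intensity.
#' @param consolidation logical; render a subpleural consolidation?
#' @param consolidation_size consolidation radius as a fraction of image
#'   height (0, 0.5].
#' @param double_lung_point logical; render A-line texture on one lateral
#'   half and B-line texture on the other (the TTN hallmark).
#' @param speckle_shape Rayleigh scale of the multiplicative speckle field
#'   (the field is mean-normalized after smoothing).
#' @param speckle_smooth integer half-width of the speckle smoothing kernel.
#' @param background baseline echo intensity of the lung field.
#' @param clinical_model list with elements `ga` and `dol`, each a
#'   `c(lo, hi)` uniform sampling range for gestational age (weeks) and days
#'   of life (days). CGATS is derived as `GA + DOL / 7`.
#' @param row_offset,col_offset whole-pixel translation applied to all
#'   rendered structures (used for intra-video frame jitter).
#'
#' @return An object of class `"phantom_spec"` (a validated list).
#' @seealso [render_phantom()], [generate_cohort()]
#' @export
phantom_spec <- function(class_label,
                         pleura = "normal",
                         pleura_thickness = 4,
                         pleura_gain = 230,
                         aline_count = 0,
                         aline_spacing = 70,
                         aline_decay = 0.55,
                         bline_mode = "none",
                         bline_count = 0,
                         bline_width = 10,
                         bline_gain = 170,
                         consolidation = FALSE,
                         consolidation_size = 0.16,
                         double_lung_point = FALSE,
                         speckle_shape = 1,
                         speckle_smooth = 1,
                         background = 12,
                         clinical_model = list(ga = c(24, 41), dol = c(0, 28)),
                         row_offset = 0,
                         col_offset = 0) {
  class_label <- match.arg(class_label, LUS_CLASSES)
  pleura <- match.arg(pleura, c("normal", "thick", "irregular"))
  bline_mode <- match.arg(bline_mode, c("none", "separate", "coalescent", "mixed"))
  geom <- c(pleura_thickness = pleura_thickness, aline_spacing = aline_spacing,
            bline_width = bline_width, pleura_gain = pleura_gain,
            bline_gain = bline_gain, consolidation_size = consolidation_size,
            speckle_shape = speckle_shape, background = background)
  if (any(!is.finite(geom)) || any(geom <= 0))
    stop("all geometric/intensity parameters must be positive and finite",
         call. = FALSE)
  if (aline_count < 0 || bline_count < 0)
    stop("aline_count and bline_count must be >= 0", call. = FALSE)
  if (aline_decay <= 0 || aline_decay > 1)
    stop("aline_decay must lie in (0, 1]", call. = FALSE)
  if (bline_mode %in% c("separate", "mixed") && bline_count < 1)
    stop("separate/mixed B-line modes need bline_count >= 1", call. = FALSE)
  stopifnot(is.list(clinical_model),
            length(clinical_model$ga) == 2L, length(clinical_model$dol) == 2L)
  structure(list(
    class_label = class_label, pleura = pleura,
    pleura_thickness = pleura_thickness, pleura_gain = pleura_gain,
    aline_count = as.integer(aline_count), aline_spacing = aline_spacing,
    aline_decay = aline_decay,
    bline_mode = bline_mode, bline_count = as.integer(bline_count),
    bline_width = bline_width, bline_gain = bline_gain,
    consolidation = isTRUE(consolidation),
    consolidation_size = consolidation_size,
    double_lung_point = isTRUE(double_lung_point),
    speckle_shape = speckle_shape, speckle_smooth = as.integer(speckle_smooth),
    background = background, clinical_model = clinical_model,
    row_offset = as.integer(row_offset), col_offset = as.integer(col_offset)
  ), class = "phantom_spec")
}

#' Default per-class phantom specifications
#'
#' One [phantom_spec()] per pathology class, encoding the morphology grid:
#' \itemize{
#'   \item Normal: thin regular pleura, equidistant A-lines, no B-lines.
#'   \item TTN: regular pleura, separate B-lines, double lung point.
#'   \item PTX: regular pleura with enhanced (brighter, more persistent)
#'     A-lines and no B-lines.
#'   \item RDS: thick irregular pleura, coalescent B-lines, small
#'     subpleural consolidation.
#'   \item CLD: thick irregular pleura, mixed separate/coalescent B-lines,
#'     no consolidation.
#'   \item CON: thick pleura, large consolidation with bright rim, a few
#'     separate B-lines.
#' }
#' Clinical sampling ranges: CLD has low GA (24-28 wk) and high DOL
#' (28-90 d); RDS low GA (24-32 wk) and low DOL (0-7 d); TTN near-term GA
#' (34-41 wk) and DOL 0-3 d; Normal, PTX and CON are uniform over the full
#' GA range, so the clinical triple is uninformative for separating them.
#'
#' @return Named list of `"phantom_spec"` objects in [LUS_CLASSES] order.
#' @export
default_phantom_specs <- function() {
  list(
    Normal = phantom_spec("Normal", pleura = "normal", pleura_thickness = 4,
                          aline_count = 4, aline_spacing = 70,
                          clinical_model = list(ga = c(24, 41), dol = c(0, 28))),
    CLD = phantom_spec("CLD", pleura = "irregular", pleura_thickness = 8,
                       bline_mode = "mixed", bline_count = 3, bline_width = 12,
                       clinical_model = list(ga = c(24, 28), dol = c(28, 90))),
    CON = phantom_spec("CON", pleura = "thick", pleura_thickness = 9,
                       bline_mode = "separate", bline_count = 2,
                       consolidation = TRUE, consolidation_size = 0.2,
                       clinical_model = list(ga = c(24, 41), dol = c(0, 28))),
    PTX = phantom_spec("PTX", pleura = "normal", pleura_thickness = 5,
                       aline_count = 5, aline_spacing = 70, aline_decay = 0.8,
                       clinical_model = list(ga = c(24, 41), dol = c(0, 28))),
    RDS = phantom_spec("RDS", pleura = "irregular", pleura_thickness = 8,
                       bline_mode = "coalescent", bline_width = 80,
                       bline_gain = 150, consolidation = TRUE,
                       consolidation_size = 0.12,
                       clinical_model = list(ga = c(24, 32), dol = c(0, 7))),
    TTN = phantom_spec("TTN", pleura = "normal", pleura_thickness = 4,
                       aline_count = 3, aline_spacing = 70,
                       bline_mode = "separate", bline_count = 4,
                       double_lung_point = TRUE,
                       clinical_model = list(ga = c(34, 41), dol = c(0, 3)))
  )
}

# Gaussian cross-profile vertical band centred at column `centre`.
.bline_band <- function(width_img, centre, half_width, gain) {
  gain * exp(-0.5 * ((seq_len(width_img) - centre) / (half_width / 1.5))^2)
}

#' Render one synthetic LUS frame
#'
#' Draws the morphologies enabled in `spec` on an echo map (brightest
#' structure wins where they overlap), then multiplies by a smoothed
#' Rayleigh speckle field. The same `spec` and `seed` always reproduce the
#' identical image. Layout: a bright horizontal pleural band near the top;
#' A-lines as equidistant horizontal echoes of decaying brightness below
#' it; B-lines as vertical bright bands running from the pleural row to the
#' bottom row (erasing A-lines where they pass); consolidation as a
#' hypoechoic blob with a bright irregular rim directly under the pleura;
#' a double lung point as A-line texture on one lateral half and B-line
#' texture on the other.
#'
#' @param spec a [phantom_spec()].
#' @param height,width output raster size in pixels (both >= 64).
#' @param seed integer seed controlling speckle and structure jitter.
#' @return Numeric `height x width` matrix of non-negative intensities on
#'   the 8-bit scale.
#' @examples
#' img <- render_phantom(default_phantom_specs()$TTN, 128, 96, seed = 1)
#' dim(img)
#' @export
render_phantom <- function(spec, height = 520, width = 420, seed = 1) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  if (height < 64 || width < 64) stop("height and width must be >= 64")
  height <- as.integer(height); width <- as.integer(width)
  with_seed(seed, {
    rows <- seq_len(height); cols <- seq_len(width)
    echo <- matrix(spec$background, height, width)

    p0 <- round(0.13 * height) + spec$row_offset
    th <- spec$pleura_thickness

    # Pleural band: row profile per column; irregular pleura wobbles in
    # depth and thickness.
    if (spec$pleura == "irregular") {
      phase <- stats::runif(1, 0, 2 * pi)
      wob <- 0.012 * height * sin(2 * pi * (cols + spec$col_offset) /
                                    (0.45 * width) + phase)
      thc <- th * (1 + 0.3 * sin(2 * pi * cols / (0.22 * width) + 2 * phase))
    } else {
      wob <- rep(0, width)
      thc <- rep(th, width)
    }
    centre <- p0 + wob
    pleura_prof <- spec$pleura_gain *
      exp(-0.5 * (outer(rows, centre, "-") / rep(thc / 2, each = height))^2)
    echo <- pmax(echo, pleura_prof)

    # Lateral split for the double lung point: A-lines on one half,
    # B-lines on the other.
    split_col <- if (spec$double_lung_point)
      round(width * stats::runif(1, 0.45, 0.55)) else NA_integer_
    aline_cols <- bline_cols <- rep(TRUE, width)
    if (spec$double_lung_point) {
      aline_cols <- cols <= split_col
      bline_cols <- cols > split_col
    }

    # A-lines: horizontal echoes at p0 + k * spacing with decaying gain.
    if (spec$aline_count > 0) {
      amap <- matrix(0, height, width)
      for (k in seq_len(spec$aline_count)) {
        d <- p0 + round(k * spec$aline_spacing)
        if (d > height) next
        gain <- spec$pleura_gain * spec$aline_decay^k
        prof <- gain * exp(-0.5 * ((rows - d) / (max(th, 3) / 2))^2)
        amap <- pmax(amap, matrix(prof, height, width))
      }
      amap[, !aline_cols] <- 0
      echo <- pmax(echo, amap)
    }

    # B-lines: vertical bands from the pleural row to the bottom.
    if (spec$bline_mode != "none") {
      bprof <- rep(0, width)
      usable <- which(bline_cols)
      n_sep <- if (spec$bline_mode %in% c("separate", "mixed"))
        spec$bline_count else 0L
      if (n_sep > 0) {
        at <- usable[round(seq(0.12, 0.88, length.out = n_sep) *
                             length(usable))] +
          round(stats::runif(n_sep, -0.03, 0.03) * length(usable))
        at <- pmin(pmax(at, 1L), width)
        for (ctr in at)
          bprof <- pmax(bprof, .bline_band(width, ctr, spec$bline_width / 2,
                                           spec$bline_gain))
      }
      if (spec$bline_mode %in% c("coalescent", "mixed")) {
        w <- if (spec$bline_mode == "mixed") 0.45 * spec$bline_width * 6
             else spec$bline_width
        ctr <- usable[round(stats::runif(1, 0.3, 0.7) * length(usable))]
        bprof <- pmax(bprof, .bline_band(width, ctr, w / 2,
                                         0.9 * spec$bline_gain))
      }
      bmask <- outer(rows >= p0, bprof > 0.05 * spec$bline_gain, "&")
      bmap <- matrix(bprof, height, width, byrow = TRUE)
      bmap[!bmask] <- 0
      # B-lines erase A-lines: overwrite rather than blend where present.
      echo[bmask] <- pmax(spec$background, bmap[bmask])
      echo <- pmax(echo, bmap)
      # keep the pleura on top of B-line roots
      echo <- pmax(echo, pleura_prof)
    }

    # Consolidation: hypoechoic ellipse with a bright irregular rim.
    if (spec$consolidation) {
      rr <- spec$consolidation_size * height
      rc <- spec$consolidation_size * 1.3 * width
      cr <- p0 + th + rr * stats::runif(1, 1.05, 1.3)
      cc <- width * stats::runif(1, 0.35, 0.65) + spec$col_offset
      d2 <- outer((rows - cr) / rr, rep(1, width))^2 +
        outer(rep(1, height), (cols - cc) / rc)^2
      rim_phase <- stats::runif(1, 0, 2 * pi)
      ang <- atan2(outer(rows - cr, rep(1, width)),
                   outer(rep(1, height), cols - cc))
      rim_r <- 1 + 0.08 * sin(5 * ang + rim_phase)
      inside <- d2 < rim_r^2
      rim <- abs(sqrt(d2) - rim_r) < 0.12
      echo[inside] <- 25
      echo[rim] <- 0.95 * spec$pleura_gain
    }

    # Multiplicative speckle: smoothed Rayleigh field, mean-normalized.
    ray <- matrix(spec$speckle_shape *
                    sqrt(-2 * log(stats::runif(height * width))),
                  height, width)
    k <- spec$speckle_smooth
    if (k > 0) {
      ray <- .box_smooth(ray, k)
    }
    speck <- ray / mean(ray)
    pmin(pmax(echo * speck, 0), 255)
  })
}

# Separable box smoothing with edge replication, window 2k+1.
.box_smooth <- function(x, k) {
  n <- 2L * k + 1L
  pad_r <- x[c(rep(1L, k), seq_len(nrow(x)), rep(nrow(x), k)), , drop = FALSE]
  cs <- apply(pad_r, 2L, cumsum)
  row_sm <- (cs[seq(n, nrow(cs)), , drop = FALSE] -
               rbind(0, cs[seq_len(nrow(cs) - n), , drop = FALSE])) / n
  pad_c <- row_sm[, c(rep(1L, k), seq_len(ncol(x)), rep(ncol(x), k)),
                  drop = FALSE]
  cs <- t(apply(pad_c, 1L, cumsum))
  (cs[, seq(n, ncol(cs)), drop = FALSE] -
      cbind(0, cs[, seq_len(ncol(cs) - n), drop = FALSE])) / n
}

# Draw the clinical covariate triple for one subject of a class.
.draw_clinical <- function(spec) {
  ga <- stats::runif(1, spec$clinical_model$ga[1], spec$clinical_model$ga[2])
  dol <- stats::runif(1, spec$clinical_model$dol[1], spec$clinical_model$dol[2])
  c(ga_weeks = ga, cgats_weeks = ga + dol / 7, dol_days = dol)
}

# Subject-level jitter of continuous geometry parameters.
.jitter_spec <- function(spec) {
  spec$pleura_thickness <- max(2, spec$pleura_thickness + stats::runif(1, -1, 1))
  spec$aline_spacing <- spec$aline_spacing * stats::runif(1, 0.93, 1.07)
  spec$bline_width <- spec$bline_width * stats::runif(1, 0.85, 1.15)
  spec$pleura_gain <- spec$pleura_gain * stats::runif(1, 0.92, 1.08)
  spec$bline_gain <- spec$bline_gain * stats::runif(1, 0.9, 1.1)
  spec$consolidation_size <- spec$consolidation_size * stats::runif(1, 0.9, 1.1)
  spec
}

#' Generate a balanced synthetic LUS cohort
#'
#' Builds `n_subjects_per_class` subjects for each of the six classes; each
#' subject contributes `videos_per_subject` videos (cycling through the six
#' standard lung regions) of `frames_per_video` frames. Frames within one
#' video share the subject-level phantom specification up to a +/- 2 px
#' translation and a fresh speckle realization. Clinical covariates are
#' drawn once per subject from the class's clinical model.
#'
#' @param n_subjects_per_class,videos_per_subject,frames_per_video counts
#'   (all >= 1).
#' @param seed master seed; all randomness derives from it.
#' @param height,width frame size passed to [render_phantom()].
#' @param specs per-class specification list as from
#'   [default_phantom_specs()].
#' @param frame_fun optional callback `function(image, meta_row)`; when
#'   supplied, each rendered frame is passed to it immediately and only the
#'   callback results (plus metadata) are returned, so large cohorts never
#'   reside in memory at once.
#' @return List with `images` (list of matrices, or of `frame_fun` results)
#'   and `meta` (data frame of sample metadata: subject_id, video_id,
#'   frame_index, class_label, lung_region, ga_weeks, cgats_weeks,
#'   dol_days).
#' @examples
#' coh <- generate_cohort(1, 1, 1, seed = 3, height = 64, width = 64)
#' nrow(coh$meta)  # 6 images, one per class
#' @export
generate_cohort <- function(n_subjects_per_class, videos_per_subject,
                            frames_per_video, seed = 1,
                            height = 520, width = 420,
                            specs = default_phantom_specs(),
                            frame_fun = NULL) {
  stopifnot(n_subjects_per_class >= 1, videos_per_subject >= 1,
            frames_per_video >= 1)
  classes <- LUS_CLASSES
  n_total <- n_subjects_per_class * length(classes) * videos_per_subject *
    frames_per_video
  seeds <- derive_seeds(seed, n_total + n_subjects_per_class * length(classes))
  subj_seeds <- seeds[seq_len(n_subjects_per_class * length(classes))]
  frame_seeds <- seeds[-seq_len(n_subjects_per_class * length(classes))]

  images <- vector("list", n_total)
  meta <- vector("list", n_total)
  i <- 0L; si <- 0L
  for (cl in classes) {
    for (s in seq_len(n_subjects_per_class)) {
      si <- si + 1L
      subject_id <- sprintf("S_%s_%02d", cl, s)
      sc <- with_seed(subj_seeds[si],
                      list(spec = .jitter_spec(specs[[cl]]),
                           clin = .draw_clinical(specs[[cl]])))
      sspec <- sc$spec
      clin <- sc$clin
      for (v in seq_len(videos_per_subject)) {
        region <- LUS_REGIONS[(v - 1L) %% length(LUS_REGIONS) + 1L]
        video_id <- sprintf("%s_V%02d_%s", subject_id, v, region)
        for (f in seq_len(frames_per_video)) {
          i <- i + 1L
          fspec <- sspec
          off <- with_seed(frame_seeds[i] %% 100000L,
                           sample(-2:2, 2, replace = TRUE))
          fspec$row_offset <- off[1]
          fspec$col_offset <- off[2]
          img <- render_phantom(fspec, height, width, seed = frame_seeds[i])
          row <- data.frame(subject_id = subject_id, video_id = video_id,
                            frame_index = f - 1L, class_label = cl,
                            lung_region = region,
                            ga_weeks = clin[["ga_weeks"]],
                            cgats_weeks = clin[["cgats_weeks"]],
                            dol_days = clin[["dol_days"]],
                            stringsAsFactors = FALSE)
          meta[[i]] <- row
          images[[i]] <- if (is.null(frame_fun)) img else frame_fun(img, row)
        }
      }
    }
  }
  list(images = images, meta = do.call(rbind, meta))
}
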