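test_that("rendering is deterministic in spec and seed", {
  spec <- default_phantom_specs()$TTN
  a <- render_phantom(spec, 128, 96, seed = 7)
  b <- render_phantom(spec, 128, 96, seed = 7)
  expect_identical(a, b)
  c <- render_phantom(spec, 128, 96, seed = 8)
  expect_false(identical(a, c))
  expect_true(all(a >= 0))
})

test_that("A-lines appear as equidistant horizontal echo maxima", {
  spec <- phantom_spec("Normal", aline_count = 4, aline_spacing = 40,
                       bline_mode = "none")
  img <- render_phantom(spec, 320, 256, seed = 3)
  prof <- rowMeans(img)
  sm <- stats::filter(prof, rep(1 / 5, 5))
  interior <- 5:(length(sm) - 4)
  peaks <- interior[sapply(interior, function(i)
    sm[i] == max(sm[(i - 4):(i + 4)]) && sm[i] > 1.3 * median(prof))]
  peaks <- peaks[c(TRUE, diff(peaks) > 5)]
  pleura <- peaks[1]
  alines <- peaks[peaks > pleura + 10]
  expect_length(alines, 4)
  expect_true(all(abs(diff(alines) - 40) <= 2))
  expect_true(all(abs(alines - (pleura + 40 * 1:4)) <= 2))
})

test_that("default specs follow the morphology-by-pathology grid", {
  sp <- default_phantom_specs()
  expect_named(sp, LUS_CLASSES, ignore.order = TRUE)
  # aerated-lung classes: A-lines, no B-lines for Normal/PTX
  expect_true(sp$Normal$aline_count > 0)
  expect_identical(sp$Normal$bline_mode, "none")
  expect_false(sp$Normal$consolidation)
  expect_identical(sp$PTX$bline_mode, "none")
  expect_false(sp$PTX$consolidation)
  # TTN: separate B-lines, double lung point, no consolidation
  expect_identical(sp$TTN$bline_mode, "separate")
  expect_true(sp$TTN$double_lung_point)
  expect_false(sp$TTN$consolidation)
  # RDS/CLD: abnormal pleura with coalescent-type B-lines
  expect_true(sp$RDS$pleura != "normal" && sp$CLD$pleura != "normal")
  expect_true(sp$RDS$bline_mode %in% c("coalescent", "mixed"))
  expect_true(sp$CLD$bline_mode %in% c("coalescent", "mixed"))
  # consolidation present for CON (and RDS), absent for CLD
  expect_true(sp$CON$consolidation)
  expect_true(sp$RDS$consolidation)
  expect_false(sp$CLD$consolidation)
})

test_that("TTN frames carry B-line texture and CON frames a hypoechoic core", {
  sp <- default_phantom_specs()
  ttn <- render_phantom(sp$TTN, 256, 192, seed = 5)
  # a separate B-line shows as a bright vertical band below the pleura
  lower <- ttn[150:256, ]
  colprof <- colMeans(lower)
  expect_gt(max(colprof), 2.5 * median(colprof))
  con <- render_phantom(sp$CON, 256, 192, seed = 5)
  # consolidation: a dark interior region well below its bright rim
  mid <- con[90:140, 60:130]
  expect_lt(min(rowMeans(mid)), 40)
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec("XXX"), "arg")
  expect_error(phantom_spec("Normal", pleura_thickness = -1), "positive")
  expect_error(phantom_spec("Normal", bline_mode = "separate",
                            bline_count = 0), "bline_count")
  expect_error(render_phantom(default_phantom_specs()$Normal, 32, 32),
               ">= 64")
})

test_that("cohort generation yields the balanced design", {
  coh <- generate_cohort(1, 1, 1, seed = 2, height = 64, width = 64)
  expect_length(coh$images, 6)
  expect_setequal(coh$meta$class_label, LUS_CLASSES)

  coh <- generate_cohort(4, 6, 5, seed = 2, height = 64, width = 64)
  expect_length(coh$images, 720)
  expect_equal(length(unique(coh$meta$subject_id)), 24)
  expect_equal(length(unique(coh$meta$video_id)), 144)
  tab <- table(coh$meta$class_label)
  expect_true(all(tab == 120))
  # clinical invariants
  expect_true(all(coh$meta$cgats_weeks >= coh$meta$ga_weeks))
  expect_true(all(coh$meta$dol_days >= 0))
  expect_true(all(coh$meta$frame_index >= 0))
  expect_true(all(coh$meta$lung_region %in% LUS_REGIONS))
  # class-dependent covariates: CLD late scans at low GA, RDS early scans
  cld <- coh$meta[coh$meta$class_label == "CLD", ]
  rds <- coh$meta[coh$meta$class_label == "RDS", ]
  ttn <- coh$meta[coh$meta$class_label == "TTN", ]
  expect_true(all(cld$ga_weeks <= 28 & cld$dol_days >= 28))
  expect_true(all(rds$ga_weeks <= 32 & rds$dol_days <= 7))
  expect_true(all(ttn$ga_weeks >= 34 & ttn$dol_days <= 3))

  coh2 <- generate_cohort(4, 6, 5, seed = 3, height = 64, width = 64)
  expect_identical(dim(coh$meta), dim(coh2$meta))
  expect_identical(coh$meta[c("subject_id", "video_id", "frame_index",
                              "class_label", "lung_region")],
                   coh2$meta[c("subject_id", "video_id", "frame_index",
                               "class_label", "lung_region")])
  expect_false(identical(coh$images[[1]], coh2$images[[1]]))
})

test_that("frames within a video share the subject spec up to jitter", {
  coh <- generate_cohort(1, 1, 3, seed = 9, height = 128, width = 96)
  v <- coh$meta$video_id == coh$meta$video_id[1]
  imgs <- coh$images[v]
  # same morphology: strong cross-correlation between frames, but fresh
  # speckle: not identical
  expect_false(identical(imgs[[1]], imgs[[2]]))
  expect_gt(cor(as.numeric(imgs[[1]]), as.numeric(imgs[[2]])), 0.7)
})
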