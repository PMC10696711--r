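test_that("split_rois partitions rows with the floor convention", {
  r <- matrix(seq_len(500 * 4), 500, 4)
  sp <- split_rois(r)
  expect_identical(nrow(sp$top), 250L)
  expect_identical(nrow(sp$bottom), 250L)
  r2 <- matrix(seq_len(31 * 3), 31, 3)
  sp2 <- split_rois(r2)
  expect_identical(nrow(sp2$top), 15L)
  expect_identical(nrow(sp2$bottom), 16L)
  expect_identical(rbind(sp2$top, sp2$bottom), sp2$full)
})

test_that("statistical features match hand arithmetic and closed forms", {
  f <- statistical_features(matrix(c(1, 2, 3, 4), 2))
  expect_equal(unname(f["mean"]), 2.5)
  expect_equal(unname(f["sd"]), sqrt(5) / 2, tolerance = 1e-12)  # 1.1180
  expect_equal(unname(f["skewness"]), 0, tolerance = 1e-12)
  # constant region: maximal entropy log2(n m), degenerate moments
  cst <- statistical_features(matrix(3, 8, 4))
  expect_equal(unname(cst["sd"]), 0)
  expect_equal(unname(cst["skewness"]), 0)
  expect_equal(unname(cst["entropy"]), log2(32))
  expect_true(attr(cst, "degenerate"))
  # large-sample Gaussian: excess kurtosis near 0
  set.seed(42)
  g <- statistical_features(matrix(rnorm(1e5), 500))
  expect_lt(abs(g["kurtosis"]), 0.05)
  # permutation invariance
  set.seed(7)
  x <- matrix(runif(64, 1, 9), 8)
  xp <- matrix(sample(x), 8)
  expect_equal(statistical_features(x), statistical_features(xp),
               ignore_attr = TRUE)
})

test_that("statistical features agree with the brute-force oracle", {
  for (i in 1:50) {
    set.seed(3000 + i)
    x <- matrix(runif(256, 0, 255), 16)
    expect_equal(as.numeric(statistical_features(x)),
                 as.numeric(oracle_stats(x)), tolerance = 1e-9)
  }
})

test_that("quantization spans the range in equal-width bins", {
  roi <- matrix(c(0, 0.5 + 0:7, 8 - 1e-9), 2, 5)
  q <- quantize(roi, 8)
  expect_identical(q$levels[1, 1], 1L)
  expect_identical(q$levels[2, 5], 8L)
  # with range [0, 8) the mapping is floor(v) + 1
  expect_identical(as.integer(q$levels[c(2, 3, 4, 5)]),
                   as.integer(floor(roi[c(2, 3, 4, 5)]) + 1))
  cst <- quantize(matrix(4, 3, 3), 8)
  expect_true(all(cst$levels == 1L))
  set.seed(1)
  qq <- quantize(matrix(rnorm(100), 10), 8)
  expect_true(all(qq$levels >= 1 & qq$levels <= 8))
  expect_true(all(diff(qq$bin_edges) > 0))
})

test_that("co-occurrence counts match hand enumeration", {
  q <- quantize(matrix(c(1, 2, 1, 2), 2), 2)  # levels [[1,1],[2,2]]
  expect_identical(unname(q$levels), matrix(c(1L, 2L, 1L, 2L), 2))
  g01 <- glcm(q, c(0, 1))
  expect_identical(g01$counts[1, 1], 1L)
  expect_identical(g01$counts[2, 2], 1L)
  expect_identical(sum(g01$counts), 2L)
  g10 <- glcm(q, c(1, 0))
  expect_identical(g10$counts[1, 2], 2L)
  expect_identical(sum(g10$counts), 2L)
  # pair-count identity on a random raster for all canonical offsets
  set.seed(2)
  q2 <- quantize(matrix(runif(15 * 11), 15, 11), 8)
  for (off in list(c(0, 1), c(1, 0), c(0, 2), c(2, 0), c(1, 1), c(2, 2))) {
    m <- glcm(q2, off)
    expect_equal(sum(m$counts), (15 - off[1]) * (11 - off[2]))
    expect_equal(sum(m$normalized), 1, tolerance = 1e-9)
  }
  expect_error(glcm(quantize(matrix(1:2, 1), 2), c(1, 0)), "pairs")
})

test_that("co-occurrence features match hand values and bounds", {
  q <- quantize(matrix(c(1, 2, 1, 2), 2), 2)
  f <- glcm_features(glcm(q, c(0, 1)), q)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["homogeneity"]), 1)
  expect_equal(unname(f["energy"]), 0.5)
  expect_equal(unname(f["entropy"]), 1)
  set.seed(3)
  q2 <- quantize(matrix(runif(144), 12), 8)
  f2 <- glcm_features(glcm(q2, c(1, 1)), q2)
  expect_gt(f2["energy"], 0); expect_lte(f2["energy"], 1)
  expect_gt(f2["homogeneity"], 0); expect_lte(f2["homogeneity"], 1)
  # identity-like matrix: all mass on the diagonal -> zero contrast
  qd <- quantize(matrix(rep(c(1, 5), each = 8), 4), 8)
  fd <- glcm_features(glcm(qd, c(1, 0)), qd)
  expect_equal(unname(fd["contrast"]), 0)
})

test_that("run-length matrices count maximal collinear runs", {
  q <- quantize(matrix(c(1, 1, 2, 2, 2), 1), 2)
  r <- glrlm(q, 0)
  expect_identical(r$runs[1, 2], 1L)
  expect_identical(r$runs[2, 3], 1L)
  expect_identical(sum(r$runs), 2L)
  cst <- quantize(matrix(1, 4, 4), 8)
  r2 <- glrlm(cst, 0)
  expect_identical(r2$runs[1, 4], 4L)
  # run partition identity in every direction
  set.seed(4)
  q3 <- quantize(matrix(runif(13 * 9), 13, 9), 4)
  for (d in c(0, 45, 90, 135)) {
    r3 <- glrlm(q3, d)
    expect_identical(sum(r3$runs *
                           rep(seq_len(ncol(r3$runs)),
                               each = nrow(r3$runs))),
                     13L * 9L)
  }
})

test_that("run-length features match the printed arithmetic", {
  # runs {(level 1, len 2): 1, (level 2, len 3): 1}, N = 5
  q <- quantize(matrix(c(1, 1, 2, 2, 2), 1), 2)
  f <- glrlm_features(glrlm(q, 0))
  expect_equal(unname(f["sre"]), (1 / 4 + 1 / 9) / 2, tolerance = 1e-12)
  expect_equal(unname(f["lre"]), 6.5)
  expect_equal(unname(f["rp"]), 0.4)
  # single run of length 1 at level 1: degenerate identities
  f1 <- glrlm_features(glrlm(quantize(matrix(5, 1, 1), 8), 0))
  expect_equal(unname(f1[c("sre", "lre", "lgre", "hgre")]), rep(1, 4))
  # SRE <= 1 <= LRE always
  set.seed(5)
  f2 <- glrlm_features(glrlm(quantize(matrix(runif(100), 10), 8), 45))
  expect_lte(f2["sre"], 1)
  expect_gte(f2["lre"], 1)
})

test_that("LBP histogram has ten bins, sums to one, constant maps to u8", {
  h <- lbp_histogram(matrix(7, 5, 5))
  expect_length(h, 10)
  expect_equal(sum(h), 1)
  expect_equal(unname(h["u8"]), 1)  # neighbours >= centre everywhere
  set.seed(6)
  h2 <- lbp_histogram(matrix(runif(15 * 17), 15, 17))
  expect_equal(sum(h2), 1, tolerance = 1e-12)
  expect_error(lbp_histogram(matrix(1, 2, 5)), "3 x 3")
})

test_that("texture families equal brute-force oracles on random rasters", {
  for (i in 1:50) {
    set.seed(4000 + i)
    x <- matrix(runif(256, 0, 255), 16, 16)
    q <- quantize(x, 8)
    for (off in list(c(0, 1), c(2, 0), c(1, 1))) {
      G <- glcm(q, off)
      expect_identical(G$counts,
                       oracle_glcm_counts(q$levels, 8, off[1], off[2]))
      expect_equal(as.numeric(glcm_features(G, q)),
                   as.numeric(oracle_glcm_features(G$counts, q$levels)),
                   tolerance = 1e-9)
    }
    for (d in c(0, 45, 90, 135)) {
      R <- glrlm(q, d)
      RO <- oracle_glrlm(q$levels, 8, d)
      expect_identical(R$runs[, seq_len(ncol(RO))], RO)
      expect_equal(as.numeric(glrlm_features(R)),
                   as.numeric(oracle_glrlm_features(RO, 256)),
                   tolerance = 1e-9)
    }
    expect_equal(as.numeric(lbp_histogram(x)),
                 as.numeric(oracle_lbp_hist(x)), tolerance = 1e-12)
  }
})

test_that("GLCM and GLRLM respond to pixel arrangement, not just values", {
  img <- matrix(rep(c(0, 255), each = 32), 8, 8)  # two vertical blocks
  set.seed(8)
  prm <- matrix(sample(img), 8, 8)
  qa <- quantize(img, 8); qb <- quantize(prm, 8)
  expect_false(isTRUE(all.equal(
    as.numeric(glcm_features(glcm(qa, c(0, 1)), qa)),
    as.numeric(glcm_features(glcm(qb, c(0, 1)), qb)))))
  expect_false(isTRUE(all.equal(
    as.numeric(glrlm_features(glrlm(qa, 90))),
    as.numeric(glrlm_features(glrlm(qb, 90))))))
})

test_that("the assembled feature vector is named, complete and consistent", {
  set.seed(9)
  img <- matrix(runif(256 * 224, 0, 255), 256, 224)
  s <- dtcwt_forward(img, levels = 3)
  meta <- list(ga_weeks = 30, cgats_weeks = 31, dol_days = 7)
  fv <- extract_features(s, meta, feature_config(levels = 3))
  # 21 rasters x 2 regions + 3 low-pass full regions, 89 features each
  expect_length(fv, (21 * 2 + 3) * 89 + 3)
  expect_false(anyDuplicated(names(fv)) > 0)
  expect_identical(tail(names(fv), 3),
                   c("ga_weeks", "cgats_weeks", "dol_days"))
  # M2 full-region mean is the plain mean of the level-2 low-pass raster
  expect_equal(unname(fv["M2_full_stat_mean"]), mean(s$lowpass[[2]]))
  # spot-check one oriented band against the standalone operations
  m <- magnitude_subimages(s)
  top <- split_rois(m$D45p1)$top
  q <- quantize(pmax(top, 0), 8)
  expect_equal(unname(fv["D45p1_top_glcm_contrast_o01"]),
               unname(glcm_features(glcm(q, c(0, 1)), q)["contrast"]))
  expect_equal(unname(fv["D45p1_top_glrlm_sre_d90"]),
               unname(glrlm_features(glrlm(q, 90))["sre"]))
  expect_equal(unname(fv["D45p1_top_stat_mean"]), mean(top))
  # identical call -> identical names and values
  fv2 <- extract_features(s, meta, feature_config(levels = 3))
  expect_identical(fv, fv2)
})

test_that("constant input propagates to degenerate texture features", {
  s <- dtcwt_forward(matrix(42, 256, 224), levels = 3)
  fv <- extract_features(s, list(ga_weeks = 1, cgats_weeks = 1,
                                 dol_days = 0),
                         feature_config(levels = 3))
  expect_true(all(abs(fv[grep("stat_sd$", names(fv))]) < 1e-9))
  expect_true(all(abs(fv[grep("glcm_contrast", names(fv))]) < 1e-9))
})
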