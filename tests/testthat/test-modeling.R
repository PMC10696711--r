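# Build a feature table with a planted informative feature and noise.
make_table <- function(n = 300, p = 20, seed = 1, planted = "f2",
                       noise = 1e-4) {
  set.seed(seed)
  labs <- sample(LUS_CLASSES, n, TRUE)
  m <- matrix(rnorm(n * p), n, p)
  colnames(m) <- paste0("f", seq_len(p))
  if (!is.null(planted))
    m[, planted] <- as.integer(factor(labs, levels = LUS_CLASSES)) +
      rnorm(n, 0, noise)
  m <- cbind(m, ga_weeks = runif(n, 24, 41), cgats_weeks = runif(n, 24, 45),
             dol_days = runif(n, 0, 60))
  feature_table(m, labels = labs, groups = paste0("s", seq_len(n) %% 24))
}

test_that("chi-square ranking finds planted dependence and ignores noise", {
  t <- make_table(n = 600, seed = 11)
  r <- chi2_rank(t)
  expect_s3_class(r, "ranked_features")
  expect_identical(r$name[1], "f2")
  expect_lt(r$p_value[1], 1e-10)
  expect_true(!is.unsorted(r$p_value))
  expect_true(all(r$p_value >= 0 & r$p_value <= 1))
  # clinical features never enter the ranking
  expect_false(any(CLINICAL_FEATURES %in% r$name))
})

test_that("constant features get p = 1 and rank last", {
  t <- make_table(n = 200, seed = 12)
  t$matrix[, "f5"] <- 3.14
  r <- chi2_rank(t)
  expect_identical(r$name[nrow(r)], "f5")
  expect_identical(r$p_value[nrow(r)], 1)
  one_class <- feature_table(t$matrix[t$labels == "TTN", , drop = FALSE],
                             labels = t$labels[t$labels == "TTN"],
                             groups = t$groups[t$labels == "TTN"])
  expect_error(chi2_rank(one_class), "two classes")
})

test_that("ranking agrees with stats::chisq.test per feature", {
  t <- make_table(n = 240, seed = 13)
  r <- chi2_rank(t)
  for (nm in c("f1", "f2", "f7")) {
    x <- t$matrix[, nm]
    e <- unique(stats::quantile(x, (1:9) / 10, type = 7))
    b <- findInterval(x, e)
    ct <- suppressWarnings(stats::chisq.test(table(b, t$labels)))
    expect_equal(r$statistic[r$name == nm], unname(ct$statistic),
                 tolerance = 1e-9)
    expect_equal(r$p_value[r$name == nm], unname(ct$p.value),
                 tolerance = 1e-9)
  }
})

test_that("the compiled fold ranking equals the reference ranking", {
  t <- make_table(n = 150, p = 60, seed = 14)
  train <- setdiff(seq_len(150), c(3, 77, 120))
  slow <- chi2_rank(neolus:::.ft_subset(t, rows = train))
  prep <- neolus:::.cv_prep(t)
  mask <- rep(FALSE, 150); mask[train] <- TRUE
  sc <- neolus:::cpp_chi2_scan(prep$Ximg, prep$ord, as.integer(t$labels),
                               mask, 10L, 6L)
  pv <- ifelse(sc$df > 0, stats::pchisq(sc$stat, sc$df,
                                        lower.tail = FALSE), 1)
  fast_names <- colnames(prep$Ximg)[order(pv, seq_along(pv))]
  expect_identical(fast_names, slow$name)
  expect_equal(sort(pv), slow$p_value, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("withholding rows changes the ranking of a leaky feature", {
  # planted leak: feature encodes the class only in the held-out rows
  set.seed(15)
  n <- 120
  labs <- rep(LUS_CLASSES, each = 20)
  m <- matrix(rnorm(n * 10), n, 10)
  colnames(m) <- paste0("f", 1:10)
  test_rows <- seq(1, n, by = 4)
  m[test_rows, "f3"] <- 50 * as.integer(factor(labs[test_rows],
                                               levels = LUS_CLASSES))
  m <- cbind(m, ga_weeks = 30, cgats_weeks = 31, dol_days = 1)
  t <- feature_table(m, labs, paste0("s", seq_len(n) %% 12))
  with_leak <- chi2_rank(t)
  without <- chi2_rank(neolus:::.ft_subset(t, rows = -test_rows))
  expect_lt(which(with_leak$name == "f3"), 3)
  expect_gt(which(without$name == "f3"), 3)
})

test_that("top-k selection keeps clinical features outside the budget", {
  t <- make_table(n = 200, p = 40, seed = 16)
  r <- chi2_rank(t)
  sel <- select_top_k(r, k = 15, t)
  expect_identical(ncol(sel$matrix), 18L)
  expect_true(all(CLINICAL_FEATURES %in% sel$names))
  expect_identical(sum(sel$clinical_mask), 3L)
  all_sel <- select_top_k(r, k = 40, t)
  expect_setequal(all_sel$names, t$names)
  expect_error(select_top_k(r, k = 0, t), "k must")
  expect_error(select_top_k(r, k = 41, t), "exceeds")
})

test_that("p-value ties break by original column order", {
  set.seed(17)
  n <- 60
  labs <- rep(LUS_CLASSES, each = 10)
  m <- cbind(a = rep(1, n), b = rep(2, n), c = rnorm(n),
             ga_weeks = 1, cgats_weeks = 1, dol_days = 1)
  t <- feature_table(m, labs, paste0("s", 1:n))
  r <- chi2_rank(t)
  # both constants tie at p = 1; 'a' precedes 'b'
  expect_identical(r$name[r$p_value == 1], c("a", "b"))
})

test_that("equal-covariance LDA puts the boundary midway between means", {
  set.seed(18)
  n <- 500
  x <- c(rnorm(n, 0), rnorm(n, 10))
  labs <- rep(c("Normal", "TTN"), each = n)
  m <- cbind(f1 = x, ga_weeks = 30, cgats_weeks = 31, dol_days = 1)
  t <- feature_table(m, labs, paste0("s", seq_len(2 * n)))
  fit <- suppressWarnings(fit_lda(t, "equal"))
  grid <- seq(4, 6, by = 0.01)
  nd <- cbind(f1 = grid, ga_weeks = 30, cgats_weeks = 31, dol_days = 1)
  pr <- predict(fit, nd)$class
  flip <- grid[max(which(pr == "Normal"))]
  expect_lt(abs(flip - 5), 0.2)
})

test_that("empirical priors reproduce the cohort class shares", {
  cnt <- c(Normal = 185, CLD = 180, CON = 305, PTX = 105, RDS = 245,
           TTN = 530)
  labs <- rep(names(cnt), cnt)
  set.seed(19)
  m <- cbind(f1 = rnorm(sum(cnt)) +
               as.integer(factor(labs, levels = LUS_CLASSES)),
             ga_weeks = 30, cgats_weeks = 31, dol_days = 1)
  t <- feature_table(m, labs, paste0("s", seq_along(labs)))
  fit <- suppressWarnings(fit_lda(t, "empirical"))
  expect_equal(unname(fit$priors["TTN"]), 530 / 1550)
  expect_equal(sum(fit$priors), 1)
  eq <- suppressWarnings(fit_lda(t, "equal"))
  expect_equal(unname(eq$priors["CLD"]), 1 / 6)
})

test_that("separable training data is fit perfectly", {
  set.seed(20)
  labs <- rep(LUS_CLASSES, each = 30)
  m <- cbind(f1 = 20 * as.integer(factor(labs, levels = LUS_CLASSES)) +
               rnorm(180),
             f2 = rnorm(180), ga_weeks = 30, cgats_weeks = 31,
             dol_days = 1)
  t <- feature_table(m, labs, paste0("s", 1:180))
  fit <- fit_lda(t, "equal")
  pr <- predict(fit, t$matrix)$class
  expect_identical(as.character(pr), as.character(t$labels))
})

test_that("boosting a prior flips a borderline prediction", {
  set.seed(21)
  n <- 200
  labs <- rep(c("Normal", "TTN"), each = n)
  m <- cbind(f1 = c(rnorm(n, 0), rnorm(n, 4)), ga_weeks = 30,
             cgats_weeks = 31, dol_days = 1)
  t <- feature_table(m, labs, paste0("s", seq_len(2 * n)))
  eq <- suppressWarnings(fit_lda(t, "equal"))
  # inflate the TTN prior by duplicating its rows -> empirical priors
  dup <- c(seq_len(2 * n), which(labs == "TTN"), which(labs == "TTN"))
  t2 <- neolus:::.ft_subset(t, rows = dup)
  emp <- suppressWarnings(fit_lda(t2, "empirical"))
  mid <- cbind(f1 = 2, ga_weeks = 30, cgats_weeks = 31, dol_days = 1)
  expect_identical(as.character(predict(eq, mid)$class), "Normal")
  expect_identical(as.character(predict(emp, mid)$class), "TTN")
})

test_that("predictions are invariant to feature-wise affine rescaling", {
  t <- make_table(n = 240, p = 6, seed = 22, planted = NULL)
  t$matrix[, "f1"] <- t$matrix[, "f1"] +
    0.8 * as.integer(factor(t$labels, levels = LUS_CLASSES))
  fit <- suppressWarnings(fit_lda(t, "equal"))
  p1 <- predict(fit, t$matrix)$class
  t2 <- t
  t2$matrix[, "f1"] <- 1000 * t2$matrix[, "f1"] + 77
  fit2 <- suppressWarnings(fit_lda(t2, "equal"))
  p2 <- predict(fit2, t2$matrix)$class
  expect_identical(p1, p2)
})

test_that("predictions agree with MASS::lda on well-conditioned data", {
  skip_if_not_installed("MASS")
  set.seed(23)
  n <- 120
  labs <- rep(c("Normal", "RDS", "TTN"), each = n)
  m <- matrix(rnorm(3 * n * 4), ncol = 4)
  m[labs == "RDS", 1] <- m[labs == "RDS", 1] + 2.5
  m[labs == "TTN", 2] <- m[labs == "TTN", 2] + 2.5
  colnames(m) <- paste0("f", 1:4)
  mm <- cbind(m, ga_weeks = 30, cgats_weeks = 31, dol_days = 1)
  t <- feature_table(mm, labs, paste0("s", seq_along(labs)))
  fit <- suppressWarnings(fit_lda(t, "equal"))
  ours <- predict(fit, t$matrix)$class
  ref <- MASS::lda(m, grouping = factor(labs),
                   prior = rep(1 / 3, 3))
  theirs <- predict(ref, m)$class
  expect_gt(mean(as.character(ours) == as.character(theirs)), 0.99)
})

test_that("models survive a JSON round trip", {
  t <- make_table(n = 120, p = 5, seed = 24)
  fit <- suppressWarnings(fit_lda(t, "empirical"))
  path <- withr::local_tempfile(fileext = ".json")
  save_lda_model(fit, path)
  back <- load_lda_model(path)
  expect_equal(back$means, fit$means, tolerance = 1e-12)
  expect_equal(back$priors, fit$priors, tolerance = 1e-12)
  p1 <- predict(fit, t$matrix)$class
  p2 <- predict(back, t$matrix)$class
  expect_identical(p1, p2)
})
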