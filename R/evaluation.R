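#' Overall accuracy and weighted F1 from a confusion matrix
#'
#' Rows are true classes, columns predicted. Accuracy is
#' `100 * trace / total`. Per-class precision comes from columns, recall
#' from rows, `F1 = 2PR / (P + R)` (0 when undefined), and the weighted F1
#' averages per-class F1 values with weights proportional to each class's
#' true count.
#'
#' @param counts square non-negative count matrix (rows = true classes).
#' @return List with `overall_accuracy` (percent), `weighted_f1`, and a
#'   per-class data frame `per_class` (precision, recall, f1, support).
#' @export
metrics_from_confusion <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("confusion matrix must be square")
  if (any(counts < 0)) stop("confusion matrix entries must be >= 0")
  total <- sum(counts)
  if (total == 0) stop("confusion matrix is empty")
  tp <- diag(counts)
  support <- rowSums(counts)
  predicted <- colSums(counts)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(overall_accuracy = 100 * sum(tp) / total,
       weighted_f1 = sum(support / total * f1),
       per_class = data.frame(class = rownames(counts) %||%
                                as.character(seq_len(nrow(counts))),
                              precision = precision, recall = recall,
                              f1 = f1, support = support,
                              row.names = NULL))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reconstruct confusion counts from printed row percentages
#'
#' Published confusion matrices are printed as row percentages rounded to
#' two decimals. Given those percentages and the known per-class totals,
#' this rounds each cell to the nearest count and then repairs every row
#' to its exact total by the largest-remainder rule, which is the integer
#' matrix closest to the printed cells.
#'
#' @param rowpct matrix of row percentages (each row sums to ~100).
#' @param row_totals integer vector of true-class sample counts.
#' @return Integer count matrix with `rowSums == row_totals`.
#' @export
counts_from_rowpct <- function(rowpct, row_totals) {
  rowpct <- as.matrix(rowpct)
  stopifnot(nrow(rowpct) == length(row_totals))
  out <- matrix(0L, nrow(rowpct), ncol(rowpct),
                dimnames = dimnames(rowpct))
  for (r in seq_len(nrow(rowpct))) {
    x <- rowpct[r, ] * row_totals[r] / 100
    base <- floor(x)
    rem <- x - base
    deficit <- row_totals[r] - sum(base)
    if (deficit > 0) {
      add <- order(rem, decreasing = TRUE)[seq_len(deficit)]
      base[add] <- base[add] + 1
    } else if (deficit < 0) {
      sub <- order(rem)[seq_len(-deficit)]
      base[sub] <- base[sub] - 1
    }
    out[r, ] <- as.integer(base)
  }
  out
}

# Precompute the per-column global sort order of the image features once
# per table; each fold's training-only quantile binning walks this order.
.cv_prep <- function(t) {
  img_cols <- which(!t$clinical_mask)
  Ximg <- t$matrix[, img_cols, drop = FALSE]
  list(img_cols = img_cols, Ximg = Ximg,
       ord = apply(Ximg, 2L, order))
}

# Shared per-fold protocol: rank on training rows only, keep the top-k
# image features plus clinical, fit, predict the held-out rows. Produces
# the same ranking as chi2_rank() on the training subset.
.cv_fold <- function(t, prep, train, test, k, priors_mode, n_bins) {
  y <- as.integer(t$labels)
  mask <- rep(FALSE, nrow(t$matrix))
  mask[train] <- TRUE
  if (nlevels(droplevels(t$labels[train])) <
      nlevels(droplevels(t$labels)))
    warning("a class is absent from this training fold", call. = FALSE)
  sc <- cpp_chi2_scan(prep$Ximg, prep$ord, y, mask, as.integer(n_bins),
                      nlevels(t$labels))
  pval <- ifelse(sc$df > 0,
                 stats::pchisq(sc$stat, sc$df, lower.tail = FALSE), 1)
  top <- order(pval, seq_along(pval))[seq_len(k)]
  cols <- c(prep$img_cols[top], which(t$clinical_mask))
  tr <- .ft_subset(t, rows = train, cols = cols)
  fit <- suppressWarnings(fit_lda(tr, priors_mode = priors_mode))
  te <- .ft_subset(t, rows = test, cols = cols)
  pred <- predict(fit, te$matrix)
  list(pred = pred$class, selected = tr$names[!tr$clinical_mask])
}

.cv_report <- function(scheme, t, predicted, k, priors_mode, selected) {
  truth <- t$labels
  counts <- table(true = truth, predicted = factor(predicted,
                                                   levels = LUS_CLASSES))
  counts <- unclass(counts)
  met <- metrics_from_confusion(counts)
  structure(list(scheme = scheme, predicted = predicted, truth = truth,
                 confusion_counts = counts,
                 confusion_rowpct = 100 * counts /
                   pmax(1, rowSums(counts)),
                 overall_accuracy = met$overall_accuracy,
                 weighted_f1 = met$weighted_f1,
                 per_class = met$per_class,
                 selected_features = selected,
                 k = k, priors_mode = priors_mode),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%s cross-validation: %d samples, k = %d, priors = %s\n",
              x$scheme, length(x$truth), x$k, x$priors_mode))
  cat(sprintf("overall accuracy: %.2f%%   weighted F1: %.3f\n",
              x$overall_accuracy, x$weighted_f1))
  cat("confusion (row %):\n")
  print(round(x$confusion_rowpct, 2))
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' One fold per image: feature ranking, top-k selection, standardization
#' and LDA fitting are all redone on the training rows of every fold so
#' no information from the held-out image leaks into selection.
#'
#' @param t a [feature_table()].
#' @param k image features kept per fold (default 15).
#' @param priors_mode `"equal"` or `"empirical"`.
#' @param n_bins quantile bins for the chi-square ranking.
#' @param progress print a dot every 50 folds.
#' @return A `"cv_report"`: per-sample predictions, count and
#'   row-percentage confusion matrices, overall accuracy (percent),
#'   weighted F1 and the per-fold selected features.
#' @export
run_loo_cv <- function(t, k = 15, priors_mode = c("equal", "empirical"),
                       n_bins = 10, progress = FALSE) {
  priors_mode <- match.arg(priors_mode)
  n <- nrow(t$matrix)
  if (n < 2L) stop("need at least two samples")
  prep <- .cv_prep(t)
  predicted <- factor(rep(NA_character_, n), levels = LUS_CLASSES)
  selected <- vector("list", n)
  for (i in seq_len(n)) {
    f <- .cv_fold(t, prep, train = setdiff(seq_len(n), i), test = i,
                  k = k, priors_mode = priors_mode, n_bins = n_bins)
    predicted[i] <- f$pred
    selected[[i]] <- f$selected
    if (progress && i %% 50L == 0L) cat(".")
  }
  if (progress) cat("\n")
  .cv_report("LOO", t, predicted, k, priors_mode, selected)
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: every image of the held-out subject is predicted
#' by a model trained on all other subjects' images, removing subject
#' bias. Accuracy is computed over all images under this subject-wise
#' folding. A class contributed by a single subject cannot be learned in
#' its own fold; a warning is raised and the fold proceeds.
#'
#' @inheritParams run_loo_cv
#' @return A `"cv_report"` (see [run_loo_cv()]).
#' @export
run_loso_cv <- function(t, k = 15, priors_mode = c("equal", "empirical"),
                        n_bins = 10, progress = FALSE) {
  priors_mode <- match.arg(priors_mode)
  subjects <- unique(t$groups)
  if (length(subjects) < 2L) stop("need at least two subjects")
  n <- nrow(t$matrix)
  prep <- .cv_prep(t)
  predicted <- factor(rep(NA_character_, n), levels = LUS_CLASSES)
  selected <- vector("list", length(subjects))
  for (s in seq_along(subjects)) {
    test <- which(t$groups == subjects[s])
    f <- .cv_fold(t, prep, train = which(t$groups != subjects[s]),
                  test = test, k = k, priors_mode = priors_mode,
                  n_bins = n_bins)
    predicted[test] <- f$pred
    selected[[s]] <- f$selected
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  .cv_report("LOSO", t, predicted, k, priors_mode, selected)
}

#' Accuracy as a function of the number of selected features
#'
#' Re-runs the full cross-validation (per-fold ranking included) for each
#' candidate `k` and returns the accuracy curve.
#'
#' @param t a [feature_table()].
#' @param k_values ascending vector of feature counts.
#' @param scheme `"loo"` or `"loso"`.
#' @param priors_mode `"equal"` or `"empirical"`.
#' @return Data frame with columns `k`, `overall_accuracy`,
#'   `weighted_f1`.
#' @export
sweep_feature_count <- function(t, k_values, scheme = c("loso", "loo"),
                                priors_mode = c("equal", "empirical")) {
  scheme <- match.arg(scheme)
  priors_mode <- match.arg(priors_mode)
  if (!length(k_values) || is.unsorted(k_values))
    stop("k_values must be a non-empty ascending vector")
  runner <- if (scheme == "loo") run_loo_cv else run_loso_cv
  rows <- lapply(k_values, function(k) {
    rep <- runner(t, k = k, priors_mode = priors_mode)
    data.frame(k = k, overall_accuracy = rep$overall_accuracy,
               weighted_f1 = rep$weighted_f1)
  })
  do.call(rbind, rows)
}
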