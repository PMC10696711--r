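#' Assemble a feature table
#'
#' Container tying the feature matrix to per-row sample identity. Clinical
#' covariates are flagged so that ranking and selection never touch them.
#'
#' @param matrix numeric `n x p` matrix with unique column names.
#' @param labels class label per row (character or factor; levels from
#'   [LUS_CLASSES]).
#' @param groups subject identifier per row (character).
#' @param clinical_mask logical vector of length `p`; defaults to marking
#'   the [CLINICAL_FEATURES] columns.
#' @return Object of class `"feature_table"`.
#' @export
feature_table <- function(matrix, labels, groups,
                          clinical_mask = colnames(matrix) %in%
                            CLINICAL_FEATURES) {
  stopifnot(is.matrix(matrix), nrow(matrix) == length(labels),
            nrow(matrix) == length(groups),
            length(clinical_mask) == ncol(matrix))
  if (anyNA(matrix)) stop("feature matrix contains missing values")
  if (is.null(colnames(matrix)) || anyDuplicated(colnames(matrix)))
    stop("feature matrix needs unique column names")
  labels <- factor(as.character(labels), levels = LUS_CLASSES)
  if (anyNA(labels)) stop("labels outside the six-class enum")
  structure(list(matrix = matrix, names = colnames(matrix),
                 labels = labels, groups = as.character(groups),
                 clinical_mask = clinical_mask),
            class = "feature_table")
}

#' @export
dim.feature_table <- function(x) dim(x$matrix)

# Keep rows/columns of a feature table.
.ft_subset <- function(t, rows = NULL, cols = NULL) {
  m <- t$matrix
  cm <- t$clinical_mask
  lb <- t$labels
  gr <- t$groups
  if (!is.null(cols)) {
    m <- m[, cols, drop = FALSE]
    cm <- cm[cols]
  }
  if (!is.null(rows)) {
    m <- m[rows, , drop = FALSE]
    lb <- lb[rows]
    gr <- gr[rows]
  }
  structure(list(matrix = m, names = colnames(m), labels = lb, groups = gr,
                 clinical_mask = cm), class = "feature_table")
}

# Type-7 quantiles of each column of a matrix, vectorized over columns.
.col_quantiles <- function(m, probs) {
  n <- nrow(m)
  s <- apply(m, 2L, sort.int, method = "radix")
  h <- (n - 1) * probs + 1
  lo <- floor(h)
  fr <- h - lo
  s[lo, , drop = FALSE] * (1 - fr) +
    s[pmin(lo + 1, n), , drop = FALSE] * fr
}

#' Chi-square ranking of image features
#'
#' Each non-clinical feature is discretized into `n_bins` quantile bins
#' computed on the supplied table (so, when called inside a
#' cross-validation fold, on the training rows only), and a chi-square
#' test of independence between the binned feature and the class labels
#' yields its p-value. Features are ranked by ascending p: a small p-value
#' indicates that the feature depends on the class. Constant features
#' (or any with fewer than two populated bins) get p = 1 and rank last;
#' ties are broken by original column order.
#'
#' @param t a [feature_table()] with at least two classes present.
#' @param n_bins number of quantile bins (default 10).
#' @return Object of class `"ranked_features"`: data frame with columns
#'   `name`, `p_value`, `statistic`, `df`, ordered by ascending p-value.
#' @export
chi2_rank <- function(t, n_bins = 10) {
  stopifnot(inherits(t, "feature_table"), n_bins >= 2)
  y <- as.integer(droplevels(t$labels))
  g <- max(y)
  if (g < 2L) stop("need at least two classes to rank features")
  m <- t$matrix[, !t$clinical_mask, drop = FALSE]
  n <- nrow(m)
  p <- ncol(m)
  probs <- seq_len(n_bins - 1L) / n_bins
  edges <- .col_quantiles(m, probs)
  B <- matrix(1L, n, p)
  for (k in seq_len(p)) {
    e <- unique(edges[, k])
    B[, k] <- findInterval(m[, k], e) + 1L
  }
  nb <- max(B)
  # one pass: per-feature (class x bin) contingency tables
  idx <- rep.int((seq_len(p) - 1L) * (nb * g), rep.int(n, p)) +
    (as.integer(B) - 1L) * g + y
  counts <- array(tabulate(idx, nbins = p * nb * g), c(g, nb, p))
  n_c <- tabulate(y, nbins = g)
  bin_tot <- colSums(counts)             # nb x p
  E <- outer(n_c, bin_tot) / n           # g x nb x p
  X2 <- (counts - E)^2 / E
  X2[E == 0] <- 0
  stat <- colSums(matrix(X2, ncol = p))
  r_used <- colSums(bin_tot > 0)
  df <- (pmax(r_used, 1L) - 1L) * (g - 1L)
  pval <- ifelse(df > 0, stats::pchisq(stat, df, lower.tail = FALSE), 1)
  ord <- order(pval, seq_len(p))
  structure(data.frame(name = colnames(m)[ord], p_value = pval[ord],
                       statistic = stat[ord], df = df[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_features", "data.frame"))
}

#' Keep the k best image features (clinical always retained)
#'
#' Restricts the table to the `k` top-ranked image features plus all
#' clinical covariates; clinical features never count towards `k`.
#'
#' @param r a `"ranked_features"` object from [chi2_rank()].
#' @param k number of image features to keep (default 15).
#' @param t the [feature_table()] to subset.
#' @return A [feature_table()] with `k + #clinical` columns.
#' @export
select_top_k <- function(r, k = 15, t) {
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(r)) stop("k exceeds the number of ranked features")
  keep <- c(r$name[seq_len(k)], t$names[t$clinical_mask])
  .ft_subset(t, cols = match(keep, t$names))
}

#' Fit a regularized pooled-covariance linear discriminant model
#'
#' Features are standardized with training means and SDs, class means and
#' the pooled within-class covariance are estimated, and a small ridge
#' `epsilon * trace(Sigma) / d` is added to the diagonal so folds with
#' nearly collinear features stay well-posed. Priors are either equal
#' across the six classes or proportional to training class counts.
#' Classes absent from the training data keep `NA` means and are never
#' predicted.
#'
#' @param t a [feature_table()]; every present class should have at least
#'   two rows.
#' @param priors_mode `"equal"` or `"empirical"`.
#' @param epsilon ridge fraction (default 1e-6).
#' @return Object of class `"lda_model"`.
#' @export
fit_lda <- function(t, priors_mode = c("equal", "empirical"),
                    epsilon = 1e-6) {
  priors_mode <- match.arg(priors_mode)
  X <- t$matrix
  y <- t$labels
  classes <- levels(y)
  cnt <- table(y)
  present <- names(cnt)[cnt > 0]
  if (length(present) < 2L) stop("need at least two classes to fit LDA")
  if (any(cnt[present] < 2L))
    warning("some classes have fewer than two training samples")
  if (ncol(X) >= nrow(X))
    warning("more features than samples; covariance estimate is weak")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  d <- ncol(Xs)
  means <- matrix(NA_real_, length(classes), d,
                  dimnames = list(classes, colnames(X)))
  S <- matrix(0, d, d)
  for (cl in present) {
    rows <- which(y == cl)
    mu <- colMeans(Xs[rows, , drop = FALSE])
    means[cl, ] <- mu
    if (length(rows) > 1) {
      C <- sweep(Xs[rows, , drop = FALSE], 2L, mu)
      S <- S + crossprod(C)
    }
  }
  S <- S / max(1L, nrow(Xs) - length(present))
  S <- S + diag(epsilon * sum(diag(S)) / d, d)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("pooled covariance is singular even after regularization")
  priors <- stats::setNames(rep(0, length(classes)), classes)
  if (priors_mode == "equal") {
    priors[present] <- 1 / length(present)
  } else {
    priors[present] <- as.numeric(cnt[present]) / sum(cnt[present])
  }
  Sinv <- solve(S)
  structure(list(classes = classes, present = present, means = means,
                 cov = S, cov_inv = Sinv, priors = priors,
                 center = ctr, scale = scl, priors_mode = priors_mode,
                 feature_names = colnames(X)),
            class = "lda_model")
}

#' Predict class labels with a fitted LDA model
#'
#' Applies the training standardization, evaluates the linear discriminant
#' score of every learnable class (including log-priors) and returns the
#' argmax; ties break towards the earlier class in [LUS_CLASSES] order.
#'
#' @param object an `"lda_model"`.
#' @param newdata numeric matrix (or [feature_table()]) whose columns
#'   match the training features.
#' @param ... unused.
#' @return List with factor `class` and the matrix of discriminant
#'   `scores` (columns = learnable classes).
#' @export
predict.lda_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_table")) newdata$matrix else newdata
  if (is.null(dim(X))) X <- matrix(X, nrow = 1,
                                   dimnames = list(NULL, object$feature_names))
  if (ncol(X) != length(object$feature_names))
    stop("newdata feature dimensionality does not match the model")
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), object$feature_names))
    X <- X[, object$feature_names, drop = FALSE]
  Xs <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  cls <- object$present
  Mu <- object$means[cls, , drop = FALSE]
  A <- Mu %*% object$cov_inv                       # g x d
  const <- -0.5 * rowSums(A * Mu) + log(object$priors[cls])
  scores <- Xs %*% t(A) + matrix(const, nrow(Xs), length(cls), byrow = TRUE)
  colnames(scores) <- cls
  pick <- max.col(scores, ties.method = "first")
  list(class = factor(cls[pick], levels = object$classes), scores = scores)
}

#' Serialize a fitted LDA model to a portable JSON file
#' @param model an `"lda_model"`.
#' @param path output file.
#' @export
save_lda_model <- function(model, path) {
  obj <- model
  obj$means <- apply(obj$means, 1L, identity, simplify = FALSE)
  obj$cov <- as.numeric(model$cov)
  obj$cov_inv <- NULL
  obj$priors <- as.numeric(model$priors)   # class order = obj$classes
  obj$center <- as.numeric(model$center)   # feature order = feature_names
  obj$scale <- as.numeric(model$scale)
  obj$d <- length(model$feature_names)
  class(obj) <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Load a model written by [save_lda_model()]
#' @param path JSON file.
#' @return An `"lda_model"`.
#' @export
load_lda_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- obj$d
  means <- do.call(rbind, obj$means)
  dimnames(means) <- list(obj$classes, obj$feature_names)
  S <- matrix(obj$cov, d, d)
  structure(list(classes = obj$classes, present = obj$present,
                 means = means, cov = S, cov_inv = solve(S),
                 priors = stats::setNames(as.numeric(obj$priors),
                                          obj$classes),
                 center = stats::setNames(as.numeric(obj$center),
                                          obj$feature_names),
                 scale = stats::setNames(as.numeric(obj$scale),
                                         obj$feature_names),
                 priors_mode = obj$priors_mode,
                 feature_names = obj$feature_names),
            class = "lda_model")
}
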