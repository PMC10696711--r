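# Independent brute-force oracles for the texture-feature families, written
# as direct loop enumerations so they share no code with the implementation.

oracle_glcm_counts <- function(lev, L, dr, dc) {
  G <- matrix(0L, L, L)
  H <- nrow(lev); W <- ncol(lev)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W)
      G[lev[r, c], lev[r2, c2]] <- G[lev[r, c], lev[r2, c2]] + 1L
  }
  G
}

oracle_glcm_features <- function(G, lev) {
  P <- G / sum(G)
  L <- nrow(P)
  contrast <- corr <- energy <- homog <- ent <- 0
  u <- mean(lev)
  s2 <- mean((lev - u)^2)
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    contrast <- contrast + (i - j)^2 * p
    energy <- energy + p^2
    homog <- homog + p / (1 + (i - j)^2)
    if (p > 0) ent <- ent - p * log2(p)
    corr <- corr + (i - u) * (j - u) * p
  }
  c(contrast = contrast,
    correlation = if (s2 > 0) corr / s2 else 0,
    energy = energy, homogeneity = homog, entropy = ent)
}

# Enumerate maximal runs by walking each line pixel by pixel.
oracle_glrlm <- function(lev, L, direction) {
  H <- nrow(lev); W <- ncol(lev)
  step <- switch(as.character(direction),
                 "0" = c(0, 1), "45" = c(-1, 1), "90" = c(1, 0),
                 "135" = c(1, 1))
  starts <- switch(as.character(direction),
    "0" = cbind(seq_len(H), 1),
    "90" = cbind(1, seq_len(W)),
    "45" = rbind(cbind(seq_len(H), 1), cbind(H, 1 + seq_len(W - 1))),
    "135" = rbind(cbind(1, seq_len(W)), cbind(1 + seq_len(H - 1), 1)))
  jmax <- max(H, W)
  R <- matrix(0L, L, jmax)
  for (s in seq_len(nrow(starts))) {
    r <- starts[s, 1]; c <- starts[s, 2]
    cur <- NA; len <- 0
    while (r >= 1 && r <= H && c >= 1 && c <= W) {
      v <- lev[r, c]
      if (!is.na(cur) && v == cur) len <- len + 1
      else {
        if (!is.na(cur)) R[cur, len] <- R[cur, len] + 1L
        cur <- v; len <- 1
      }
      r <- r + step[1]; c <- c + step[2]
    }
    R[cur, len] <- R[cur, len] + 1L
  }
  R
}

oracle_glrlm_features <- function(R, N) {
  nr <- sum(R)
  f <- rep(0, 11)
  names(f) <- c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
                "srlge", "srhge", "lrlge", "lrhge")
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R))) {
    x <- R[i, j]
    if (x == 0) next
    f["sre"] <- f["sre"] + x / j^2
    f["lre"] <- f["lre"] + x * j^2
    f["lgre"] <- f["lgre"] + x / i^2
    f["hgre"] <- f["hgre"] + x * i^2
    f["srlge"] <- f["srlge"] + x / (i^2 * j^2)
    f["srhge"] <- f["srhge"] + x * i^2 / j^2
    f["lrlge"] <- f["lrlge"] + x * j^2 / i^2
    f["lrhge"] <- f["lrhge"] + x * i^2 * j^2
  }
  f["gln"] <- sum(rowSums(R)^2)
  f["rln"] <- sum(colSums(R)^2)
  f <- f / nr
  f["rp"] <- nr / N
  f
}

# Exhaustive per-pixel LBP labelling: build the 8-bit pattern explicitly,
# test uniformity by counting circular transitions, bin by ones count.
oracle_lbp_hist <- function(roi) {
  H <- nrow(roi); W <- ncol(roi)
  dr <- c(0, -1, -1, -1, 0, 1, 1, 1)
  dc <- c(1, 1, 0, -1, -1, -1, 0, 1)
  bins <- rep(0, 10)
  for (r in 2:(H - 1)) for (c in 2:(W - 1)) {
    bits <- integer(8)
    for (b in 1:8)
      bits[b] <- as.integer(roi[r + dr[b], c + dc[b]] >= roi[r, c])
    trans <- sum(bits != c(bits[-1], bits[1]))
    k <- if (trans <= 2) sum(bits) + 1 else 10
    bins[k] <- bins[k] + 1
  }
  bins / sum(bins)
}

oracle_stats <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / n)
  p <- x / sum(x)
  p <- p[p > 0]
  c(mean = m, sd = s,
    skewness = if (s > 0) sum((x - m)^3) / (n * s^3) else 0,
    kurtosis = if (s > 0) sum((x - m)^4) / (n * s^4) - 3 else 0,
    entropy = -sum(p * log2(p)))
}

# Smoothed multiplicative-speckle field fixture on the native 8-bit scale.
speckle_fixture <- function(h, w, seed, gain = 30) {
  set.seed(seed)
  raw <- matrix(sqrt(-2 * log(runif(h * w))), h, w)
  k <- matrix(1 / 9, 3, 3)
  pad <- raw[c(1, seq_len(h), h), c(1, seq_len(w), w)]
  sm <- matrix(0, h, w)
  for (dr in 0:2) for (dc in 0:2)
    sm <- sm + pad[dr + seq_len(h), dc + seq_len(w)] / 9
  sm * gain
}

# Memoized small phantom cohort so several tests can share one extraction.
.cohort_cache <- new.env(parent = emptyenv())
small_cohort_features <- function() {
  if (is.null(.cohort_cache$ft)) {
    .cohort_cache$ft <- phantom_feature_table(
      n_subjects_per_class = 2, videos_per_subject = 2,
      frames_per_video = 2, seed = 404)
  }
  .cohort_cache$ft
}
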