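# Independent oracles used across the suite. They deliberately share no
# code with the implementation: brute-force enumeration for K-means and
# the weighted naive Bayes, and textbook formulas for the two-sample tests.

# Minimum within-cluster sum of squares over all 2-partitions (n <= ~12).
brute_kmeans2 <- function(points) {
  n <- nrow(points)
  ss <- function(m) {
    if (nrow(m) == 0L) return(0)
    sum(sweep(m, 2, colMeans(m))^2)
  }
  best <- Inf
  # fix point 1 in group A to halve the enumeration
  for (mask in 0:(2^(n - 1) - 1)) {
    in_a <- c(TRUE, as.logical(bitwAnd(mask, 2^(0:(n - 2)))))
    if (all(in_a)) next   # need both clusters non-empty
    j <- ss(points[in_a, , drop = FALSE]) + ss(points[!in_a, , drop = FALSE])
    if (j < best) best <- j
  }
  best
}

# Posterior of the attribute-weighted naive Bayes evaluated directly from
# raw counts: prior * prod_j P(d_j | c) * W(d_j | c), normalized.
wnb_oracle_posterior <- function(x, y, query, smoothing = 1) {
  x <- as.data.frame(lapply(x, as.character), stringsAsFactors = FALSE)
  y <- as.character(y)
  classes <- sort(unique(y))
  classes <- c(intersect(c("ASD", "TD"), classes),
               setdiff(classes, c("ASD", "TD")))
  n_m <- ncol(x)
  score <- sapply(classes, function(ci) {
    rows_c <- y == ci
    s <- sum(rows_c) / length(y)           # prior
    for (m in seq_len(n_m)) {
      v <- as.character(query[[m]])
      vals <- sort(unique(x[[m]]))
      n_vc <- sum(x[[m]] == v & rows_c)
      n_v <- sum(x[[m]] == v)
      cond <- (n_vc + smoothing) / (sum(rows_c) + smoothing * length(vals))
      w <- if (n_v == 0) 1 else (n_m + n_vc / n_v) / n_m
      s <- s * cond * w
    }
    s
  })
  score / sum(score)
}

# Textbook two-sample t statistics.
pooled_t_oracle <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  se <- sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  t <- (mean(x) - mean(y)) / se
  df <- length(x) + length(y) - 2
  list(t = t, p = 2 * pt(-abs(t), df), se = se)
}

welch_t_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, p = 2 * pt(-abs(t), df), se = sqrt(vx + vy))
}

# Single- or few-channel recording from a signal vector or matrix.
make_rec <- function(x, fs = 128, channels = "AF3") {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  neurofuse::eeg_recording(x, fs = fs, channels = channels)
}

# Small cohort defaults used by unit tests (short EEG keeps them fast).
small_spec <- function(seed, n_asd = 5, n_td = 5, ...) {
  neurofuse::cohort_spec(n_asd = n_asd, n_td = n_td, seed = seed,
                         eeg_duration_s = 8, ...)
}
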