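# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# Run-length-encoding transition counter: compress each voxel's label
# series into runs (within zero-free segments), and count one (f, i, n)
# transition for each adjacent run pair, n being the earlier run's
# length; the final run of each segment is never an initial state.
oracle_accumulate <- function(labels, n_layers = ncol(labels)) {
  counts <- array(0L, c(10, 10, n_layers))
  for (v in seq_len(nrow(labels))) {
    x <- labels[v, ]
    for (seg in split(x, cumsum(x == 0L))) {
      seg <- seg[seg != 0L]
      if (length(seg) < 2L) next
      r <- rle(seg)
      if (length(r$values) < 2L) next
      for (j in seq_len(length(r$values) - 1L)) {
        i <- r$values[j]; f <- r$values[j + 1L]; n <- r$lengths[j]
        counts[f, i, n] <- counts[f, i, n] + 1L
      }
    }
  }
  counts
}

# Brute-force AUC: (wins + half-ties) / pairs, in percent.
oracle_auc <- function(positive, negative) {
  wins <- ties <- 0
  for (p in positive) for (q in negative) {
    if (p > q) wins <- wins + 1
    else if (p == q) ties <- ties + 1
  }
  100 * (wins + ties / 2) / (length(positive) * length(negative))
}

# Two-pass Pearson correlation.
oracle_cor <- function(a, b) {
  am <- mean(a); bm <- mean(b)
  sum((a - am) * (b - bm)) /
    sqrt(sum((a - am)^2) * sum((b - bm)^2))
}

# Closed-form two-variable OLS via the normal equations.
oracle_ols <- function(x, y) {
  sxx <- sum(x^2) - length(x) * mean(x)^2
  sxy <- sum(x * y) - length(x) * mean(x) * mean(y)
  slope <- sxy / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Pooled-variance two-sample t statistic and two-sided p.
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  c(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# Random label matrix with occasional undefined samples and sticky runs.
random_labels <- function(n_voxels, n_frames, p_undef = 0.02, p_stay = 0.5) {
  m <- matrix(0L, n_voxels, n_frames)
  for (v in seq_len(n_voxels)) {
    s <- sample.int(10L, 1L)
    for (t in seq_len(n_frames)) {
      if (runif(1) < p_undef) {
        m[v, t] <- 0L
        s <- sample.int(10L, 1L)
      } else {
        if (runif(1) > p_stay) s <- sample(setdiff(1:10, s), 1L)
        m[v, t] <- s
      }
    }
  }
  m
}
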