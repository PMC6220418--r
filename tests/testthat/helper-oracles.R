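# Independent brute-force oracles used to freeze expected values. These
# deliberately avoid the package's vectorised code paths.

# Naive windowed frame-differencing detector: explicit per-pixel loops.
# Mirrors the window rule (reference = first frame of each 30-min section,
# comparisons include the next section's first frame) but nothing else.
oracle_detect <- function(frames, timestamps, mask = NULL,
                          window_minutes = 30, pixel_fraction = 0.05,
                          intensity_fraction = 0.5, bit_depth_max = 255) {
  d <- dim(frames)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  n_valid <- sum(mask)
  cut <- intensity_fraction * bit_depth_max
  bins <- floor((timestamps - timestamps[1]) / window_minutes)
  for (b in sort(unique(bins))) {
    idx <- which(bins == b)
    nxt <- which(bins == b + 1)
    cmp <- c(idx[-1], if (length(nxt)) nxt[1])
    ref_k <- idx[1]
    for (j in cmp) {
      changed <- 0L
      for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
        if (!mask[r, cc]) next
        if (abs(frames[r, cc, j] - frames[r, cc, ref_k]) > cut)
          changed <- changed + 1L
      }
      if (changed / n_valid >= pixel_fraction)
        return(list(opened = TRUE, frame = j, taa = timestamps[j]))
    }
  }
  list(opened = FALSE, frame = NA_integer_, taa = NA_real_)
}

# Direct sums-of-squares one-way ANOVA.
oracle_anova <- function(groups) {
  y <- unlist(groups); g <- rep(seq_along(groups), lengths(groups))
  k <- length(groups); N <- length(y)
  gm <- mean(y)
  ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - gm)^2,
                    numeric(1)))
  ssw <- sum(unlist(lapply(groups, function(v) (v - mean(v))^2)))
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = F, df1 = k - 1, df2 = N - k,
       p = pf(F, k - 1, N - k, lower.tail = FALSE))
}

# Holm step-down adjustment from first principles.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * (m - seq_len(m) + 1)
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Nearest-centroid classifier on flattened raw pixels.
oracle_nearest_centroid <- function(crops, labels, newcrops) {
  flat <- t(vapply(crops, as.vector, numeric(length(crops[[1]]))))
  cents <- lapply(split(seq_along(labels), labels),
                  function(i) colMeans(flat[i, , drop = FALSE]))
  vapply(newcrops, function(cr) {
    v <- as.vector(cr)
    d <- vapply(cents, function(ce) sum((v - ce)^2), numeric(1))
    names(cents)[which.min(d)]
  }, character(1))
}

# Trapezoidal mean of a sampled function over its full support.
oracle_trapezoid_mean <- function(x, y) {
  area <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  area / (max(x) - min(x))
}
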