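# Independent brute-force oracles and tiny fixture builders used across
# the test files. These deliberately use naive loops so they share no
# code path with the package implementations they check.

rand_image <- function(h, w, seed, spacing = 0.1) {
  set.seed(seed)
  gray_image(matrix(sample(0:255, h * w, replace = TRUE), h, w),
             pixel_spacing_mm = spacing)
}

# per-pixel median with mirror border (edge pixel not repeated)
oracle_median <- function(px, k) {
  r <- (k - 1) %/% 2
  h <- nrow(px); w <- ncol(px)
  reflect <- function(i, n) {
    if (i < 1) 2 - i else if (i > n) 2 * n - i else i
  }
  out <- px
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- numeric(k * k); m <- 0
    for (di in -r:r) for (dj in -r:r) {
      m <- m + 1
      vals[m] <- px[reflect(i + di, h), reflect(j + dj, w)]
    }
    out[i, j] <- stats::median(vals)
  }
  out
}

# exhaustive between-class-variance maximization over all thresholds
oracle_otsu <- function(px) {
  v <- as.vector(px)
  best_t <- NA; best_s <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best_s) { best_s <- s; best_t <- t }
  }
  best_t
}

# ordered-pair cooccurrence counts by literal double loop over pixels;
# symmetric counting = offset applied in both directions
oracle_glcm_counts <- function(px, drow, dcol, levels) {
  q <- (px * levels) %/% 256 + 1
  h <- nrow(q); w <- ncol(q)
  counts <- matrix(0L, levels, levels)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    for (sgn in c(1, -1)) {
      i2 <- i + sgn * drow; j2 <- j + sgn * dcol
      if (i2 >= 1 && i2 <= h && j2 >= 1 && j2 <= w)
        counts[q[i, j], q[i2, j2]] <- counts[q[i, j], q[i2, j2]] + 1L
    }
  }
  counts
}

glcm_offset <- function(d, theta) {
  switch(as.character(theta),
         "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d))
}

# smooth unimodal surrogate affinity over the decoded (C, r) plane,
# peaked inside the search box; ignores the dataset argument
surrogate_affinity <- function(ab, data, cfg) {
  ph <- decode_antibody(ab$bits, cfg)
  exp(-((log2(ph$C) - 5)^2 + (log2(ph$r) + 6)^2) / 50)
}

# unimodal sphere surrogate over all 32 decoded fields (optimum at 0.7
# in every field) -- high-dimensional, so blind random sampling is a
# weak baseline while hill-climbing pays off
surrogate_sphere <- function(ab, data, cfg) {
  n <- cfg$bits_per_field
  xs <- vapply(seq_len(32), function(k)
    decode_field(ab$bits[((k - 1) * n + 1):(k * n)], 0, 1), 0)
  exp(-sum((xs - 0.7)^2))
}

# well separated 3-class Gaussian blobs as a 30-feature dataset: the
# class signal is spread over the first ten columns (five per
# discriminative axis) so it survives per-column standardization
blob_dataset <- function(n_per_class = 20, sep = 6, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  x <- do.call(rbind, lapply(1:3, function(k) {
    m <- matrix(rnorm(n_per_class * 30), ncol = 30)
    m[, 1:5] <- m[, 1:5] + centers[k, 1]
    m[, 6:10] <- m[, 6:10] + centers[k, 2]
    m
  }))
  colnames(x) <- feature_names()
  labels <- factor(rep(c("normal", "cirrhosis", "cancer"),
                       each = n_per_class),
                   levels = c("normal", "cirrhosis", "cancer"))
  labeled_dataset(x, labels)
}

# three classes spread along ONE latent axis expressed in six correlated
# columns (centers -sep/0/+sep); the layout a 1-component PCA can find
axis_blob_dataset <- function(n_per_class = 15, sep = 6, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(c(-sep, 0, sep), function(mu) {
    m <- matrix(rnorm(n_per_class * 30), ncol = 30)
    m[, 1:6] <- m[, 1:6] + mu
    m
  }))
  colnames(x) <- feature_names()
  labels <- factor(rep(c("normal", "cirrhosis", "cancer"),
                       each = n_per_class),
                   levels = c("normal", "cirrhosis", "cancer"))
  labeled_dataset(x, labels)
}
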