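#' Gray-level cooccurrence matrix
#'
#' Counts how often two pixels separated by a fixed offset (distance `d`
#' pixels along direction `theta`) take each pair of quantized gray
#' levels, then normalizes the counts to a joint probability matrix.
#' Pairs are counted symmetrically (each ordered pair and its reverse),
#' the common convention, and `T` records the raw symmetric pair count.
#'
#' @param window a [gray_image()] or bare intensity matrix in
#'   \[0, 255\] (an analysis window, typically a 1 x 1 cm tile of an
#'   ROI).
#' @param d offset distance in pixels (1 or 2 are the usual choices).
#' @param theta offset direction in degrees, one of 0, 45, 90, 135.
#'   0 degrees is along a row (increasing column), 90 along a column.
#' @param levels number of equal-width quantization bins over \[0, 255\],
#'   between 2 and 64 (default 32; 8/16/32/64 are the usual choices).
#' @return an object of class `glcm`: `matrix` (levels x levels joint
#'   probabilities summing to 1), `levels`, `d`, `theta`, `T` (raw pair
#'   count).
#' @export
compute_glcm <- function(window, d = 1L, theta = 0, levels = 32L) {
  px <- if (inherits(window, "gray_image")) window$pixels
        else round(as.matrix(window))
  if (min(px) < 0 || max(px) > 255) stop("intensities must lie in [0, 255]")
  d <- as.integer(d); levels <- as.integer(levels)
  if (levels < 2L || levels > 64L) stop("`levels` must be between 2 and 64")
  if (!theta %in% c(0, 45, 90, 135)) stop("`theta` must be 0, 45, 90 or 135")
  if (d < 1L) stop("`d` must be >= 1")
  off <- switch(as.character(theta),
    "0"   = c(0L, d),     # (drow, dcol): along a row
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d))
  q <- quantize_levels(px, levels)
  h <- nrow(q); w <- ncol(q)
  r0 <- max(1L, 1L - off[1]); r1 <- min(h, h - off[1])
  c0 <- max(1L, 1L - off[2]); c1 <- min(w, w - off[2])
  if (r1 < r0 || c1 < c0) stop("window too small for offset (d, theta)")
  a <- q[r0:r1, c0:c1, drop = FALSE]
  b <- q[(r0 + off[1]):(r1 + off[1]), (c0 + off[2]):(c1 + off[2]), drop = FALSE]
  counts <- tabulate((a - 1L) * levels + b, levels * levels)
  m <- matrix(counts, levels, levels, byrow = TRUE)
  m <- m + t(m)                          # symmetric pair counting
  T <- sum(m)
  structure(list(matrix = m / T, levels = levels, d = d, theta = theta, T = T),
            class = "glcm")
}

# equal-width quantization of [0,255] into `levels` bins, 1-based indices
quantize_levels <- function(px, levels) {
  q <- (px * as.integer(levels)) %/% 256L + 1L
  storage.mode(q) <- "integer"
  q
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("glcm: %d levels, d = %d, theta = %d deg, %d pairs\n",
              x$levels, x$d, x$theta, x$T))
  invisible(x)
}

.glcm_mat <- function(g) if (inherits(g, "glcm")) g$matrix else g

#' GLCM entropy
#'
#' H = -sum P(i,j) log2 P(i,j) over the nonzero cells, in bits. Complex,
#' nonuniform texture spreads the cooccurrence mass over many cells and
#' drives the entropy up; a single-cell matrix has entropy 0.
#'
#' @param g a [compute_glcm()] result or a normalized probability matrix.
#' @return nonnegative entropy in bits.
#' @export
glcm_entropy <- function(g) {
  p <- .glcm_mat(g)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' GLCM angular second moment (energy)
#'
#' ASM = sum P(i,j)^2. Maximal (1) when all mass sits in one cell, i.e.
#' for a perfectly uniform gray distribution; small for rough, uneven
#' texture.
#'
#' @inheritParams glcm_entropy
#' @return value in (0, 1\].
#' @export
glcm_asm <- function(g) {
  p <- .glcm_mat(g)
  sum(p^2)
}

#' GLCM contrast (inertia)
#'
#' sum (i-j)^2 P(i,j) over quantized level indices; 0 exactly when all
#' mass lies on the diagonal (neighbouring pixels always share a level).
#'
#' @inheritParams glcm_entropy
#' @return nonnegative contrast.
#' @export
glcm_contrast <- function(g) {
  p <- .glcm_mat(g)
  n <- nrow(p)
  idx <- seq_len(n)
  d2 <- outer(idx, idx, function(i, j) (i - j)^2)
  sum(d2 * p)
}

#' Fourier ring energies
#'
#' Radial partition of the 2-D power spectrum: the magnitude-squared DFT
#' (DC term removed) is split into `n_rings` equal-width concentric bands
#' about the zero frequency and each band's energy is reported as a
#' fraction of the total. Fine texture pushes energy into the outer
#' rings, coarse texture concentrates it near DC.
#'
#' @param window a square [gray_image()].
#' @param n_rings number of radial bands (default 4).
#' @return an object of class `fourier_features`: `ring_energies`
#'   (fractions summing to 1, or all zero for a constant window) and
#'   `total_energy`.
#' @export
fourier_ring_energies <- function(window, n_rings = 4L) {
  window <- as_gray_image(window)
  n <- window$height
  if (n != window$width) stop("window must be square")
  n_rings <- as.integer(n_rings)
  if (n < 2L * n_rings) stop("window side must be at least 2 * n_rings")
  spec <- Mod(stats::fft(window$pixels))^2
  spec[1, 1] <- 0                       # remove DC
  # centered frequency index of each DFT bin
  f <- function(k, n) ifelse(k <= n %/% 2, k, k - n)
  fr <- f(0:(n - 1), n); fc <- f(0:(n - 1), n)
  rad <- sqrt(outer(fr^2, fc^2, "+"))
  rmax <- n / 2
  ring <- pmin(floor(rad / (rmax / n_rings)) + 1, n_rings)
  total <- sum(spec)
  if (total <= 0) {
    e <- rep(0, n_rings)
  } else {
    e <- vapply(seq_len(n_rings), function(k) sum(spec[ring == k]), 0)
    e <- e / total
  }
  structure(list(ring_energies = e, total_energy = total),
            class = "fourier_features")
}
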