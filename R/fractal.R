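#' Two-level hybrid wavelet decomposition
#'
#' Multiresolution split used by the fractal feature vector. Level 1 is a
#' separable 2-channel Haar analysis of the window into LL/LH/HL/HH
#' half-resolution subbands. Level 2 re-analyses the LH band (low-pass
#' along the abscissa, high-pass along the ordinate — the band that
#' carries the diagnostic horizontal-texture detail) with a separable
#' 3-channel uniform filter bank, giving a 3 x 3 grid of third-resolution
#' subimages.
#'
#' The 3-channel bank uses the orthonormal 3-point DCT-II filters
#' (low / band / high), the real-valued modulated bank on three uniform
#' channels; a complex DFT-modulated bank would make channels 1 and 2
#' redundant conjugates for real images.
#'
#' @param window a square [gray_image()] (or numeric matrix) with even
#'   side >= 64.
#' @return an object of class `subband_tree`: `original`, `ll`, `lh`,
#'   `hl`, `hh` (level 1) and `level2`, a 3 x 3 list-matrix of subimages
#'   indexed by (row channel, column channel), channel 1 = low-pass.
#' @export
hybrid_decompose <- function(window) {
  m <- if (inherits(window, "gray_image")) window$pixels else window
  n <- nrow(m)
  if (n != ncol(m)) stop("window must be square")
  if (n < 64 || n %% 2 != 0) stop("window side must be even and >= 64")
  s <- 1 / sqrt(2)
  lo1 <- function(x) s * (x[c(TRUE, FALSE), , drop = FALSE] +
                          x[c(FALSE, TRUE), , drop = FALSE])
  hi1 <- function(x) s * (x[c(TRUE, FALSE), , drop = FALSE] -
                          x[c(FALSE, TRUE), , drop = FALSE])
  L <- lo1(m); H <- hi1(m)
  ll <- t(lo1(t(L))); lh <- t(hi1(t(L)))
  hl <- t(lo1(t(H))); hh <- t(hi1(t(H)))

  # 3-channel analysis along rows: DCT-II filters on length-3 blocks
  split3 <- function(x) {
    n3 <- (nrow(x) %/% 3L) * 3L
    x <- x[seq_len(n3), , drop = FALSE]
    a <- x[seq(1L, n3, 3L), , drop = FALSE]
    b <- x[seq(2L, n3, 3L), , drop = FALSE]
    c <- x[seq(3L, n3, 3L), , drop = FALSE]
    list((a + b + c) / sqrt(3),          # low
         (a - c) / sqrt(2),              # band
         (a - 2 * b + c) / sqrt(6))      # high
  }
  rows <- split3(lh)
  lvl2 <- vector("list", 9L)
  dim(lvl2) <- c(3L, 3L)
  for (i in 1:3) {
    cols <- split3(t(rows[[i]]))
    for (j in 1:3) lvl2[[i, j]] <- t(cols[[j]])
  }
  structure(list(original = m, ll = ll, lh = lh, hl = hl, hh = hh,
                 level2 = lvl2),
            class = "subband_tree")
}

#' Differential box-counting fractal dimension
#'
#' Treats the intensity grid as a surface z = f(x, y) and estimates its
#' fractal (roughness) dimension from differential box spans: for each
#' box size s in \{2, 4, 8, ..., side/4\} the grid is tiled into s x s
#' cells and the mean intensity span (cell maximum minus minimum) is
#' recorded. For an ideal self-affine surface the mean span grows as
#' s^H with D = 3 - H; on a sampled grid the span of a small cell misses
#' the sub-sample excursions of the surface, a scale-independent deficit
#' that flattens the raw log-log slope and biases the classical
#' box-count slope toward 2 on rough surfaces. The estimator therefore
#' fits span(s) = c s^H - a (the deficit `a` absorbing the missing
#' sub-sample roughness) by least squares on a grid of H values and
#' reports D = 3 - H, clipped to the surface-dimension range \[2, 3\].
#' When fewer than three box sizes are available the deficit term is
#' dropped and the plain two-point slope is used. The grid is linearly
#' rescaled to \[0, 255\] first so subbands are treated comparably.
#'
#' @param grid numeric matrix (side >= 8) or [gray_image()].
#' @return fractal dimension in \[2, 3\]; exactly 2 for a constant grid.
#' @export
fractal_dimension <- function(grid) {
  m <- if (inherits(grid, "gray_image")) grid$pixels else grid
  side <- min(dim(m))
  if (side < 8) stop("grid side must be >= 8")
  rng <- range(m)
  if (rng[2] <= rng[1]) return(2.0)
  m <- (m - rng[1]) / (rng[2] - rng[1]) * 255
  sizes <- 2^(1:30)
  sizes <- sizes[sizes <= side / 4]
  if (length(sizes) < 2) sizes <- c(2L, 4L)
  sp <- vapply(sizes, function(s) .dbc_mean_span(m, s), 0)
  if (any(sp <= 0)) return(2.0)
  if (length(sizes) < 3) {
    h_hat <- (log(sp[2]) - log(sp[1])) / (log(sizes[2]) - log(sizes[1]))
    return(min(max(3 - h_hat, 2.0), 3.0))
  }
  h_grid <- seq(0.02, 1, by = 0.01)
  sse <- vapply(h_grid, function(H) {
    X <- cbind(sizes^H, -1)
    cf <- stats::lm.fit(X, sp)$coefficients
    if (!is.finite(cf[1]) || cf[1] <= 0) return(Inf)
    pred <- X %*% cf
    if (any(pred <= 0)) return(Inf)
    sum((log(sp) - log(pred))^2)
  }, 0)
  min(max(3 - h_grid[which.min(sse)], 2.0), 3.0)
}

# mean differential span (cell max - min) over the s x s box grid
.dbc_mean_span <- function(m, s) {
  h <- nrow(m); w <- ncol(m)
  nh <- h %/% s; nw <- w %/% s
  mm <- m[seq_len(nh * s), seq_len(nw * s), drop = FALSE]
  mx <- matrix(-Inf, nh, nw); mn <- matrix(Inf, nh, nw)
  for (di in seq_len(s)) for (dj in seq_len(s)) {
    sl <- mm[seq(di, by = s, length.out = nh),
             seq(dj, by = s, length.out = nw), drop = FALSE]
    mx <- pmax(mx, sl); mn <- pmin(mn, sl)
  }
  mean(mx - mn)
}

#' Wavelet-fractal feature vector
#'
#' Nine fractal dimensions summarizing the window's roughness across the
#' hybrid decomposition: the raw window, the level-1 LL and LH bands, and
#' six level-2 subimages of the LH band. The six are the cells of the
#' 3 x 3 level-2 grid whose column (abscissa) channel is not purely
#' low-pass, taken in raster order — the mixed and detail bands that
#' discriminate coarse from irregular texture.
#'
#' @param window a square [gray_image()] satisfying the
#'   [hybrid_decompose()] preconditions.
#' @return named numeric vector of length 9 with entries in \[2, 3\]:
#'   `mf_3_0` (raw window), `mf_2_1` (LL), `mf_2_2` (LH),
#'   `mf_1_1` ... `mf_1_6` (level-2 subimages).
#' @export
fractal_feature_vector <- function(window) {
  tr <- hybrid_decompose(window)
  lvl2 <- tr$level2
  keep <- list(lvl2[[1, 2]], lvl2[[1, 3]],
               lvl2[[2, 2]], lvl2[[2, 3]],
               lvl2[[3, 2]], lvl2[[3, 3]])
  mf <- c(fractal_dimension(tr$original),
          fractal_dimension(tr$ll),
          fractal_dimension(tr$lh),
          vapply(keep, fractal_dimension, 0))
  names(mf) <- c("mf_3_0", "mf_2_1", "mf_2_2", paste0("mf_1_", 1:6))
  mf
}

#' Fractional Brownian surface by spectral synthesis
#'
#' Generates an isotropic fractional Brownian motion surface with Hurst
#' exponent `hurst` by shaping white Gaussian noise in the frequency
#' domain with amplitude f^-(hurst + 1) (2-D power spectrum
#' f^-(2 hurst + 2)); the theoretical fractal dimension of the surface
#' is 3 - hurst. The field is synthesized on a domain twice the
#' requested side and cropped, so the circular periodicity of the FFT
#' does not saturate large-scale spans inside the returned patch. Used
#' to calibrate [fractal_dimension()].
#'
#' @param side grid side in pixels.
#' @param hurst Hurst exponent in (0, 1).
#' @param seed integer seed.
#' @return `side` x `side` numeric matrix.
#' @export
synth_fbm <- function(side, hurst, seed = 1L) {
  stopifnot(hurst > 0, hurst < 1, side >= 8)
  set.seed(as.integer(seed))
  n <- 2L * as.integer(side)
  f <- function(k, n) ifelse(k <= n %/% 2, k, k - n)
  fr <- f(0:(n - 1), n)
  rad <- sqrt(outer(fr^2, fr^2, "+"))
  amp <- ifelse(rad > 0, rad^-(hurst + 1), 0)
  phase <- matrix(stats::rnorm(n^2), n) + 1i * matrix(stats::rnorm(n^2), n)
  z <- Re(stats::fft(amp * phase, inverse = TRUE)) / n
  z[seq_len(side), seq_len(side)]
}
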