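#' Tissue-class speckle recipe
#'
#' Parameters of the synthetic speckle model for one tissue class. The
#' model is fully developed speckle — a complex Gaussian scatterer field
#' low-pass filtered at the speckle correlation length, whose envelope
#' magnitude is Rayleigh distributed — modulated by a slow multiplicative
#' gain field (tissue heterogeneity) and mapped linearly onto the class's
#' gray range.
#'
#' @param label class name, one of `normal`, `cirrhosis`, `cancer`.
#' @param corr_len speckle correlation length in pixels (>= 1): short =
#'   fine, dense speckle; long = coarse speckle.
#' @param heterogeneity amplitude of the slow multiplicative gain
#'   variation (0 = stationary speckle).
#' @param gray_lo,gray_hi intensity range the envelope is mapped onto;
#'   a wide range emulates a widened gray-level distribution.
#' @param irregular logical: render an irregular hypoechoic (darker)
#'   lesion blob, as in the cancer class.
#' @param jitter relative per-image jitter of `corr_len` and
#'   `heterogeneity` (within-class variability; default 0).
#' @return list of class `class_recipe`.
#' @export
class_recipe <- function(label, corr_len, heterogeneity, gray_lo, gray_hi,
                         irregular = FALSE, jitter = 0) {
  stopifnot(corr_len >= 1, heterogeneity >= 0, jitter >= 0,
            gray_lo >= 0, gray_hi <= 255, gray_hi > gray_lo)
  structure(list(label = match.arg(label, CLASS_LEVELS),
                 corr_len = corr_len, heterogeneity = heterogeneity,
                 gray_lo = gray_lo, gray_hi = gray_hi,
                 irregular = irregular, jitter = jitter),
            class = "class_recipe")
}

#' Default recipes for the three tissue classes
#'
#' Encodes the qualitative sonographic descriptions as speckle
#' parameters: normal parenchyma is fine, dense, uniform speckle over a
#' moderate gray range; cirrhosis is coarse, uneven speckle (long
#' correlation length, strong gain heterogeneity, wider range); cancer
#' is irregular — comparable coarseness to cirrhosis but with a widened
#' gray-level range, an irregular hypoechoic blob and larger
#' image-to-image variability, making it the hardest class.
#'
#' @return named list of three [class_recipe()]s.
#' @export
default_recipes <- function() {
  list(
    normal    = class_recipe("normal",    corr_len = 1.2,
                             heterogeneity = 0.03,
                             gray_lo = 70, gray_hi = 150),
    cirrhosis = class_recipe("cirrhosis", corr_len = 3.5,
                             heterogeneity = 0.35,
                             gray_lo = 25, gray_hi = 215, jitter = 0.10),
    cancer    = class_recipe("cancer",    corr_len = 2.8,
                             heterogeneity = 0.45,
                             gray_lo = 10, gray_hi = 255,
                             irregular = TRUE, jitter = 0.25))
}

# FFT-based Gaussian low-pass of a matrix, circular boundary
.gauss_lowpass <- function(m, sigma) {
  n <- nrow(m); w <- ncol(m)
  f <- function(k, n) ifelse(k <= n %/% 2, k, k - n) / n
  fr <- f(0:(n - 1), n); fc <- f(0:(w - 1), w)
  h <- exp(-2 * pi^2 * sigma^2 * outer(fr^2, fc^2, "+"))
  Re(stats::fft(stats::fft(m) * h, inverse = TRUE)) / (n * w)
}

# irregular blob mask: radial cosine-perturbed ellipse
.blob_mask <- function(size, centre, radius, irregularity = 0.35) {
  idx <- seq_len(size)
  dr <- outer(idx - centre[1], rep(1, size))
  dc <- outer(rep(1, size), idx - centre[2])
  ang <- atan2(dr, dc)
  k <- sample(2:5, 1)
  phase <- stats::runif(1, 0, 2 * pi)
  r_eff <- radius * (1 + irregularity * cos(k * ang + phase))
  sqrt(dr^2 + dc^2) < r_eff
}

#' Generate one synthetic speckle image
#'
#' Draws an i.i.d. complex Gaussian scatterer field, low-pass filters it
#' at the recipe's correlation length, takes the envelope magnitude
#' (Rayleigh-distributed fully developed speckle), multiplies by a slow
#' gain field of the recipe's heterogeneity amplitude, optionally
#' carves an irregular hypoechoic blob, and maps the result linearly
#' onto the recipe's gray range.
#'
#' @param recipe a [class_recipe()].
#' @param size image side in pixels (>= 128; default 256, i.e. four
#'   1 x 1 cm analysis windows at 0.1 mm spacing).
#' @param seed integer seed; the image is bit-reproducible.
#' @param pixel_spacing_mm pixel spacing metadata.
#' @return a [gray_image()].
#' @export
generate_speckle_image <- function(recipe, size = 256L, seed = 1L,
                                   pixel_spacing_mm = 0.1) {
  stopifnot(inherits(recipe, "class_recipe"))
  size <- as.integer(size)
  if (size < 128L) stop("`size` must be >= 128")
  set.seed(as.integer(seed))
  cl <- recipe$corr_len
  het <- recipe$heterogeneity
  if (recipe$jitter > 0) {
    cl <- cl * exp(stats::rnorm(1, 0, recipe$jitter))
    het <- het * exp(stats::rnorm(1, 0, recipe$jitter))
  }
  field <- matrix(stats::rnorm(size^2), size) +
    1i * matrix(stats::rnorm(size^2), size)
  # filter real and imaginary parts with the same Gaussian kernel: a
  # linear filter preserves circular Gaussianity, so Mod() is Rayleigh
  env <- Mod(.gauss_lowpass(Re(field), cl / 2) +
             1i * .gauss_lowpass(Im(field), cl / 2))
  if (het > 0) {
    gain <- .gauss_lowpass(matrix(stats::rnorm(size^2), size), size / 8)
    gain <- gain / stats::sd(gain)
    env <- env * pmax(1 + het * gain, 0.05)
  }
  if (recipe$irregular) {
    centre <- stats::runif(2, 0.25 * size, 0.75 * size)
    radius <- stats::runif(1, 0.15, 0.30) * size
    depth <- stats::runif(1, 0.35, 0.65)
    mask <- .blob_mask(size, centre, radius)
    env[mask] <- env[mask] * depth
  }
  hi <- stats::quantile(env, 0.999, names = FALSE)
  g <- recipe$gray_lo + (recipe$gray_hi - recipe$gray_lo) * pmin(env / hi, 1)
  gray_image(pmin(pmax(round(g), 0), 255), pixel_spacing_mm)
}

#' Generate a labeled synthetic dataset
#'
#' Balanced dataset emulating the study design: `n_per_class` images per
#' tissue class (default 100, i.e. 300 samples), each reduced to its
#' 30-feature vector by the standard pipeline ([extract_features()] on
#' the full image), with stratified five-group rotation folds. With
#' `out_dir` set, the PNG images, an ROI configuration YAML and the
#' feature CSV are also written to disk.
#'
#' @param n_per_class images per class (>= 5; default 100).
#' @param recipes named list of three [class_recipe()]s (default
#'   [default_recipes()]).
#' @param seed integer master seed; per-image seeds and the fold
#'   assignment derive from it.
#' @param size image side in pixels.
#' @param out_dir optional directory for PNGs, `rois.yaml` and
#'   `features.csv`.
#' @return a [labeled_dataset()]; the generated images are attached as
#'   attribute `images` when `keep_images = TRUE`.
#' @param keep_images logical: attach the image list to the result.
#' @export
generate_dataset <- function(n_per_class = 100L, recipes = default_recipes(),
                             seed = 1L, size = 256L, out_dir = NULL,
                             keep_images = FALSE) {
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 5L) stop("`n_per_class` must be >= 5")
  stopifnot(length(recipes) == 3L)
  labels <- character(0)
  rows <- list()
  images <- list()
  roi_cfg <- list()
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  i_img <- 0L
  for (cl in names(recipes)) {
    for (k in seq_len(n_per_class)) {
      i_img <- i_img + 1L
      img_seed <- (as.integer(seed) * 1000L + i_img) %% .Machine$integer.max
      img <- generate_speckle_image(recipes[[cl]], size = size,
                                    seed = img_seed)
      rows[[i_img]] <- extract_features(img)
      labels <- c(labels, recipes[[cl]]$label)
      if (keep_images) images[[i_img]] <- img
      if (!is.null(out_dir)) {
        fname <- sprintf("%s_%03d.png", cl, k)
        write_gray_png(img, file.path(out_dir, fname))
        half <- size %/% 2L
        roi_cfg[[fname]] <- list(
          label = recipes[[cl]]$label,
          a1 = c(0L, 0L, half, half),
          a2 = c(0L, half, half, size))
      }
    }
  }
  feats <- do.call(rbind, rows)
  set.seed(as.integer(seed))
  data <- labeled_dataset(feats, factor(labels, levels = CLASS_LEVELS))
  if (!is.null(out_dir)) {
    yaml::write_yaml(roi_cfg, file.path(out_dir, "rois.yaml"))
    write_feature_csv(data, file.path(out_dir, "features.csv"))
  }
  if (keep_images) attr(data, "images") <- images
  data
}
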