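GLCM_CONFIGS <- list(c(1, 0), c(1, 45), c(1, 90), c(1, 135),
                     c(2, 0), c(2, 90))

#' Names of the 30 texture features, in table order
#'
#' The fixed column layout of every feature CSV: for each cooccurrence
#' offset (d = 1 at 0/45/90/135 degrees, d = 2 at 0/90) the entropy,
#' angular second moment and contrast (18 columns); the first three of
#' four Fourier ring-energy fractions (3 columns — the four fractions
#' sum to 1, so the fourth carries no extra information); and the nine
#' wavelet-fractal dimensions (9 columns).
#'
#' @return character vector of length 30.
#' @export
feature_names <- function() {
  g <- unlist(lapply(GLCM_CONFIGS, function(cf)
    sprintf("glcm_d%d_a%d_%s", cf[1], cf[2], c("entropy", "asm", "contrast"))))
  c(g, paste0("fourier_ring_", 1:3), c("mf_3_0", "mf_2_1", "mf_2_2",
                                       paste0("mf_1_", 1:6)))
}

#' Texture features of one analysis window
#'
#' Computes the full 30-element feature vector on a single square
#' analysis window: GLCM entropy/ASM/contrast for the six supported
#' offsets, Fourier ring energies, and the wavelet-fractal vector.
#'
#' @param window a square [gray_image()] (side even, >= 64; the standard
#'   window is the 1 x 1 cm tile, 100 x 100 px at 0.1 mm spacing).
#' @param levels GLCM quantization levels (default 32).
#' @return named numeric vector of length 30 in [feature_names()] order.
#' @export
window_features <- function(window, levels = 32L) {
  window <- as_gray_image(window)
  g <- unlist(lapply(GLCM_CONFIGS, function(cf) {
    gl <- compute_glcm(window, d = cf[1], theta = cf[2], levels = levels)
    c(glcm_entropy(gl), glcm_asm(gl), glcm_contrast(gl))
  }))
  fr <- fourier_ring_energies(window, n_rings = 4L)$ring_energies[1:3]
  mf <- fractal_feature_vector(window)
  out <- c(g, fr, mf)
  names(out) <- feature_names()
  out
}

#' Tile an ROI into 1 x 1 cm analysis windows
#'
#' Non-overlapping square tiles of physical side `window_mm` (default
#' 10 mm), anchored at the ROI's top-left corner; partial tiles at the
#' right/bottom edges are dropped.
#'
#' @param roi a [gray_image()] crop.
#' @param window_mm physical tile side in millimetres.
#' @return list of [gray_image()] tiles (at least one; errors if the ROI
#'   is smaller than one tile).
#' @export
tile_windows <- function(roi, window_mm = 10) {
  roi <- as_gray_image(roi)
  side <- floor(window_mm / roi$pixel_spacing_mm)
  if (side %% 2 == 1) side <- side - 1   # decomposition needs an even side
  if (roi$height < side || roi$width < side)
    stop("ROI smaller than one analysis window")
  tiles <- list()
  for (r0 in seq(0, roi$height - side, by = side))
    for (c0 in seq(0, roi$width - side, by = side))
      tiles[[length(tiles) + 1L]] <-
        extract_roi(roi, roi_rect(r0, c0, r0 + side, c0 + side))
  tiles
}

#' 30-feature vector of an ROI
#'
#' Despeckles the ROI (3 x 3 median), tiles it into 1 x 1 cm analysis
#' windows and averages the per-window feature vectors. The contrast
#' stretch of the display chain is deliberately not applied here: the
#' width of the gray-level distribution is itself a diagnostic texture
#' axis (widened in malignancy), and a per-ROI stretch would normalize
#' it away.
#'
#' @param img a [gray_image()].
#' @param rect optional [roi_rect()] to crop first; `NULL` uses the
#'   whole image.
#' @param preprocess logical: apply the median despeckle (default
#'   `TRUE`).
#' @param levels GLCM quantization levels.
#' @return named numeric vector of length 30.
#' @export
extract_features <- function(img, rect = NULL, preprocess = TRUE,
                             levels = 32L) {
  img <- as_gray_image(img)
  roi <- if (is.null(rect)) img else extract_roi(img, rect)
  if (preprocess) roi <- despeckle(roi, 3L)
  tiles <- tile_windows(roi)
  feats <- vapply(tiles, window_features, numeric(30L), levels = levels)
  rowMeans(feats)
}

#' Write a feature table to CSV
#'
#' One row per ROI: the 30 feature columns in [feature_names()] order,
#' a `label` column (0 = normal, 1 = cirrhosis, 2 = cancer) and a
#' `fold_id` column when present.
#'
#' @param data a [labeled_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(data, path) {
  df <- as.data.frame(data$features)
  df$label <- as.integer(data$labels) - 1L
  df$fold_id <- data$fold_id
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Inverse of [write_feature_csv()]; validates the 30-column schema.
#'
#' @param path CSV path with [feature_names()] columns, `label`
#'   (0/1/2 or class names) and optional `fold_id`.
#' @return a [labeled_dataset()].
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(feature_names(), names(df))
  if (length(missing))
    stop("feature CSV is missing columns: ", paste(missing, collapse = ", "))
  if (!"label" %in% names(df)) stop("feature CSV is missing a `label` column")
  lab <- df$label
  labels <- if (is.numeric(lab)) factor(CLASS_LEVELS[lab + 1L],
                                        levels = CLASS_LEVELS)
            else factor(lab, levels = CLASS_LEVELS)
  fold <- if ("fold_id" %in% names(df)) df$fold_id else NULL
  labeled_dataset(as.matrix(df[, feature_names()]), labels, fold)
}
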