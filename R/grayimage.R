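#' Grayscale ultrasound image
#'
#' A `gray_image` is a 2-D integer intensity grid in \[0, 255\] with a
#' physical pixel spacing. It is the common currency of the preprocessing
#' and feature-extraction functions: B-mode ultrasound stores the echo
#' amplitude as the brightness of each pixel, so all texture statistics
#' operate on this single intensity channel.
#'
#' @param pixels numeric matrix of intensities in \[0, 255\] (rows = image
#'   rows). Values are rounded to the nearest integer.
#' @param pixel_spacing_mm physical size of one pixel edge in millimetres
#'   (default 0.1, so a 1 x 1 cm analysis window is 100 x 100 pixels).
#' @return an object of class `gray_image` with elements `pixels`,
#'   `height`, `width`, `pixel_spacing_mm`.
#' @export
gray_image <- function(pixels, pixel_spacing_mm = 0.1) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  px <- round(pixels)
  if (anyNA(px) || min(px) < 0 || max(px) > 255)
    stop("intensities must lie in [0, 255]")
  if (nrow(px) < 8 || ncol(px) < 8)
    stop("image must be at least 8 x 8 pixels")
  if (!is.numeric(pixel_spacing_mm) || pixel_spacing_mm <= 0)
    stop("`pixel_spacing_mm` must be a positive number")
  structure(
    list(pixels = px, height = nrow(px), width = ncol(px),
         pixel_spacing_mm = pixel_spacing_mm),
    class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("gray_image %d x %d px (%.2f mm/px), intensities [%d, %d]\n",
              x$height, x$width, x$pixel_spacing_mm,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

as_gray_image <- function(x, pixel_spacing_mm = 0.1) {
  if (inherits(x, "gray_image")) return(x)
  gray_image(x, pixel_spacing_mm)
}

#' Convert an image array to grayscale
#'
#' Reduces a 3-channel (RGB, channels-last) array to a single luminance
#' channel with the ITU-R BT.601 weights 0.299/0.587/0.114; a 2-D input is
#' passed through unchanged. Inputs scaled to \[0, 1\] (as returned by
#' [png::readPNG()]) are rescaled to \[0, 255\] first.
#'
#' @param x 2-D matrix or 3-D array with 3 (or 4, alpha dropped) channels
#'   in the last dimension.
#' @param pixel_spacing_mm pixel spacing passed to [gray_image()].
#' @return a [gray_image()].
#' @export
to_grayscale <- function(x, pixel_spacing_mm = 0.1) {
  if (is.array(x) && length(dim(x)) == 3) {
    nc <- dim(x)[3]
    if (nc == 4) x <- x[, , 1:3, drop = FALSE]
    else if (nc != 3) stop("3-D input must have 3 channels (channels last)")
    if (max(x) <= 1) x <- x * 255
    g <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
    gray_image(pmin(pmax(round(g), 0), 255), pixel_spacing_mm)
  } else if (is.matrix(x)) {
    if (max(x) <= 1 && min(x) >= 0 && any(x != round(x))) x <- x * 255
    gray_image(x, pixel_spacing_mm)
  } else {
    stop("input must be a 2-D matrix or a 3-D channels-last array")
  }
}

#' Percentile contrast stretch
#'
#' Linearly maps the `lo_pct` and `hi_pct` intensity percentiles to 0 and
#' 255 and clips, enlarging the gray change range of a low-contrast scan.
#' A constant image (or one whose two percentiles coincide) is returned
#' unchanged, since no linear map can spread a single value.
#'
#' @param img a [gray_image()].
#' @param lo_pct,hi_pct percentile bounds, 0 <= lo_pct < hi_pct <= 100.
#'   The defaults (1, 99) resist isolated outlier pixels.
#' @return a [gray_image()] spanning \[0, 255\] (unless degenerate).
#' @export
stretch_contrast <- function(img, lo_pct = 1, hi_pct = 99) {
  img <- as_gray_image(img)
  if (!is.numeric(lo_pct) || !is.numeric(hi_pct) ||
      lo_pct < 0 || hi_pct > 100 || lo_pct >= hi_pct)
    stop("need 0 <= lo_pct < hi_pct <= 100")
  q <- stats::quantile(img$pixels, c(lo_pct, hi_pct) / 100,
                       names = FALSE, type = 7)
  if (q[2] <= q[1]) return(img)
  out <- (img$pixels - q[1]) * (255 / (q[2] - q[1]))
  gray_image(pmin(pmax(round(out), 0), 255), img$pixel_spacing_mm)
}

#' Histogram equalization
#'
#' Alternative enhancement to [stretch_contrast()]: maps intensities
#' through the empirical CDF so the output histogram is approximately
#' uniform over \[0, 255\].
#'
#' @param img a [gray_image()].
#' @return a [gray_image()].
#' @export
equalize_hist <- function(img) {
  img <- as_gray_image(img)
  v <- as.vector(img$pixels)
  cdf <- cumsum(tabulate(v + 1L, 256L))
  cdf0 <- cdf[cdf > 0][1]
  n <- length(v)
  if (n == cdf0) return(img)  # constant image
  lut <- round((cdf - cdf0) / (n - cdf0) * 255)
  gray_image(matrix(lut[v + 1L], img$height, img$width),
             img$pixel_spacing_mm)
}

# Odd-even transposition sort applied to a list of equal-length vectors:
# after the network runs, element k of the list holds the k-th order
# statistic at every position. Keeps the median filter vectorized.
.sort_network <- function(vs) {
  m <- length(vs)
  for (pass in seq_len(m)) {
    start <- if (pass %% 2 == 1) 1L else 2L
    i <- start
    while (i + 1L <= m) {
      lo <- pmin(vs[[i]], vs[[i + 1L]])
      hi <- pmax(vs[[i]], vs[[i + 1L]])
      vs[[i]] <- lo; vs[[i + 1L]] <- hi
      i <- i + 2L
    }
  }
  vs
}

# reflect-pad a matrix by r rows/cols on each side
.pad_reflect <- function(m, r) {
  # mirror border that does not repeat the edge pixel
  ri <- c(rev(seq_len(r)) + 1L, seq_len(nrow(m)), nrow(m) - seq_len(r))
  ci <- c(rev(seq_len(r)) + 1L, seq_len(ncol(m)), ncol(m) - seq_len(r))
  m[ri, ci, drop = FALSE]
}

#' Median despeckle filter
#'
#' Square median filter with a reflective border, the standard
#' edge-preserving choice against multiplicative speckle noise.
#'
#' @param img a [gray_image()].
#' @param kernel odd window side in pixels (default 3).
#' @return a filtered [gray_image()] of the same size.
#' @export
despeckle <- function(img, kernel = 3L) {
  img <- as_gray_image(img)
  kernel <- as.integer(kernel)
  if (is.na(kernel) || kernel < 3L || kernel %% 2L == 0L)
    stop("`kernel` must be an odd integer >= 3")
  if (kernel > min(img$height, img$width))
    stop("`kernel` exceeds the image size")
  r <- (kernel - 1L) %/% 2L
  p <- .pad_reflect(img$pixels, r)
  h <- img$height; w <- img$width
  shifts <- vector("list", kernel * kernel)
  k <- 1L
  for (di in 0:(kernel - 1L)) for (dj in 0:(kernel - 1L)) {
    shifts[[k]] <- p[di + seq_len(h), dj + seq_len(w), drop = FALSE]
    k <- k + 1L
  }
  med <- .sort_network(shifts)[[(kernel * kernel + 1L) %/% 2L]]
  gray_image(med, img$pixel_spacing_mm)
}

#' Otsu threshold of a grayscale image
#'
#' Exhaustively maximizes the between-class variance over all 255 integer
#' thresholds.
#'
#' @param img a [gray_image()].
#' @return integer threshold t in \[0, 254\]; pixels with intensity > t
#'   form the foreground.
#' @export
otsu_threshold <- function(img) {
  img <- as_gray_image(img)
  h <- tabulate(as.vector(img$pixels) + 1L, 256L)
  if (sum(h > 0) < 2) stop("constant image: no threshold separates it")
  p <- h / sum(h)
  omega <- cumsum(p)                    # P(class0) for t = 0..255
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  t_all <- 1:255                        # candidate thresholds t = 0..254
  w0 <- omega[t_all]
  sigma_b <- (mu_t * w0 - mu[t_all])^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  which.max(sigma_b) - 1L
}

#' Binarize by Otsu's method
#'
#' Produces the foreground mask used for visual quality control of the
#' preprocessing chain; the mask is not a feature input.
#'
#' @param img a [gray_image()].
#' @return logical matrix, `TRUE` where intensity exceeds the Otsu
#'   threshold.
#' @export
binarize <- function(img) {
  img <- as_gray_image(img)
  img$pixels > otsu_threshold(img)
}

#' Axis-aligned pixel rectangle
#'
#' Half-open rectangle \[row0, row1) x \[col0, col1) in 0-based row-major
#' pixel coordinates, used to place the paired analysis regions.
#'
#' @param row0,col0,row1,col1 integer pixel bounds, `row1 > row0`,
#'   `col1 > col0`.
#' @return an object of class `roi_rect`.
#' @export
roi_rect <- function(row0, col0, row1, col1) {
  v <- as.integer(c(row0, col0, row1, col1))
  if (anyNA(v) || v[3] <= v[1] || v[4] <= v[2] || v[1] < 0 || v[2] < 0)
    stop("need 0 <= row0 < row1 and 0 <= col0 < col1")
  structure(list(row0 = v[1], col0 = v[2], row1 = v[3], col1 = v[4]),
            class = "roi_rect")
}

.rect_inside <- function(rect, img) {
  rect$row0 >= 0 && rect$col0 >= 0 &&
    rect$row1 <= img$height && rect$col1 <= img$width
}

.rects_overlap <- function(a, b) {
  a$row0 < b$row1 && b$row0 < a$row1 && a$col0 < b$col1 && b$col0 < a$col1
}

#' Paired lesion/reference regions of interest
#'
#' On each scan two rectangles are marked: `a1` inside the focal lesion
#' and `a2` in normal parenchyma at (as near as possible) the same depth,
#' so both regions experience comparable attenuation and gain.
#'
#' @param a1 lesion rectangle ([roi_rect()]).
#' @param a2 normal-reference rectangle ([roi_rect()]).
#' @return an object of class `roi_pair`.
#' @export
roi_pair <- function(a1, a2) {
  stopifnot(inherits(a1, "roi_rect"), inherits(a2, "roi_rect"))
  if (.rects_overlap(a1, a2)) stop("A1 and A2 must not overlap")
  structure(list(a1 = a1, a2 = a2), class = "roi_pair")
}

#' Validate an ROI pair against the placement principles
#'
#' Checks the rules under which the paired regions are placed: the two
#' rectangles must not overlap, must sit at the same depth (row-centre
#' difference within `depth_tol`, the linear-probe reading of equal
#' depth), and each must be large enough to hold at least one 1 x 1 cm
#' analysis window at the image's pixel spacing.
#'
#' @param img a [gray_image()].
#' @param pair a [roi_pair()] (or a list with `a1`, `a2` rects).
#' @param depth_tol tolerated row-centre difference in pixels (default 10).
#' @return character vector of violated rules, subset of
#'   `c("overlap", "depth", "size")`; empty when all principles hold.
#' @export
validate_roi_pair <- function(img, pair, depth_tol = 10) {
  img <- as_gray_image(img)
  a1 <- pair$a1; a2 <- pair$a2
  if (!.rect_inside(a1, img) || !.rect_inside(a2, img))
    stop("ROI rectangle lies outside the image")
  bad <- character(0)
  if (.rects_overlap(a1, a2)) bad <- c(bad, "overlap")
  c1 <- (a1$row0 + a1$row1) / 2
  c2 <- (a2$row0 + a2$row1) / 2
  if (abs(c1 - c2) > depth_tol) bad <- c(bad, "depth")
  win <- ceiling(10 / img$pixel_spacing_mm)  # 1 cm in pixels
  sides <- c(a1$row1 - a1$row0, a1$col1 - a1$col0,
             a2$row1 - a2$row0, a2$col1 - a2$col0)
  if (any(sides < win)) bad <- c(bad, "size")
  bad
}

#' Crop a rectangle out of an image
#'
#' @param img a [gray_image()].
#' @param rect a [roi_rect()] fully inside the image.
#' @return the cropped [gray_image()]; pixel spacing is preserved.
#' @export
extract_roi <- function(img, rect) {
  img <- as_gray_image(img)
  if (!.rect_inside(rect, img)) stop("rectangle lies outside the image")
  gray_image(img$pixels[(rect$row0 + 1L):rect$row1,
                        (rect$col0 + 1L):rect$col1, drop = FALSE],
             img$pixel_spacing_mm)
}

#' Read an image file as grayscale
#'
#' Reads 8-bit PNG or TIFF (gray or RGB) and converts to a [gray_image()].
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param pixel_spacing_mm pixel spacing to attach.
#' @return a [gray_image()].
#' @export
read_gray_image <- function(path, pixel_spacing_mm = 0.1) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(x)) == 2) x <- round(x * 255)
  to_grayscale(x, pixel_spacing_mm)
}

#' Write a grayscale image (or mask) to PNG
#'
#' @param img a [gray_image()] or a logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  m <- if (is.logical(img)) img * 1 else as_gray_image(img)$pixels / 255
  png::writePNG(m, path)
  invisible(path)
}
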