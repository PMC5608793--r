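#' Grayscale image with physical pixel spacing
#'
#' Container for a single axial 2D MR-like slice: a matrix of finite,
#' non-negative intensities (indexed `[row, col]`) plus the physical pixel
#' size in mm. All geometry in the package uses 0-based `(col, row)`
#' coordinates with pixel centers at integers.
#'
#' @param pixels Numeric matrix, at least 32 x 32, finite, non-negative.
#' @param spacing Numeric length-2: `(row_mm, col_mm)`, both > 0.
#' @param id Optional identifier string.
#' @return An object of class `grayscale_image` with fields `pixels`,
#'   `spacing`, `id`.
#' @export
grayscale_image <- function(pixels, spacing, id = "image") {
  if (!is.matrix(pixels) || nrow(pixels) < 32 || ncol(pixels) < 32)
    stop_thighseg("pixels must be a matrix of at least 32 x 32")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop_thighseg("pixel intensities must be finite and non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_thighseg("spacing must be two positive values (row_mm, col_mm)")
  structure(list(pixels = pixels, spacing = spacing, id = as.character(id)),
            class = "grayscale_image")
}

#' @export
print.grayscale_image <- function(x, ...) {
  cat(sprintf("<grayscale_image '%s' %d x %d, spacing %.3g x %.3g mm, range [%.4g, %.4g]>\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

as_image_matrix <- function(img) {
  if (inherits(img, "grayscale_image")) img$pixels else img
}

#' Load a 2D grayscale image
#'
#' Reads PNG, TIFF or NIfTI. Integer raster formats are read losslessly
#' (8-bit scaled back to 0..255, 16-bit to 0..65535) and require an explicit
#' `spacing`; NIfTI spacing is taken from the header `pixdim`.
#'
#' @param path File path (`.png`, `.tif(f)`, `.nii`, `.nii.gz`).
#' @param spacing `(row_mm, col_mm)`; mandatory for PNG/TIFF, overrides the
#'   header if given for NIfTI.
#' @param slice For 3D NIfTI volumes, the (1-based) slice index along the
#'   third axis.
#' @return A [grayscale_image].
#' @export
load_image <- function(path, spacing = NULL, slice = NULL) {
  if (!file.exists(path)) stop_thighseg("file not found: ", path)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    vol <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(vol)
    arr <- as.array(vol)
    if (length(dim(arr)) == 3) {
      if (dim(arr)[3] == 1) arr <- arr[, , 1]
      else if (is.null(slice)) stop_thighseg("3D NIfTI needs a slice index")
      else arr <- arr[, , slice]
    }
    if (length(dim(arr)) != 2) stop_thighseg("NIfTI is not a 2D slice")
    # NIfTI stores x (column) fastest; transpose to [row, col]
    px <- t(arr)
    sp <- spacing %||% c(pd[2], pd[1])  # pixdim is (dx, dy) = (col, row)
    return(grayscale_image(px, sp, id = basename(path)))
  }
  if (is.null(spacing))
    stop_thighseg("raster formats require explicit pixel spacing")
  if (grepl("\\.png$", lower)) {
    raw <- png::readPNG(path, info = TRUE)
    depth <- attr(raw, "info")$bit.depth %||% 8
    if (length(dim(raw)) == 3) raw <- raw[, , 1]
    px <- round(raw * (2^depth - 1))
  } else if (grepl("\\.tiff?$", lower)) {
    raw <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(raw)) == 3) raw <- raw[, , 1]
    px <- raw
  } else stop_thighseg("unsupported image format: ", path)
  grayscale_image(px, spacing, id = basename(path))
}

#' Save a grayscale image
#'
#' TIFF output (`.tif`/`.tiff`) is written at 16-bit depth (lossless for
#' integer intensities in 0..65535), PNG at 8-bit. Intensities already in
#' `[0, 1]` are scaled to the full depth, otherwise they are written as
#' stored integers.
#'
#' @param img A [grayscale_image] or matrix.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  px <- as_image_matrix(img)
  lower <- tolower(path)
  if (grepl("\\.tiff?$", lower)) {
    if (max(px) > 1) px <- px / 65535
    tiff::writeTIFF(px, path, bits.per.sample = 16)
  } else if (grepl("\\.png$", lower)) {
    if (max(px) > 1) px <- px / 255
    png::writePNG(px, path)
  } else stop_thighseg("unsupported output format: ", path)
  invisible(path)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with clip limit (CLAHE), the contrast
#' enhancement applied before the shape-model search. Output intensities are
#' rescaled to `[0, 1]`; a constant image is returned unchanged (rescaled to
#' its constant level if already in range, else as-is).
#'
#' @param img A [grayscale_image] or matrix.
#' @param tiles Tile grid `(rows, cols)`, each >= 2.
#' @param clip Clip limit as a fraction of the tile pixel count, in (0, 1].
#' @return A [grayscale_image] on the same grid with intensities in `[0, 1]`.
#' @export
equalize_adaptive <- function(img, tiles = c(8, 8), clip = 0.01) {
  stopifnot(length(tiles) == 2, all(tiles >= 2), clip > 0, clip <= 1)
  gi <- if (inherits(img, "grayscale_image")) img else grayscale_image(img, c(1, 1))
  px <- gi$pixels
  rng <- range(px)
  if (rng[1] == rng[2]) {
    out <- if (rng[1] >= 0 && rng[1] <= 1) px else px / max(rng[1], 1)
    return(grayscale_image(pmin(out, 1), gi$spacing, gi$id))
  }
  norm <- (px - rng[1]) / (rng[2] - rng[1])
  # EBImage images are indexed [x, y]
  eq <- EBImage::clahe(t(norm), nx = tiles[2], ny = tiles[1],
                       bins = 256L, limit = max(clip * 256, 1e-6))
  out <- pmin(pmax(t(as.matrix(eq)), 0), 1)
  grayscale_image(out, gi$spacing, gi$id)
}

#' Median filtering with even-window support
#'
#' k x k lower-median filter under reflective padding. For even k (the 2 x 2
#' prefilter and the 6 x 6 filter used before the femur/medulla contour
#' refinement) the output pixel is anchored at the top-left of the window's
#' central 2 x 2 block.
#'
#' @param img A [grayscale_image] or matrix.
#' @param window Window side k, 2..15.
#' @return Filtered image of the same class as the input.
#' @export
median_filter <- function(img, window) {
  window <- as.integer(window)
  if (window < 2 || window > 15) stop_thighseg("window must be in 2..15")
  px <- as_image_matrix(img)
  if (window > min(dim(px))) stop_thighseg("window larger than image")
  out <- median_filter_cpp(px, window)
  if (inherits(img, "grayscale_image"))
    grayscale_image(out, img$spacing, img$id)
  else out
}

#' Range normalization to [0, 1]
#'
#' Affine rescaling by the image extrema. The extrema (`pixel_lowest`,
#' `pixel_highest`) are returned alongside because the tissue threshold is
#' defined relative to them.
#'
#' @param img A [grayscale_image] or matrix; must be non-constant.
#' @return List with `image` (normalized [grayscale_image] / matrix),
#'   `pixel_lowest`, `pixel_highest`.
#' @export
normalize_range <- function(img) {
  px <- as_image_matrix(img)
  rng <- range(px)
  if (rng[1] == rng[2]) stop_thighseg("cannot normalize a constant image")
  out <- (px - rng[1]) / (rng[2] - rng[1])
  if (inherits(img, "grayscale_image"))
    out <- grayscale_image(out, img$spacing, img$id)
  list(image = out, pixel_lowest = rng[1], pixel_highest = rng[2])
}

#' Standard preprocessing for model fitting
#'
#' Adaptive equalization, 2 x 2 lower-median filtering and range
#' normalization, in the pipeline order. Model fitting and the threshold
#' statistics both consume the normalized filtered image; contour refinement
#' consumes the equalized image without median filtering.
#'
#' @param img A [grayscale_image].
#' @param tiles,clip Passed to [equalize_adaptive()].
#' @return List with `fitted` (equalized + 2x2 median + normalized image),
#'   `equalized` (equalized image), `unfiltered` (the input image range
#'   normalized but neither equalized nor median filtered — the image the
#'   contour refinement attaches to), `pixel_lowest`, `pixel_highest`
#'   (extrema of the equalized filtered image before normalization).
#' @export
preprocess_image <- function(img, tiles = c(8, 8), clip = 0.01) {
  eq <- equalize_adaptive(img, tiles, clip)
  filt <- median_filter(eq, 2)
  nr <- normalize_range(filt)
  list(fitted = nr$image, equalized = eq,
       unfiltered = normalize_range(img)$image,
       pixel_lowest = nr$pixel_lowest, pixel_highest = nr$pixel_highest)
}
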