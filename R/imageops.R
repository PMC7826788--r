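# Deterministic image pre-processing (resize + global histogram equalization)
# and prediction post-processing (binarize, keep the two largest connected
# components). Images are H x W matrices: grayscale values 0-255 (integers),
# masks {0, 1}. PNGs store masks as {0, 255}.

check_gray_image <- function(img, name = "img") {
  if (!is.matrix(img) || length(img) == 0L) stop(name, " must be a non-empty matrix")
  if (!all(is.finite(img))) stop(name, " contains non-finite values")
  if (min(img) < 0 || max(img) > 255) stop(name, " is not in 8-bit range 0-255")
  invisible(dim(img))
}

#' Resize a grayscale image or a binary mask
#'
#' Bilinear interpolation for grayscale images (via EBImage), nearest-neighbour
#' for masks so binarity is preserved. Resizing to the current size is the
#' identity on pixel values.
#'
#' @param img H x W numeric matrix.
#' @param target Integer (H, W) target size.
#' @param mask Logical; use nearest-neighbour and keep values binary.
#' @return Resized matrix.
#' @export
resize_image <- function(img, target, mask = FALSE) {
  target <- as.integer(rep(target, length.out = 2L))
  if (identical(dim(img), target)) return(img)
  # EBImage lays images out (x, y) = (width, height), hence the transposes
  filt <- if (mask) "none" else "bilinear"
  out <- t(EBImage::resize(t(img), w = target[2], h = target[1], filter = filt))
  out <- matrix(as.numeric(out), target[1], target[2])
  if (mask) out <- (out > 0.5) + 0L
  out
}

#' Global histogram equalization of an 8-bit image
#'
#' Standard 256-bin cumulative-distribution remap: each gray level v maps to
#' `round(255 * cdf(v))` where cdf is the empirical CDF of the pixel values.
#' The remap is monotone non-decreasing, so pixel-value ordering is preserved;
#' a constant image maps to constant 255 (its single level has cdf 1).
#'
#' @param img H x W matrix with integer values in 0-255.
#' @return Equalized matrix of the same size, integer values in 0-255.
#' @export
equalize_histogram <- function(img) {
  check_gray_image(img)
  v <- as.integer(round(img))
  counts <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(v)
  map <- as.integer(round(255 * cdf))
  matrix(map[v + 1L], nrow(img), ncol(img))
}

#' Preprocess a radiograph for the network
#'
#' Resizes to the target size (bilinear) and then applies global histogram
#' equalization, so the equalization statistics match the resolution the
#' network sees. No mean/standard-deviation normalization is applied.
#'
#' @param img H x W matrix, 8-bit grayscale.
#' @param target Integer (H, W); defaults to 512 x 512.
#' @return Preprocessed 8-bit image of size `target`.
#' @export
preprocess_image <- function(img, target = c(512L, 512L)) {
  check_gray_image(img)
  out <- resize_image(img, target)
  out[out < 0] <- 0
  out[out > 255] <- 255
  equalize_histogram(round(out))
}

#' Threshold a probability map into a binary mask
#'
#' Strict inequality: a pixel is foreground iff `prob > threshold`, so a map
#' exactly at the threshold yields background.
#'
#' @param prob H x W matrix with entries in unit range.
#' @param threshold Scalar in (0, 1); 0.5 is the MSE-on-binary-targets
#'   decision boundary.
#' @return H x W integer matrix in \{0, 1\}.
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (!all(is.finite(prob))) stop("probability map contains non-finite values")
  stopifnot(threshold > 0, threshold < 1)
  m <- (prob > threshold) + 0L
  dim(m) <- dim(prob)
  m
}

#' Label connected components of a binary mask
#'
#' @param mask H x W binary matrix.
#' @param connectivity 4 or 8 (default; diagonal neighbours connect).
#' @return H x W integer matrix of component labels (0 = background), labeled
#'   in row-major order of each component's first pixel.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  storage.mode(mask) <- "integer"
  label_components_cpp(mask, as.integer(connectivity))
}

#' Keep the largest connected components of a mask
#'
#' Removes all but the `k` largest components (by pixel area); ties are broken
#' deterministically in favour of the component whose first pixel comes
#' earlier in row-major order. With the default `k = 2` this implements the
#' two-lung-fields post-processing rule. Never adds a pixel, and is
#' idempotent.
#'
#' @param mask H x W binary matrix.
#' @param k Number of components to keep (default 2).
#' @param connectivity 4 or 8 (default).
#' @return H x W integer mask.
#' @export
keep_largest_components <- function(mask, k = 2L, connectivity = 8L) {
  if (!all(mask %in% c(0L, 1L))) stop("mask must be binary")
  lab <- label_components(mask, connectivity)
  n <- max(lab)
  if (n <= k) {
    out <- mask
    storage.mode(out) <- "integer"
    return(out)
  }
  areas <- tabulate(lab[lab > 0L], nbins = n)
  # labels are assigned in row-major first-pixel order, so ranking by
  # (-area, label) realizes the deterministic tie rule
  keep <- order(-areas, seq_len(n))[seq_len(k)]
  out <- (lab %in% keep) + 0L
  dim(out) <- dim(mask)
  out
}

# ---- PNG I/O ---------------------------------------------------------------

#' Read and write 8-bit grayscale images and binary masks as PNG
#'
#' Images round-trip exactly at 8-bit depth. Masks are stored with foreground
#' 255 and read back as \{0, 1\}.
#'
#' @param path PNG file path.
#' @param img H x W matrix, values 0-255.
#' @param mask H x W binary matrix.
#' @return Readers return a matrix; writers return `path` invisibly.
#' @export
read_gray_image <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  matrix(as.integer(round(v * 255)), nrow(v), ncol(v))
}

#' @rdname read_gray_image
#' @export
write_gray_image <- function(img, path) {
  check_gray_image(img)
  png::writePNG(round(img) / 255, path)
  invisible(path)
}

#' @rdname read_gray_image
#' @export
read_mask <- function(path) {
  (read_gray_image(path) >= 128L) + 0L
}

#' @rdname read_gray_image
#' @export
write_mask <- function(mask, path) {
  if (!all(mask %in% c(0L, 1L))) stop("mask must be binary")
  png::writePNG(mask * 1.0, path)
  invisible(path)
}
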