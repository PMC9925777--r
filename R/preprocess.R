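#' Read an 8-bit greyscale image
#'
#' Reads a single-channel PNG or TIFF image and returns an integer intensity
#' matrix in \[0, 255\] (0 = black, 255 = white). Multi-channel images are
#' rejected rather than silently converted.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Integer matrix of intensities in \[0, 255\].
#' @export
read_grey_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: '", ext, "' (expected png/tif/tiff)")
  )
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L)
      stop("multi-channel image rejected: expected a single greyscale channel, got ",
           dim(img)[3])
    img <- img[, , 1L]
  }
  round(img * 255)
}

#' Write a binary mask as an 8-bit PNG
#'
#' @param mask Logical matrix (`TRUE` = white).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binary_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Otsu threshold of a greyscale image
#'
#' Finds the integer threshold `t` maximising the between-class variance of
#' the image histogram, the classes being pixels with intensity `<= t`
#' (black) and `> t` (white). The threshold is computed once on the whole
#' image, before any patching. Ties at the threshold value go to black; among
#' equally optimal thresholds the smallest is returned.
#'
#' @param img Integer matrix of intensities in \[0, 255\].
#' @return List with `threshold` (integer) and `mask` (logical matrix,
#'   `TRUE` = white/signal phase).
#' @export
otsu_threshold <- function(img) {
  stopifnot(is.matrix(img))
  if (any(img < 0 | img > 255)) stop("intensities must lie in [0, 255]")
  counts <- tabulate(as.integer(img) + 1L, nbins = 256L)
  if (sum(counts > 0) < 2L)
    stop("degenerate histogram: image has fewer than two distinct intensities")
  n <- sum(counts)
  levels <- 0:255
  w0 <- cumsum(counts)[1:255]            # class "<= t" for t = 0..254
  s0 <- cumsum(counts * levels)[1:255]
  total <- sum(counts * levels)
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- s0 / w0
  mu1 <- (total - s0) / w1
  bcv <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  t <- which.max(bcv) - 1L
  list(threshold = t, mask = img > t)
}

#' Trim empty borders from a binary image
#'
#' Removes leading and trailing rows/columns containing no white pixels. An
#' all-black image yields a 0 x 0 matrix.
#'
#' @param mask Logical matrix (`TRUE` = white).
#' @return Trimmed logical matrix.
#' @export
trim_empty_borders <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (length(rows) == 0L) return(matrix(logical(0), 0, 0))
  mask[min(rows):max(rows), min(cols):max(cols), drop = FALSE]
}

#' Pad and tile a binary image into patches
#'
#' Pads the image with black pixels on the bottom and right to the next
#' integer multiple of `side`, tiles it row-major with the given stride
#' (default equal to `side`, i.e. non-overlapping), and discards patches that
#' are entirely background (zero white pixels).
#'
#' @param mask Logical matrix (`TRUE` = white).
#' @param side Patch edge length in pixels (default 300).
#' @param stride Tiling stride (default `side`).
#' @return List of patches; each has `mask` (side x side logical), `origin`
#'   (top-left row/col, 1-based, in the padded image), `patch_row`,
#'   `patch_col` (tile indices) and `n_white`.
#' @export
pad_and_patch <- function(mask, side = 300L, stride = side) {
  stopifnot(side >= 1L, stride >= 1L)
  if (length(mask) == 0L) return(list())
  H <- nrow(mask); W <- ncol(mask)
  Hp <- ceiling(H / side) * side
  Wp <- ceiling(W / side) * side
  padded <- matrix(FALSE, Hp, Wp)
  padded[seq_len(H), seq_len(W)] <- mask
  out <- list()
  pr <- 0L
  for (r0 in seq(1L, Hp - side + 1L, by = stride)) {
    pr <- pr + 1L
    pc <- 0L
    for (c0 in seq(1L, Wp - side + 1L, by = stride)) {
      pc <- pc + 1L
      tile <- padded[r0:(r0 + side - 1L), c0:(c0 + side - 1L), drop = FALSE]
      nw <- sum(tile)
      if (nw == 0L) next
      out[[length(out) + 1L]] <- list(
        mask = tile, origin = c(row = r0, col = c0),
        patch_row = pr, patch_col = pc, n_white = nw)
    }
  }
  out
}

#' Preprocess a greyscale image into binary patches
#'
#' Composes Otsu thresholding (on the whole image), border trimming, padding
#' and tiling, as the first stage of the micro-hole pipeline.
#'
#' @inheritParams otsu_threshold
#' @inheritParams pad_and_patch
#' @param labels Optional named list/vector of patch labels
#'   (e.g. sample, sex, genotype, modality) attached to every patch.
#' @return List of patches as in [pad_and_patch()], each with a `labels`
#'   entry, plus attributes `threshold` and `trimmed_dim`.
#' @export
preprocess_image <- function(img, side = 300L, stride = side, labels = NULL) {
  ot <- otsu_threshold(img)
  trimmed <- trim_empty_borders(ot$mask)
  patches <- pad_and_patch(trimmed, side = side, stride = stride)
  patches <- lapply(patches, function(p) { p$labels <- labels; p })
  attr(patches, "threshold") <- ot$threshold
  attr(patches, "trimmed_dim") <- dim(trimmed)
  patches
}
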