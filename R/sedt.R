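#' Signed Euclidean distance transform
#'
#' Assigns to every pixel the Euclidean distance (between pixel centres) to
#' the nearest pixel of the opposite phase: positive in the white ("bone" /
#' signal) phase, negative in the black ("micro-hole") phase. A black pixel
#' orthogonally adjacent to white therefore has value -1. If one phase is
#' empty the field is an all `+Inf` (all white) or all `-Inf` (all black)
#' sentinel and the result carries attribute `degenerate = TRUE`.
#'
#' @param mask Logical matrix (`TRUE` = white phase).
#' @return Numeric matrix of signed distances, same shape as `mask`, with
#'   attribute `degenerate`.
#' @export
signed_edt <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask), length(mask) >= 1L)
  nw <- sum(mask)
  if (nw == 0L || nw == length(mask)) {
    out <- matrix(if (nw == 0L) -Inf else Inf, nrow(mask), ncol(mask))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  # distmap: per foreground pixel, distance to the nearest background pixel
  d_white <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1), metric = "euclidean"))
  d_black <- EBImage::imageData(EBImage::distmap(EBImage::Image((!mask) * 1), metric = "euclidean"))
  out <- matrix(d_white - d_black, nrow(mask), ncol(mask))
  attr(out, "degenerate") <- FALSE
  out
}

#' Write an SEDT field as 32-bit float TIFF
#'
#' Inspection output: the field is affinely mapped from
#' `[-diag, +diag]` (diag = image diagonal; infinite sentinels are clamped)
#' to the TIFF sample range `[0, 1]`, so 0.5 marks the phase boundary.
#'
#' @param field Numeric matrix from [signed_edt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sedt_tiff <- function(field, path) {
  cap <- sqrt(nrow(field)^2 + ncol(field)^2)
  x <- pmin(pmax(field, -cap), cap)
  tiff::writeTIFF((x / cap + 1) / 2, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
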