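#' Read and write images
#'
#' Thin wrappers over the \pkg{png} (and, when installed, \pkg{tiff})
#' packages.  Images are represented throughout the package as numeric
#' matrices (grayscale) or `h x w x 3` arrays (RGB) with values in
#' `[0, 1]`; pixel `(x, y)` (0-based, x rightward, y downward) is element
#' `[y + 1, x + 1]`.
#'
#' @param path File path; format chosen by extension (`.png`, `.tif(f)`).
#' @return `read_image()` returns a matrix or array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    bcc_error("bccmap_bad_input", paste("image not found:", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        bcc_error("bccmap_bad_input", "the 'tiff' package is required for TIFF input")
      tiff::readTIFF(path)
    },
    bcc_error("bccmap_bad_input", paste("unsupported image format:", ext))
  )
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]  # drop alpha
  if (length(dim(img)) == 3 && dim(img)[3] == 1) img <- img[, , 1]
  img
}

#' @rdname read_image
#' @param img Matrix or `h x w x 3` array in `[0, 1]`.
#' @export
write_image <- function(img, path) {
  img <- clamp01(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        bcc_error("bccmap_bad_input", "the 'tiff' package is required for TIFF output")
      tiff::writeTIFF(img, path)
    },
    bcc_error("bccmap_bad_input", paste("unsupported image format:", ext))
  )
  invisible(path)
}

# resample an image (matrix or array) by an isotropic scale factor using
# bicubic interpolation; scale > 1 enlarges
resample_image <- function(img, scale) {
  d <- dim(img)
  out_h <- max(1L, as.integer(round(d[1] * scale)))
  out_w <- max(1L, as.integer(round(d[2] * scale)))
  cpp_sample_rigid(as.numeric(img), as.integer(dim(img)), out_h, out_w,
                   0, 0, 0, 1 / scale, 0)
}

# sample an image through a rigid pose: out(u) = img(R(theta) (prescale u) + t)
sample_rigid <- function(img, out_h, out_w, pose, prescale = 1, fill = 0) {
  cpp_sample_rigid(as.numeric(img), as.integer(dim(img)),
                   as.integer(out_h), as.integer(out_w),
                   pose$theta, pose$t[1], pose$t[2], prescale, fill)
}

# inscribed-circle mask of a square-ish image; TRUE inside
circle_mask <- function(h, w, margin = 0) {
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  r <- min(w, h) / 2 - margin
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), w), h, w)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

apply_circle_mask <- function(img, fill = NULL) {
  d <- dim(img)
  m <- circle_mask(d[1], d[2])
  if (is.matrix(img)) {
    if (is.null(fill)) fill <- mean(img[m])
    img[!m] <- fill
  } else {
    for (c in seq_len(d[3])) {
      ch <- img[, , c]
      f <- if (is.null(fill)) mean(ch[m]) else fill
      ch[!m] <- f
      img[, , c] <- ch
    }
  }
  img
}
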