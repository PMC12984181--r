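# internal helpers

bcc_error <- function(class, message, ..., call = sys.call(-1)) {
  stop(errorCondition(message, ..., class = c(class, "bccmap_error"),
                      call = call))
}

# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  # keep +pi rather than -pi for the branch point
  out[out == -pi] <- pi
  out
}

is_rgb <- function(img) length(dim(img)) == 3 && dim(img)[3] >= 3

#' Convert an RGB image array to luminance
#'
#' Uses the Rec. 601 luma weights (0.299 R + 0.587 G + 0.114 B), the
#' convention used throughout the package wherever a color image feeds the
#' keypoint detector or a grayscale scorer.
#'
#' @param img Either an `h x w` grayscale matrix (returned unchanged) or an
#'   `h x w x 3` RGB array with values in `[0, 1]`.
#' @return An `h x w` numeric matrix in `[0, 1]`.
#' @export
luminance <- function(img) {
  if (is.matrix(img)) return(img)
  if (!is_rgb(img)) stop("expected a matrix or an h x w x 3 array")
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}
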