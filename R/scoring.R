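#' Lesion-probability scorers
#'
#' A scorer is any pure function mapping a grayscale image region (numeric
#' matrix in `[0, 1]`) to a BCC probability score in percent (`[0, 100]`);
#' the same input must always give the same output.  The clinical device
#' computes this score with a proprietary neural model trained on LC-OCT
#' images; that model is out of scope here, so the package ships a
#' deterministic reference implementation, [reference_density_scorer()],
#' against which the surrounding machinery (heatmaps, thresholds, colormap,
#' trajectory coloring) can be validated exactly.
#'
#' @param scorer A function implementing the scorer contract.
#' @param frame Grayscale matrix in `[0, 1]`.
#' @return `global_score()` returns one score in `[0, 100]` for the whole
#'   frame.
#' @export
global_score <- function(scorer, frame) {
  s <- scorer(frame)
  min(max(as.numeric(s), 0), 100)
}

#' Reference density scorer
#'
#' Scores a B-scan-like grayscale frame as `100 x` the fraction of pixels
#' inside a sub-surface row band whose intensity is at or above a cutoff.
#' This is a deliberately simple, fully deterministic stand-in for a trained
#' lesion classifier: the synthetic B-scan generator
#' ([simulate_bscan()]) calibrates its bright-pixel density against a known
#' spatial probability field, so this scorer recovers that field value.
#'
#' @param intensity_cutoff Gray level in `[0, 1]` (default 0.5) at or above
#'   which a pixel counts as bright.
#' @param band Length-2 fractions of the region height delimiting the
#'   scored sub-surface band (default rows from 15 to 85 percent of the
#'   height, skipping the surface line and the noise floor).
#' @return A scorer function (class `bcc_scorer`).
#' @export
reference_density_scorer <- function(intensity_cutoff = 0.5,
                                     band = c(0.15, 0.85)) {
  stopifnot(intensity_cutoff >= 0, intensity_cutoff <= 1,
            length(band) == 2, band[1] < band[2])
  f <- function(frame) {
    h <- nrow(frame)
    r0 <- max(1L, 1L + floor(band[1] * h))
    r1 <- min(h, ceiling(band[2] * h))
    sub <- frame[r0:r1, , drop = FALSE]
    min(max(100 * mean(sub >= intensity_cutoff), 0), 100)
  }
  attr(f, "intensity_cutoff") <- intensity_cutoff
  attr(f, "band") <- band
  class(f) <- c("bcc_scorer", "function")
  f
}

#' Patch-grid scores
#'
#' Applies a scorer to every patch of a sliding grid covering the frame.
#' Grid origins run from 0 in steps of `stride`; a final origin is added on
#' each axis when needed so the grid covers the frame completely.
#'
#' @param scorer A scorer function (see [global_score()]).
#' @param frame Grayscale matrix in `[0, 1]`.
#' @param patch_size,stride Patch side length and grid stride, px.
#' @return List with `scores` (matrix, rows = y origins, cols = x origins),
#'   `x0`, `y0` (0-based patch origins) and `patch_size`.  Errors with class
#'   `bccmap_patch_too_large` when the patch exceeds the frame.
#' @export
patch_scores <- function(scorer, frame, patch_size = 128, stride = 64) {
  h <- nrow(frame); w <- ncol(frame)
  if (patch_size > h || patch_size > w)
    bcc_error("bccmap_patch_too_large",
              sprintf("patch %d px exceeds frame %d x %d", patch_size, w, h))
  grid_1d <- function(n) {
    o <- seq(0L, n - patch_size, by = stride)
    if (o[length(o)] + patch_size < n) o <- c(o, n - patch_size)
    o
  }
  x0 <- grid_1d(w); y0 <- grid_1d(h)
  scores <- matrix(NA_real_, length(y0), length(x0))
  for (i in seq_along(y0))
    for (j in seq_along(x0))
      scores[i, j] <- global_score(scorer,
        frame[(y0[i] + 1):(y0[i] + patch_size),
              (x0[j] + 1):(x0[j] + patch_size), drop = FALSE])
  list(scores = scores, x0 = x0, y0 = y0, patch_size = patch_size)
}

#' Blue-to-yellow score colormap
#'
#' Linear interpolation in RGB from pure blue `(0, 0, 255)` at score 0 to
#' pure yellow `(255, 255, 0)` at score 100; endpoints are exact and
#' out-of-range scores are clipped.  The map is monotone toward yellow:
#' R and G never decrease, B never increases with score.
#'
#' @param score Numeric vector of scores in percent.
#' @return An `n x 3` integer matrix with columns `r`, `g`, `b` in 0-255.
#' @examples
#' score_to_color(c(0, 50, 100))
#' @export
score_to_color <- function(score) {
  s <- pmin(pmax(as.numeric(score), 0), 100) / 100
  out <- cbind(r = as.integer(round(255 * s)),
               g = as.integer(round(255 * s)),
               b = as.integer(round(255 * (1 - s))))
  out
}

#' Patch heatmap with threshold retention
#'
#' Builds the per-frame heatmap shown over B-scans: the scorer is applied
#' to every grid patch, a threshold keeps only patches at or above
#' `config$patch_score_threshold` (the rest are suppressed), and every
#' retained patch is colored by the *global* score of the frame through
#' [score_to_color()] - so a frame with a high global score shows its
#' suspicious regions in yellowish tones.  Per-patch coloring is available
#' as a diagnostic via `config$heatmap_per_patch_color`.
#'
#' @param scorer A scorer function.
#' @param frame Grayscale matrix in `[0, 1]`.
#' @param config A [bcc_config()] (patch geometry, threshold, color mode).
#' @return A `bcc_heatmap`: list with the patch grid (`x0`, `y0`,
#'   `patch_size`, `stride`), `scores`, logical `retained` mask,
#'   `global_score`, `threshold` and `color` (n_retained x 3 RGB matrix,
#'   one row per retained patch in column-major grid order).
#' @export
build_heatmap <- function(scorer, frame, config = bcc_config()) {
  ps <- patch_scores(scorer, frame, config$patch_size_px,
                     config$patch_stride_px)
  gs <- global_score(scorer, frame)
  retained <- ps$scores >= config$patch_score_threshold
  color <- if (isTRUE(config$heatmap_per_patch_color))
    score_to_color(ps$scores[retained])
  else
    score_to_color(rep(gs, sum(retained)))
  structure(list(x0 = ps$x0, y0 = ps$y0, patch_size = ps$patch_size,
                 stride = config$patch_stride_px, scores = ps$scores,
                 retained = retained, global_score = gs,
                 threshold = config$patch_score_threshold, color = color,
                 frame_shape = c(ncol(frame), nrow(frame))),
            class = "bcc_heatmap")
}

#' @export
print.bcc_heatmap <- function(x, ...) {
  cat(sprintf("<bcc_heatmap> global score %.1f%%, %d / %d patches retained (threshold %.0f%%)\n",
              x$global_score, sum(x$retained), length(x$retained),
              x$threshold))
  invisible(x)
}

#' Render a heatmap as an RGB overlay
#'
#' @param x A `bcc_heatmap`.
#' @param frame The scored grayscale frame (background).
#' @param alpha Overlay opacity for retained patches.
#' @return `h x w x 3` RGB array in `[0, 1]`.
#' @export
heatmap_overlay <- function(x, frame, alpha = 0.45) {
  h <- nrow(frame); w <- ncol(frame)
  out <- array(rep(clamp01(frame), 3), c(h, w, 3))
  idx <- which(x$retained, arr.ind = TRUE)
  if (nrow(idx) == 0) return(out)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    ys <- (x$y0[i] + 1):(x$y0[i] + x$patch_size)
    xs <- (x$x0[j] + 1):(x$x0[j] + x$patch_size)
    col <- x$color[k, ] / 255
    for (c in 1:3)
      out[ys, xs, c] <- (1 - alpha) * out[ys, xs, c] + alpha * col[c]
  }
  out
}

#' @export
plot.bcc_heatmap <- function(x, frame = NULL, ...) {
  if (is.null(frame))
    frame <- matrix(0, x$frame_shape[2], x$frame_shape[1])
  img <- heatmap_overlay(x, frame)
  op <- graphics::par(mar = c(0, 0, 2, 0))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(0, ncol(frame)), c(nrow(frame), 0), asp = 1)
  graphics::rasterImage(img, 0, nrow(frame), ncol(frame), 0)
  graphics::title(sprintf("global score %.1f%%", x$global_score))
  invisible(x)
}
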