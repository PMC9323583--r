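#' Dyadic mesh schedule for box counting
#'
#' Mesh (box) side lengths used for the shrinking-grid box counts: dyadic
#' sizes from the largest power of two not exceeding half the smaller image
#' dimension, down to 2 px. Dyadic sizes make the analytic fixtures (line,
#' gasket, filled square) exact. At least four scales are required by the
#' slope fit, so the smaller image dimension must be at least 32 px (16 px
#' images yield only three scales and are rejected at fit time).
#'
#' @param image_height,image_width image dimensions in pixels; the smaller
#'   must be at least 16.
#' @return integer vector of strictly decreasing mesh sizes.
#' @examples
#' mesh_schedule(256, 256) # 128 64 32 16 8 4 2
#' @export
mesh_schedule <- function(image_height, image_width) {
  m <- min(image_height, image_width)
  if (m < 16) stop_input("image too small for box counting (min dim < 16)")
  kmax <- floor(log2(m / 2))
  as.integer(2^(kmax:1))
}

#' Occupied-box counts over a mesh schedule
#'
#' For each mesh size `s`, overlays a grid of `s x s` cells anchored at the
#' top-left corner (partial cells at the right/bottom edges count as cells)
#' and counts the cells containing at least one foreground pixel.
#'
#' @param skeleton a `skeleton_map`, `binary_map` or 0/1 matrix with at
#'   least one foreground pixel.
#' @param sizes_px mesh sizes, strictly decreasing positive integers;
#'   default [mesh_schedule()] for the image.
#' @return a `box_count_curve`: list with `sizes_px` and `counts`.
#' @export
box_count_curve <- function(skeleton, sizes_px = NULL) {
  px <- as_binary_matrix(skeleton, "skeleton")
  if (sum(px) == 0L) stop_input("empty structure: no foreground pixels")
  if (is.null(sizes_px)) sizes_px <- mesh_schedule(nrow(px), ncol(px))
  sizes_px <- as.integer(sizes_px)
  if (length(sizes_px) < 1L || any(sizes_px < 1L))
    stop_config("mesh sizes must be positive integers")
  if (any(diff(sizes_px) >= 0))
    stop_config("mesh sizes must be strictly decreasing")
  if (max(sizes_px) > min(nrow(px), ncol(px)))
    stop_config("largest mesh size exceeds the image")
  counts <- vapply(sizes_px, function(s) cpp_box_count(px, s), integer(1))
  structure(list(sizes_px = sizes_px, counts = counts),
            class = "box_count_curve")
}

#' Log-log slope fit of a box-count curve
#'
#' Ordinary least squares of `log(count)` on `log(1 / size)` over all
#' scheduled scales; the slope is the box-counting fractal dimension. A
#' flat curve (all counts equal) has slope 0 by convention and is reported
#' with `r_squared = 1`.
#'
#' @param curve a `box_count_curve` with at least 4 scales and all counts
#'   `>= 1`.
#' @return an `fd_result`: `fd`, `intercept`, `r_squared`, `n_scales`.
#' @export
fit_fd <- function(curve) {
  if (!inherits(curve, "box_count_curve"))
    stop_input("curve must be a box_count_curve")
  sizes <- curve$sizes_px; counts <- curve$counts
  if (length(sizes) < 4L)
    stop_input("need at least 4 scales for the slope fit (got ",
               length(sizes), ")")
  if (any(counts < 1)) stop_input("all box counts must be >= 1")
  x <- log(1 / sizes); y <- log(counts)
  if (all(y == y[1])) {
    res <- list(fd = 0, intercept = y[1], r_squared = 1,
                n_scales = length(sizes))
  } else {
    fit <- lm(y ~ x)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    res <- list(fd = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                r_squared = r2, n_scales = length(sizes))
  }
  structure(res, class = "fd_result")
}

#' @export
print.fd_result <- function(x, ...) {
  cat(sprintf("Box-counting fractal dimension: %.4f (R^2 = %.4f, %d scales)\n",
              x$fd, x$r_squared, x$n_scales))
  invisible(x)
}

#' Box-counting fractal dimension of an en-face angiogram
#'
#' Full measurement pipeline for one image: fixed-threshold binarisation,
#' one-pixel skeletonisation, vessel-continuity check, occupied-box counts
#' over the dyadic mesh schedule, and the log-log slope fit. Fails with a
#' processing error when the continuity check fails. Set
#' `skeletonise = FALSE` to count the binary map directly (used for
#' area-like fixtures whose dimension is defined on the mask, e.g. the
#' Sierpinski gasket).
#'
#' @param image an [en_face_image()] or numeric matrix in \[0, 1\].
#' @param threshold binarisation threshold, default 0.5.
#' @param skeletonise count the skeleton (default, the study's procedure)
#'   or the raw binary map.
#' @param sizes_px optional explicit mesh sizes; default dyadic schedule.
#' @return an `fd_result` (see [fit_fd()]); the box-count curve and the
#'   continuity report are attached as attributes `curve` and `continuity`.
#' @export
estimate_fd <- function(image, threshold = 0.5, skeletonise = TRUE,
                        sizes_px = NULL) {
  bin <- binarise(image, threshold)
  if (skeletonise) {
    skel <- fdretina::skeletonise(bin)
    cont <- verify_continuity(bin, skel)
    if (!cont$passed)
      stop_input("continuity check failed: skeleton has ",
                 cont$n_components_skeleton, " components vs ",
                 cont$n_components_binary, " in the binary map")
    target <- skel
  } else {
    cont <- NULL
    target <- bin
  }
  curve <- box_count_curve(target, sizes_px)
  res <- fit_fd(curve)
  attr(res, "curve") <- curve
  attr(res, "continuity") <- cont
  attr(res, "threshold_used") <- threshold
  res
}
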