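#' Parameters of the stochastic vessel-tree angiogram generator
#'
#' Bundles the knobs of the synthetic en-face angiogram simulator: a set of
#' root vessels entering from the image border grows by recursive stochastic
#' bifurcation, with segment angles jittered at each step and stroke width
#' decaying geometrically towards the capillary scale. Rendered strokes are
#' anti-aliased, laid over a dark Gaussian-noise background. The defaults
#' are calibrated once so that the skeleton box-counting dimension of a
#' default tree falls in the range reported for healthy wide-field
#' angiograms (about 1.5-1.8, centred near 1.7).
#'
#' @param size_px image side length in pixels (square image).
#' @param n_roots number of root vessels seeded on the border.
#' @param branch_prob probability that a segment bifurcates at its end.
#' @param angle_jitter_deg standard deviation of the per-step direction
#'   jitter, degrees.
#' @param initial_width_px stroke width of a root vessel, pixels.
#' @param width_decay multiplicative width decay per generation, in (0, 1].
#' @param min_segment_px,max_segment_px segment length bounds, pixels.
#' @param max_depth maximum branching generation.
#' @param background_noise_sd SD of the additive background noise,
#'   intensity units in \[0, 1\].
#' @param vessel_intensity peak stroke intensity, in (0, 1\].
#' @return a list of class `vessel_tree_params`.
#' @export
vessel_tree_params <- function(size_px = 256L,
                               n_roots = 6L,
                               branch_prob = 0.38,
                               angle_jitter_deg = 18,
                               initial_width_px = 3,
                               width_decay = 0.93,
                               min_segment_px = 6L,
                               max_segment_px = 14L,
                               max_depth = 14L,
                               background_noise_sd = 0.05,
                               vessel_intensity = 0.9) {
  p <- list(size_px = as.integer(size_px), n_roots = as.integer(n_roots),
            branch_prob = branch_prob, angle_jitter_deg = angle_jitter_deg,
            initial_width_px = initial_width_px, width_decay = width_decay,
            min_segment_px = as.integer(min_segment_px),
            max_segment_px = as.integer(max_segment_px),
            max_depth = as.integer(max_depth),
            background_noise_sd = background_noise_sd,
            vessel_intensity = vessel_intensity)
  if (p$size_px < 32L) stop_config("size_px must be at least 32")
  if (p$n_roots < 1L) stop_config("n_roots must be positive")
  if (p$branch_prob < 0 || p$branch_prob > 1)
    stop_config("branch_prob must be a probability")
  if (p$width_decay <= 0 || p$width_decay > 1)
    stop_config("width_decay must lie in (0, 1]")
  if (p$min_segment_px > p$max_segment_px)
    stop_config("min_segment_px must not exceed max_segment_px")
  if (p$min_segment_px < 1L) stop_config("segment lengths must be positive")
  if (p$background_noise_sd < 0 || p$background_noise_sd > 1)
    stop_config("background_noise_sd must lie in [0, 1]")
  if (p$vessel_intensity <= 0 || p$vessel_intensity > 1)
    stop_config("vessel_intensity must lie in (0, 1]")
  class(p) <- "vessel_tree_params"
  p
}

# Anti-aliased stroke rasterisation lives in src/pixelops.cpp (cpp_stamp);
# the canvas is modified in place and returned for clarity at call sites.
stamp_segment <- function(canvas, x0, y0, x1, y1, width, intensity) {
  cpp_stamp(canvas, x0, y0, x1, y1, width, intensity)
  canvas
}

#' Simulate a grayscale en-face angiogram as a stochastic vessel tree
#'
#' Grows `n_roots` vessels from the image border by recursive stochastic
#' bifurcation (see [vessel_tree_params()]) and renders them as
#' anti-aliased bright strokes on a dark noisy background. Reproducible:
#' the same `(params, seed)` pair yields a bit-identical image.
#'
#' @param params a [vessel_tree_params()] object.
#' @param seed integer RNG seed.
#' @return numeric matrix with intensities in \[0, 1\].
#' @export
generate_vessel_tree <- function(params = vessel_tree_params(), seed = 1L) {
  if (!inherits(params, "vessel_tree_params"))
    params <- do.call(vessel_tree_params, params)
  with_seed(seed, {
    S <- params$size_px
    canvas <- matrix(0, S, S)
    jit <- params$angle_jitter_deg * pi / 180
    # root entry points spread around the border, heading inward
    side <- sample(4L, params$n_roots, replace = TRUE)
    for (k in seq_len(params$n_roots)) {
      u <- runif(1, 0.15, 0.85) * S
      start <- switch(side[k],
                      c(u, 1),          # top edge, heading down
                      c(u, S),          # bottom edge, heading up
                      c(1, u),          # left edge, heading right
                      c(S, u))          # right edge, heading left
      ang0 <- switch(side[k], pi / 2, -pi / 2, 0, pi) + rnorm(1, 0, jit)
      # iterative stack of branch tips: x, y, angle, width, depth
      stack <- list(c(start[1], start[2], ang0, params$initial_width_px, 0))
      while (length(stack) > 0) {
        tip <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        x <- tip[1]; y <- tip[2]; ang <- tip[3]; w <- tip[4]; d <- tip[5]
        if (d >= params$max_depth || w < 0.7) next
        if (x < -0.1 * S || x > 1.1 * S || y < -0.1 * S || y > 1.1 * S) next
        len <- runif(1, params$min_segment_px, params$max_segment_px)
        ang <- ang + rnorm(1, 0, jit)
        x1 <- x + len * cos(ang); y1 <- y + len * sin(ang)
        canvas <- stamp_segment(canvas, x, y, x1, y1, w,
                                params$vessel_intensity)
        w2 <- w * params$width_decay
        if (runif(1) < params$branch_prob) {
          split <- runif(1, 0.35, 0.6)
          stack[[length(stack) + 1L]] <-
            c(x1, y1, ang + split, w2, d + 1)
          stack[[length(stack) + 1L]] <-
            c(x1, y1, ang - (runif(1, 0.35, 0.6)), w2, d + 1)
        } else {
          stack[[length(stack) + 1L]] <- c(x1, y1, ang, w2, d + 1)
        }
      }
    }
    if (all(canvas == 0))
      stop_input("degenerate parameters rendered zero foreground")
    if (params$background_noise_sd > 0)
      canvas <- canvas + matrix(rnorm(S * S, 0, params$background_noise_sd),
                                S, S)
    pmin(pmax(canvas, 0), 1)
  })
}

#' Repeat-scan perturbation model
#'
#' Describes how a re-acquisition of the same eye differs from the original
#' scan: a rigid sub-pixel translation (head/eye re-centration), a gamma
#' contrast change (device auto-brightness), and fresh acquisition noise.
#' Intra-observer and inter-observer perturbations differ only in
#' magnitude, not in kind.
#'
#' @param shift_px length-2 numeric `(dx, dy)` translation in pixels
#'   (column, row); sub-pixel values are applied by bilinear interpolation.
#' @param noise_reseed if `TRUE`, fresh zero-mean Gaussian noise of SD
#'   `extra_noise_sd` is drawn from the scan's own seed.
#' @param gamma positive contrast exponent applied as `x^gamma`.
#' @param extra_noise_sd SD of the additive acquisition noise.
#' @return a list of class `scan_perturbation`.
#' @export
scan_perturbation <- function(shift_px = c(0, 0), noise_reseed = FALSE,
                              gamma = 1, extra_noise_sd = 0) {
  if (length(shift_px) != 2L || !is.numeric(shift_px))
    stop_config("shift_px must be a numeric (dx, dy) pair")
  if (!is.numeric(gamma) || gamma <= 0) stop_config("gamma must be > 0")
  if (extra_noise_sd < 0) stop_config("extra_noise_sd must be >= 0")
  structure(list(shift_px = as.numeric(shift_px),
                 noise_reseed = isTRUE(noise_reseed),
                 gamma = gamma, extra_noise_sd = extra_noise_sd),
            class = "scan_perturbation")
}

is_identity_perturbation <- function(p) {
  all(p$shift_px == 0) && !p$noise_reseed && p$gamma == 1 &&
    p$extra_noise_sd == 0
}

# overall displacement/noise magnitude, used to order intra vs inter models
perturbation_magnitude <- function(p) {
  sqrt(sum(p$shift_px^2)) + 10 * p$extra_noise_sd + abs(log(p$gamma))
}

# bilinear translation by (dx, dy); out-of-range samples take value 0
shift_bilinear <- function(img, dx, dy) {
  H <- nrow(img); W <- ncol(img)
  xs <- matrix(seq_len(W), H, W, byrow = TRUE) - dx
  ys <- matrix(seq_len(H), H, W) - dy
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  at <- function(r, c) {
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    v <- matrix(0, H, W)
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  v00 <- at(y0, x0); v01 <- at(y0, x0 + 1)
  v10 <- at(y0 + 1, x0); v11 <- at(y0 + 1, x0 + 1)
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

#' Apply a repeat-scan perturbation to an angiogram
#'
#' Applies, in order, the sub-pixel translation, the gamma contrast change
#' and the fresh acquisition noise described by a [scan_perturbation()].
#' The identity perturbation returns the input pixel-for-pixel.
#'
#' @param image numeric matrix with intensities in \[0, 1\].
#' @param p a [scan_perturbation()].
#' @param seed integer RNG seed for the noise draw.
#' @return perturbed image, same dimensions, clipped to \[0, 1\].
#' @export
perturb_scan <- function(image, p = scan_perturbation(), seed = 1L) {
  if (!inherits(p, "scan_perturbation")) p <- do.call(scan_perturbation, p)
  if (!is.matrix(image) || !is.numeric(image))
    stop_input("image must be a numeric matrix")
  if (min(image) < 0 || max(image) > 1)
    stop_input("image intensities must lie in [0, 1]")
  if (is_identity_perturbation(p)) return(image)
  out <- image
  if (any(p$shift_px != 0))
    out <- shift_bilinear(out, p$shift_px[1], p$shift_px[2])
  if (p$gamma != 1) out <- out^p$gamma
  if (p$extra_noise_sd > 0)
    out <- out + with_seed(seed, matrix(rnorm(length(out), 0,
                                              p$extra_noise_sd),
                                        nrow(out), ncol(out)))
  pmin(pmax(out, 0), 1)
}
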