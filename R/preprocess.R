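#' En-face angiogram container
#'
#' Wraps a grayscale intensity matrix (values in \[0, 1\], row-major,
#' origin at the top-left) together with acquisition metadata: which
#' participant, observer and scan it came from, the segmented plexus
#' (superficial `SCP` or deep `DCP`), the eye, and the pixel pitch.
#'
#' @param pixels numeric matrix of intensities in \[0, 1\].
#' @param participant_id,observer_id,scan_index,plexus,eye acquisition
#'   metadata; `observer_id` in `{1, 2}`, `scan_index` in `{1, 2, 3}`,
#'   `plexus` in `{"SCP", "DCP"}`, `eye` in `{"right", "left"}`.
#' @param pixel_pitch_mm millimetres per pixel (metadata only; a 12 mm
#'   field at 256 px is about 0.047 mm/px).
#' @return an object of class `en_face_image`.
#' @export
en_face_image <- function(pixels, participant_id = NA_character_,
                          observer_id = NA_integer_, scan_index = NA_integer_,
                          plexus = NA_character_, eye = NA_character_,
                          pixel_pitch_mm = NA_real_) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    stop_input("pixels must be a non-empty numeric matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop_input("pixel intensities must lie in [0, 1]")
  structure(list(pixels = pixels, participant_id = participant_id,
                 observer_id = observer_id, scan_index = scan_index,
                 plexus = plexus, eye = eye, pixel_pitch_mm = pixel_pitch_mm),
            class = "en_face_image")
}

image_pixels <- function(image) {
  if (inherits(image, "en_face_image")) image$pixels else image
}

#' Fixed-threshold binarisation
#'
#' Classifies every pixel against a single fixed threshold: intensity
#' `>= threshold` becomes vessel (1, white), everything else background
#' (0, black). The `>=` tie-break is part of the contract so results are
#' bit-exact. Binarisation is idempotent: re-thresholding a 0/1 map at the
#' same threshold in (0, 1] returns it unchanged.
#'
#' @param image an [en_face_image()] or a numeric matrix in \[0, 1\].
#' @param threshold intensity cut in \[0, 1\]; default 0.5 (the acquisition
#'   device's fixed cut is not published, so it is configurable).
#' @return a `binary_map`: list with integer 0/1 `pixels` and
#'   `threshold_used`.
#' @export
binarise <- function(image, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop_config("threshold must lie in [0, 1]")
  px <- image_pixels(image)
  if (!is.matrix(px) || length(px) == 0L)
    stop_input("image must be a non-empty matrix")
  out <- matrix(as.integer(px >= threshold), nrow(px), ncol(px))
  structure(list(pixels = out, threshold_used = threshold),
            class = "binary_map")
}

#' One-pixel skeletonisation by iterative morphological thinning
#'
#' Thins the binary vessel mask to its one-pixel-wide centre lines with a
#' Zhang-Suen-style two-subiteration parallel thinning pass, followed by a
#' cleanup that removes 8-simple pixels from any residual fully-foreground
#' 2x2 block. Guarantees: the skeleton lies inside the input mask (thinning
#' only deletes), no 2x2 block is fully foreground, and the number of
#' 8-connected components never increases.
#'
#' @param binary a `binary_map` from [binarise()] or a 0/1 matrix.
#' @return a `skeleton_map`: list with integer 0/1 `pixels`.
#' @export
skeletonise <- function(binary) {
  px <- as_binary_matrix(binary, "binary")
  out <- cpp_thin(px)
  structure(list(pixels = out), class = "skeleton_map")
}

#' Count 8-connected components of a binary image
#'
#' @param x a 0/1 matrix, `binary_map` or `skeleton_map`.
#' @param connectivity 8 (default) or 4.
#' @return integer component count.
#' @export
count_components <- function(x, connectivity = 8L) {
  px <- as_binary_matrix(x, "x")
  cpp_label_components(px, as.integer(connectivity))$n
}

#' Vessel-continuity check after skeletonisation
#'
#' The study protocol requires that binarisation and skeletonisation
#' introduce no discontinuities into the vessel structure. Made testable:
#' the 8-connected component count of the skeleton must not exceed that of
#' the binary map it came from.
#'
#' @param binary a `binary_map` or 0/1 matrix.
#' @param skeleton a `skeleton_map` or 0/1 matrix.
#' @return a `continuity_report`: `n_components_binary`,
#'   `n_components_skeleton`, `passed`.
#' @export
verify_continuity <- function(binary, skeleton) {
  b <- as_binary_matrix(binary, "binary")
  s <- as_binary_matrix(skeleton, "skeleton")
  if (!identical(dim(b), dim(s)))
    stop_input("binary and skeleton dimensions differ")
  nb <- cpp_label_components(b, 8L)$n
  ns <- cpp_label_components(s, 8L)$n
  structure(list(n_components_binary = nb, n_components_skeleton = ns,
                 passed = ns <= nb),
            class = "continuity_report")
}
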