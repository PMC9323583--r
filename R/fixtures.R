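#' Analytic binary fixtures with known box-counting behaviour
#'
#' Deterministic binary images whose box counts (and hence fractal
#' dimensions) have closed forms, used as oracles for the box-counting
#' estimator: a one-pixel horizontal `line` (dimension 1), a
#' `filled_square` (dimension 2), a `single_pixel` (dimension 0), and the
#' `sierpinski` gasket built as Pascal's triangle mod 2 on a dyadic grid
#' (dimension log 3 / log 2). The dyadic construction aligns exactly with
#' the dyadic mesh schedule, so the count at mesh size `2^k` for a depth-d
#' gasket is exactly `3^(d-k)`.
#'
#' @param name one of `"line"`, `"filled_square"`, `"single_pixel"`,
#'   `"sierpinski"`.
#' @param size_px side length of the square image in pixels.
#' @param depth recursion depth, `sierpinski` only; requires
#'   `size_px == 2^depth`.
#' @return an integer 0/1 matrix of dimension `size_px x size_px`.
#' @examples
#' sum(generate_fixture("sierpinski", 16, depth = 4)) # 3^4 = 81
#' @export
generate_fixture <- function(name = c("line", "filled_square",
                                      "single_pixel", "sierpinski"),
                             size_px, depth = NULL) {
  name <- match.arg(name)
  if (!is.numeric(size_px) || length(size_px) != 1L || size_px < 1 ||
      size_px != round(size_px))
    stop_config("size_px must be a positive integer")
  size_px <- as.integer(size_px)
  img <- matrix(0L, size_px, size_px)
  if (name == "line") {
    img[size_px %/% 2L + 1L, ] <- 1L
  } else if (name == "filled_square") {
    img[] <- 1L
  } else if (name == "single_pixel") {
    img[1L, 1L] <- 1L
  } else {
    if (is.null(depth) || depth < 0 || depth != round(depth))
      stop_config("sierpinski requires a non-negative integer depth")
    if (size_px != 2^depth)
      stop_config("sierpinski requires size_px = 2^depth (got ", size_px,
                  " vs 2^", depth, " = ", 2^depth, ")")
    # Pascal's triangle mod 2 via Lucas: cell (i, j) is set iff
    # bitwAnd(i, j) == 0 (0-based), the standard dyadic gasket.
    idx <- 0:(size_px - 1L)
    img <- outer(idx, idx, function(i, j) as.integer(bitwAnd(i, j) == 0L))
  }
  img
}
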