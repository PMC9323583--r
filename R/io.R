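#' Read and write 8-bit grayscale PNG angiograms
#'
#' `read_enface_png()` loads a PNG as an intensity matrix in \[0, 1\]
#' (colour images are averaged to grayscale; 16-bit files are rescaled by
#' their maximum code value by the reader). `write_enface_png()` writes an
#' intensity matrix as 8-bit grayscale.
#'
#' @param path file path.
#' @param image numeric matrix with values in \[0, 1\].
#' @return `read_enface_png()` returns a numeric matrix in \[0, 1\];
#'   `write_enface_png()` returns `path` invisibly.
#' @export
read_enface_png <- function(path) {
  if (!file.exists(path)) stop_input("no such image file: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]),
                                         drop = FALSE], c(1, 2), mean)
  a
}

#' @rdname read_enface_png
#' @export
write_enface_png <- function(image, path) {
  if (!is.matrix(image) || min(image) < 0 || max(image) > 1)
    stop_input("image must be a matrix with values in [0, 1]")
  png::writePNG(image, target = path)
  invisible(path)
}

#' Write the cohort produced by [generate_cohort()] to disk
#'
#' Images go to `<dir>/images/*.png` (8-bit grayscale) and the metadata
#' table to `<dir>/metadata.csv` with an `image_path` column.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return path of the metadata CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- cohort$metadata
  meta$image_path <- file.path("images", paste0(meta$image_key, ".png"))
  for (i in seq_len(nrow(meta)))
    write_enface_png(cohort$images[[meta$image_key[i]]],
                     file.path(dir, meta$image_path[i]))
  out <- file.path(dir, "metadata.csv")
  write.csv(meta[, setdiff(names(meta), "image_key")], out,
            row.names = FALSE)
  invisible(out)
}

#' Read a cohort written by [write_cohort()] (or hand-assembled)
#'
#' @param dir directory holding `metadata.csv` and the image files it
#'   references.
#' @return list with `images` and `metadata` in the layout of
#'   [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stop_input("no metadata.csv in ", dir)
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  meta$image_key <- tools::file_path_sans_ext(basename(meta$image_path))
  images <- list()
  for (i in seq_len(nrow(meta)))
    images[[meta$image_key[i]]] <-
      read_enface_png(file.path(dir, meta$image_path[i]))
  list(images = images, metadata = meta)
}
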