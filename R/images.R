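#' Standardize a cell-morphology image
#'
#' Decodes (if given a path) and standardizes an RGB morphology image to the
#' encoder's input contract: bilinear resize to `size x size` (224 by
#' default), channels-last, pixel values in `[0, 1]`. Grayscale inputs are
#' replicated across the three channels; an alpha channel, if present, is
#' dropped.
#'
#' @param raw_image Numeric array (`h x w x 3` or `h x w`) with values in
#'   `[0, 1]` or `[0, 255]`, or a path to a JPEG/PNG file.
#' @param cell_id Cell-line identifier attached to the result. Defaults to
#'   the file name stem when reading from disk.
#' @param size Target spatial size in pixels.
#' @return A `morphology_image`: list with `pixels`
#'   (`size x size x 3` array in `[0, 1]`) and `cell_id`.
#' @export
preprocess_image <- function(raw_image, cell_id = NULL, size = 224L) {
  if (is.character(raw_image)) {
    path <- raw_image
    if (!file.exists(path)) cdr_validation_error("image file not found: ", path)
    if (is.null(cell_id)) cell_id <- sub("\\.[^.]+$", "", basename(path))
    img <- tryCatch(EBImage::readImage(path),
                    error = function(e) cdr_validation_error(
                      "cannot decode image file ", path, ": ", conditionMessage(e)))
    raw_image <- EBImage::imageData(img)
  }
  px <- unclass(raw_image)
  if (length(px) < 1) cdr_validation_error("image has no pixels")
  if (length(dim(px)) == 2) {
    px <- array(rep(px, 3), dim = c(dim(px), 3))
  }
  if (length(dim(px)) != 3) cdr_validation_error("image must be 2-D or 3-D")
  if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]   # drop alpha
  if (dim(px)[3] == 1) px <- array(rep(px, 3), dim = c(dim(px)[1:2], 3))
  if (max(px) > 1) px <- px / 255          # 8-bit inputs -> [0,1]
  px[px < 0] <- 0
  px[px > 1] <- 1
  if (!(dim(px)[1] == size && dim(px)[2] == size)) {
    img <- EBImage::Image(px, colormode = "Color")
    px <- EBImage::imageData(EBImage::resize(img, w = size, h = size))
    px[px < 0] <- 0
    px[px > 1] <- 1
  }
  dimnames(px) <- NULL
  structure(list(pixels = px, cell_id = cell_id), class = "morphology_image")
}

#' Load one morphology image per cell line from a directory
#'
#' Image file name stems are taken as cell-line identifiers.
#'
#' @param dir Directory containing one JPEG/PNG per cell line.
#' @param cell_ids Required cell-line identifiers, in order. Every id must
#'   have a matching image file.
#' @param size Target spatial size (see [preprocess_image()]).
#' @return List of `morphology_image` objects in `cell_ids` order.
#' @export
load_image_dir <- function(dir, cell_ids, size = 224L) {
  files <- list.files(dir, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                      full.names = TRUE)
  stems <- sub("\\.[^.]+$", "", basename(files))
  idx <- match(cell_ids, stems)
  if (anyNA(idx)) {
    cdr_validation_error("no image for cell line(s): ",
                         paste(cell_ids[is.na(idx)], collapse = ", "),
                         " in ", dir)
  }
  lapply(seq_along(cell_ids), function(i) {
    preprocess_image(files[idx[i]], cell_id = cell_ids[i], size = size)
  })
}

# Stack a list of morphology_image objects into an m x size x size x 3 array.
stack_images <- function(images) {
  cdr_assert(length(images) >= 1, "empty image list")
  d <- dim(images[[1]]$pixels)
  arr <- array(0, dim = c(length(images), d))
  for (i in seq_along(images)) arr[i, , , ] <- images[[i]]$pixels
  arr
}
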