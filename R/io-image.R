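readRaster <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
  else if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path)
  else stop("unsupported image format (use PNG or TIFF): ", path,
            call. = FALSE)
}

#' Read an RGB image
#'
#' Reads a PNG or TIFF into an integer array `(rows, cols, 3)` on the 0..255
#' scale, `(row, col)` indexed, 0-based origin at the top-left. An alpha
#' channel is dropped with a logged warning; single-channel input is an error.
#'
#' @param path image path.
#' @return integer array `(rows, cols, 3)`.
#' @export
readImageRGB <- function(path) {
  img <- readRaster(path)
  if (length(dim(img)) != 3L)
    stop("image format error: expected a 3-channel RGB image", call. = FALSE)
  if (dim(img)[3] == 4L) {
    warning("RGBA input: alpha channel dropped")
    stageLog("read_image", note = "alpha_dropped")
    img <- img[, , 1:3, drop = FALSE]
  }
  stopIfNot(dim(img)[3] == 3L, "image format error: expected 3 channels")
  arr <- round(img * 255)
  storage.mode(arr) <- "integer"
  arr
}

#' Write an RGB image as PNG
#'
#' @param img integer array `(rows, cols, 3)` on 0..255.
#' @param path output `.png` path.
#' @return invisibly, `path`.
#' @export
writeImageRGB <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0L), 255L) / 255, path)
  invisible(path)
}

#' Read / write binary or integer label masks
#'
#' Masks round-trip losslessly: PNG carries 8-bit masks (labels up to 255),
#' TIFF carries 16-bit masks (labels up to 65535). 0 is background.
#'
#' @param mask integer matrix of labels (0 = background).
#' @param path output path; `.png` for 8-bit, `.tif`/`.tiff` for 16-bit.
#' @return `readMask` returns an integer matrix; `writeMask` returns the path
#'   invisibly.
#' @export
writeMask <- function(mask, path) {
  stopIfNot(all(mask >= 0), "mask labels must be non-negative")
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    stopIfNot(max(mask) <= 255, "PNG masks support labels up to 255")
    png::writePNG(mask / 255, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stopIfNot(max(mask) <= 65535, "TIFF masks support labels up to 65535")
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  } else stop("unsupported mask format (use PNG or TIFF)", call. = FALSE)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  img <- readRaster(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  depth <- if (grepl("\\.png$", path, ignore.case = TRUE)) 255 else 65535
  m <- round(img * depth)
  storage.mode(m) <- "integer"
  m
}
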