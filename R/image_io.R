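# Raster I/O. Supported formats: PNG and JPEG in, PNG out.
#
# Conventions: images are integer arrays (H x W x 3, values 0..255), masks
# are logical matrices (TRUE = foreground/tumour), row-major with the origin
# at the top-left. Masks are always written losslessly as 8-bit grayscale
# PNG (foreground 255, background 0) so that pixel-level evaluation is never
# corrupted by compression artefacts.

# Decode a PNG/JPEG file to a numeric array in [0,1]. Format is detected
# from the file's magic bytes, not its extension.
read_raster <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop_chromaseg("`path` must be a single file path", "chromaseg_io_error")
  }
  if (!file.exists(path)) {
    stop_chromaseg(sprintf("cannot read image: file does not exist: '%s'", path),
                   "chromaseg_io_error")
  }
  magic <- readBin(path, "raw", n = 8L)
  arr <- tryCatch({
    if (length(magic) >= 8L &&
        identical(magic[1:4], as.raw(c(0x89, 0x50, 0x4e, 0x47)))) {
      png::readPNG(path)
    } else if (length(magic) >= 2L &&
               identical(magic[1:2], as.raw(c(0xff, 0xd8)))) {
      jpeg::readJPEG(path)
    } else {
      stop_chromaseg(
        sprintf("unsupported image format in '%s' (PNG and JPEG are supported)",
                path),
        "chromaseg_io_error")
    }
  }, error = function(e) {
    if (inherits(e, "chromaseg_io_error")) stop(e)
    stop_chromaseg(sprintf("failed to decode image '%s': %s", path,
                           conditionMessage(e)),
                   "chromaseg_io_error")
  })
  arr
}

# Collapse a decoded [0,1] array to H x W x nchannel integer (0..255).
decode_channels <- function(arr) {
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
  nch <- dim(arr)[3L]
  # 2 channels = gray+alpha, 4 = rgb+alpha: alpha is dropped.
  if (nch == 2L) arr <- arr[, , 1L, drop = FALSE]
  if (nch == 4L) arr <- arr[, , 1:3, drop = FALSE]
  round_half_up(arr * 255)
}

#' Read an RGB photomicrograph
#'
#' Reads a PNG or JPEG image into an `H x W x 3` integer array with values
#' in `[0, 255]`. Grayscale files are replicated to three channels and any
#' alpha channel is dropped.
#'
#' @param path Path to a PNG or JPEG file.
#' @return An `H x W x 3` integer array (top-left origin, row-major).
#' @examples
#' tf <- tempfile(fileext = ".png")
#' png::writePNG(matrix(1, 2, 2), tf)   # 2x2 pure white
#' img <- read_rgb_image(tf)
#' stopifnot(all(img == 255), dim(img)[3] == 3)
#' @export
read_rgb_image <- function(path) {
  px <- decode_channels(read_raster(path))
  if (dim(px)[3L] == 1L) {
    px <- array(rep(px[, , 1L], 3L), dim = c(dim(px)[1:2], 3L))
  }
  storage.mode(px) <- "integer"
  px
}

#' Read a binary mask
#'
#' Reads a PNG or JPEG file and binarizes it: a pixel is foreground iff its
#' channel-averaged 8-bit value is `>= threshold`. The `>=` rule (default
#' threshold 128) binarizes anti-aliased scans of hand-drawn delineations
#' sensibly.
#'
#' @param path Path to the mask file.
#' @param threshold 8-bit cutoff; foreground iff mean channel value is
#'   `>= threshold`.
#' @return A logical `H x W` matrix, `TRUE` = foreground.
#' @export
read_mask <- function(path, threshold = 128) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  px <- decode_channels(read_raster(path))
  avg <- if (dim(px)[3L] == 1L) px[, , 1L] else apply(px, c(1, 2), mean)
  avg >= threshold
}

#' Write a binary mask as 8-bit grayscale PNG
#'
#' Foreground is written as 255, background as 0. `read_mask(write_mask(m))`
#' recovers `m` exactly (PNG is lossless).
#'
#' @param mask Logical matrix, `TRUE` = foreground.
#' @param path Output path; the parent directory must exist.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!dir.exists(dirname(path))) {
    stop_chromaseg(sprintf("cannot write mask: directory does not exist: '%s'",
                           dirname(path)),
                   "chromaseg_io_error")
  }
  tryCatch(
    png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path),
    error = function(e) {
      stop_chromaseg(sprintf("failed to write mask '%s': %s", path,
                             conditionMessage(e)),
                     "chromaseg_io_error")
    })
  invisible(path)
}

#' Write an RGB image as PNG
#'
#' @param image `H x W x 3` integer array with values in `[0, 255]`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rgb_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3L] == 3L)
  if (!dir.exists(dirname(path))) {
    stop_chromaseg(sprintf("cannot write image: directory does not exist: '%s'",
                           dirname(path)),
                   "chromaseg_io_error")
  }
  png::writePNG(image / 255, path)
  invisible(path)
}
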