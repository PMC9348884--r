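#' Construct a microscope frame
#'
#' A frame is one greyscale image from the side-view jet microscope together
#' with its position in the acquisition sequence and the optical pixel scale.
#' Intensities live on the unsigned 16-bit scale \[0, 65535\]; 8-bit sources
#' are rescaled on read so the whole pipeline works on one internal range.
#'
#' @param pixels Numeric matrix of intensities in \[0, 65535\], at least
#'   32 x 32. Row 1 is the top of the image.
#' @param index Non-negative integer position in the sequence.
#' @param pixel_size_um Micrometres per pixel (> 0). The microscope's optical
#'   scale; distance-based rules (the 200 um break-distance cut) are
#'   meaningless without it, so there is no default.
#' @return An object of class `jet_frame`: a list with elements `pixels`,
#'   `index` and `pixel_size_um`.
#' @seealso [read_frame()], [write_frame()], [read_sequence()]
#' @export
#' @examples
#' f <- new_frame(matrix(40000, 32, 32), index = 0, pixel_size_um = 1)
#' f
new_frame <- function(pixels, index = 0L, pixel_size_um) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 32L || ncol(pixels) < 32L) {
    stop("frame must be at least 32 x 32 pixels, got ",
         nrow(pixels), " x ", ncol(pixels), call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 65535) {
    stop("intensities must lie in [0, 65535] with no missing values",
         call. = FALSE)
  }
  index <- as.integer(index)
  if (is.na(index) || index < 0L) {
    stop("`index` must be a non-negative integer", call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  }
  structure(
    list(pixels = pixels, index = index, pixel_size_um = as.numeric(pixel_size_um)),
    class = "jet_frame"
  )
}

#' @export
print.jet_frame <- function(x, ...) {
  cat(sprintf("<jet_frame> %d x %d px, index %d, %.3g um/px, intensity [%d, %d]\n",
              nrow(x$pixels), ncol(x$pixels), x$index, x$pixel_size_um,
              round(min(x$pixels)), round(max(x$pixels))))
  invisible(x)
}

#' @export
dim.jet_frame <- function(x) dim(x$pixels)

# Accept either a jet_frame or a bare matrix in image-processing functions.
as_pixels <- function(x) {
  if (inherits(x, "jet_frame")) x$pixels
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected a `jet_frame` or a numeric matrix", call. = FALSE)
}

#' Read one frame from a TIFF or PNG file
#'
#' Reads a single-channel image and returns it on the 16-bit scale. 8-bit
#' inputs are up-scaled by 257 (so 255 maps to 65535); native 16-bit input is
#' read losslessly. Multi-channel (colour or grey+alpha) images are rejected.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @inheritParams new_frame
#' @return A [new_frame()] object.
#' @export
read_frame <- function(path, index = 0L, pixel_size_um) {
  if (!file.exists(path)) {
    stop("cannot read frame: no such file: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    "tif" = , "tiff" = tiff::readTIFF(path),
    "png" = png::readPNG(path),
    stop("unsupported image format: .", ext, " (use TIFF or PNG)", call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    stop("multi-channel image (", dim(img)[3],
         " channels); a single-channel greyscale image is required",
         call. = FALSE)
  }
  # Readers normalize to [0, 1]: v/255 for 8-bit, v/65535 for 16-bit. Mapping
  # back with round(x * 65535) is exact for 16-bit and equals v * 257 for
  # 8-bit, which is the intended up-scaling.
  new_frame(round(img * 65535), index = index, pixel_size_um = pixel_size_um)
}

#' Write a frame as 16-bit greyscale TIFF
#'
#' Lossless for integer-valued intensities: a read/write/read round trip on a
#' 16-bit TIFF reproduces the pixel matrix exactly.
#'
#' @param frame A [new_frame()] object.
#' @param path Output path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  px <- as_pixels(frame)
  tiff::writeTIFF(round(px) / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read an image sequence from a directory
#'
#' Frames are ordered by filename, lexicographically in the C locale, and
#' assigned indices 0, 1, 2, ... in that order; filesystem creation order and
#' timestamps are ignored.
#'
#' @param dir Directory containing the frames.
#' @param pattern Glob pattern for filenames (default all TIFFs).
#' @inheritParams new_frame
#' @return A list of [new_frame()] objects (possibly empty).
#' @export
read_sequence <- function(dir, pattern = "*.tif*", pixel_size_um) {
  if (!dir.exists(dir)) {
    stop("no such directory: ", dir, call. = FALSE)
  }
  files <- list.files(dir, pattern = utils::glob2rx(pattern), full.names = FALSE)
  files <- sort(files, method = "radix")
  purrr::imap(files, function(f, i) {
    read_frame(file.path(dir, f), index = i - 1L, pixel_size_um = pixel_size_um)
  })
}
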