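#' Grayscale image container
#'
#' A grayscale image is a numeric matrix of non-negative, finite intensities
#' (rows = y/height, columns = x/width) with class `"gray_image"` and an
#' optional `source_path` attribute. Integer data read from disk keeps its
#' native scale (an 8-bit image spans 0--255, a 16-bit image 0--65535); no
#' rescaling to `[0, 1]` is performed.
#'
#' @param pixels Numeric matrix of intensities.
#' @param source_path Optional character path or identifier.
#' @return A `gray_image` object (a numeric matrix).
#' @examples
#' img <- gray_image(matrix(runif(32 * 32), 32, 32))
#' dim(img)
#' @export
gray_image <- function(pixels, source_path = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 16L || ncol(pixels) < 16L) {
    stop("image must be at least 16x16 pixels (got ",
         nrow(pixels), "x", ncol(pixels), ")", call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("image contains non-finite pixel values", call. = FALSE)
  }
  if (min(pixels) < 0) {
    stop("image contains negative pixel values", call. = FALSE)
  }
  storage.mode(pixels) <- "double"  # integer arithmetic overflows downstream
  structure(pixels, class = c("gray_image", class(pixels)),
            source_path = source_path)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, range [%g, %g]%s\n",
              nrow(x), ncol(x), min(x), max(x),
              if (!is.null(attr(x, "source_path")))
                paste0(", source: ", attr(x, "source_path")) else ""))
  invisible(x)
}

# strip class/attrs down to a bare matrix (internal)
as_matrix <- function(img) {
  m <- unclass(img)
  attr(m, "source_path") <- NULL
  m
}

supported_ext <- c("tif", "tiff", "png", "jpg", "jpeg")

# collapse a h x w x c array to one channel by unweighted channel mean;
# alpha (4th channel) is dropped rather than averaged in
collapse_channels <- function(a) {
  if (length(dim(a)) == 2L) return(a)
  nc <- dim(a)[3L]
  if (nc == 2L || nc == 4L) nc <- nc - 1L  # gray+alpha / RGBA
  apply(a[, , seq_len(nc), drop = FALSE], c(1L, 2L), mean)
}

#' Read an image file as a grayscale image
#'
#' Reads TIFF, PNG or JPEG files into a [gray_image()]. Color images are
#' reduced to one channel by the unweighted mean of the color channels
#' (an alpha channel, when present, is dropped). Multi-page TIFFs use the
#' first page. Integer data is kept at its native scale: an 8-bit file
#' yields values in 0--255 and a 16-bit file values in 0--65535.
#'
#' @param path Path to a `.tif`/`.tiff`, `.png`, `.jpg` or `.jpeg` file
#'   (case-insensitive).
#' @return A [gray_image()] with `source_path` set to `path`.
#' @seealso [save_image()], [list_dataset()]
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    stop("image file does not exist: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% supported_ext) {
    stop("unsupported image format '", ext, "' for: ", path, call. = FALSE)
  }
  a <- tryCatch(
    switch(ext,
      tif  = ,
      tiff = {
        x <- tiff::readTIFF(path, all = FALSE, as.is = TRUE)
        if (is.list(x)) x <- x[[1L]]
        x
      },
      png = {
        x <- png::readPNG(path, info = TRUE)
        depth <- attr(x, "info")$bit.depth
        if (is.null(depth)) depth <- 8L
        round(x * (2^depth - 1))
      },
      jpg  = ,
      jpeg = round(jpeg::readJPEG(path) * 255)
    ),
    error = function(e) {
      stop("failed to read image ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (is.null(dim(a))) {
    stop("failed to read image ", path, ": no pixel data", call. = FALSE)
  }
  gray_image(collapse_channels(a), source_path = path)
}

#' Write a grayscale image to a TIFF file
#'
#' Writes integer-valued grayscale data as an uncompressed 8- or 16-bit
#' TIFF. Values are clipped to the representable range and rounded, so
#' `load_image(save_image(img))` round-trips integer data bit-exactly.
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param path Output file path (`.tif`).
#' @param bits Bits per sample, 8 or 16.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path, bits = 16L) {
  if (!bits %in% c(8L, 16L)) stop("`bits` must be 8 or 16", call. = FALSE)
  m <- as_matrix(img)
  top <- 2^bits - 1
  m <- round(pmin(pmax(m, 0), top))
  tiff::writeTIFF(m / top, path, bits.per.sample = as.integer(bits),
                  compression = "none")
  invisible(path)
}

#' Enumerate the image files of a dataset directory
#'
#' Lists the supported image files (`.tif`, `.tiff`, `.png`, `.jpg`,
#' `.jpeg`, case-insensitive) of a directory, sorted lexicographically by
#' filename (byte order, locale-independent) so that enumeration is
#' reproducible across runs and platforms. An optional substring filter
#' selects filenames containing the substring, case-insensitively --
#' useful e.g. to separate STED from confocal exposures sharing a
#' directory.
#'
#' @param directory Path to an existing directory.
#' @param name_filter Optional substring; only filenames containing it
#'   (ignoring case) are returned.
#' @return Character vector of full file paths in lexicographic filename
#'   order. Raises an error when no file matches.
#' @export
list_dataset <- function(directory, name_filter = NULL) {
  if (!dir.exists(directory)) {
    stop("dataset directory does not exist: ", directory, call. = FALSE)
  }
  files <- list.files(directory, full.names = TRUE)
  files <- files[tolower(tools::file_ext(files)) %in% supported_ext]
  if (!is.null(name_filter) && nzchar(name_filter)) {
    keep <- grepl(name_filter, basename(files), ignore.case = TRUE,
                  fixed = FALSE)
    files <- files[keep]
  }
  if (length(files) == 0L) {
    stop("empty dataset: no supported image files",
         if (!is.null(name_filter)) paste0(" matching '", name_filter, "'"),
         " in ", directory, call. = FALSE)
  }
  files[order(basename(files), method = "radix")]
}
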