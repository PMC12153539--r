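#' Slide image container
#'
#' Wraps an 8-bit-equivalent RGB raster (stored as doubles in \[0, 1\])
#' together with its level-0 resolution in microns per pixel (mpp) and
#' optional identifiers. This is the unit of classification: all patch
#' coordinates elsewhere in the package are level-0 pixel offsets into this
#' raster, 0-based, with `x` indexing columns and `y` indexing rows.
#'
#' @param img numeric array `H x W x 3` with values in \[0, 1\].
#' @param mpp microns per pixel at level 0 (positive float).
#' @param slide_id optional slide identifier.
#' @param label optional slide label, `"benign"` or `"metastatic"`.
#' @return An object of class `slide_image`.
#' @export
slide_image <- function(img, mpp = 1.0, slide_id = NULL, label = NULL) {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3) {
    abort("img must be an H x W x 3 RGB array")
  }
  if (anyNA(img) || min(img) < 0 || max(img) > 1) {
    abort("img values must be finite and in [0, 1]")
  }
  if (!is.numeric(mpp) || mpp <= 0) abort("mpp must be a positive number")
  if (!is.null(label)) label <- check_labels(label, "label")
  structure(
    list(img = img, mpp = mpp, slide_id = slide_id, label = label),
    class = "slide_image"
  )
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$img)
  cat(sprintf("<slide_image> %s  %d x %d px  %.3g um/px  label: %s\n",
              x$slide_id %||% "(unnamed)", d[2], d[1], x$mpp,
              x$label %||% "(none)"))
  invisible(x)
}

#' @export
dim.slide_image <- function(x) dim(x$img)

# width / height in level-0 pixels
slide_width <- function(slide) dim(slide$img)[2]
slide_height <- function(slide) dim(slide$img)[1]

#' Read a slide image from disk
#'
#' Reads an 8-bit RGB PNG or TIFF into a [slide_image]. Greyscale or RGBA
#' rasters are promoted/truncated to 3 channels.
#'
#' @param path file path; format chosen by extension (`.png`, `.tif(f)`).
#' @param mpp microns per pixel at level 0.
#' @inheritParams slide_image
#' @return A [slide_image].
#' @export
read_slide <- function(path, mpp = 1.0, slide_id = NULL, label = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort("reading TIFF slides requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    },
    abort(sprintf("unsupported slide format: .%s", ext))
  )
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  slide_image(img, mpp = mpp,
              slide_id = slide_id %||% tools::file_path_sans_ext(basename(path)),
              label = label)
}

#' Write a slide image to disk as PNG
#'
#' @param slide a [slide_image].
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path) {
  png::writePNG(slide$img, path)
  invisible(path)
}

#' Thumbnail of a slide by area-average downsampling
#'
#' @param slide a [slide_image].
#' @param downsample integer linear downsample factor.
#' @return `H/downsample x W/downsample x 3` array.
#' @export
make_thumbnail <- function(slide, downsample = 16L) {
  block_mean_rgb(slide$img, as.integer(downsample))
}
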