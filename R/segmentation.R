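#' Segment tissue from background by saturation thresholding
#'
#' Tissue in an H&E slide is strongly coloured (high HSV saturation) while
#' the glass background is near-white (saturation close to zero). The mask
#' is computed at a reduced working resolution: the slide is area-average
#' downsampled by `downsample`, its per-pixel HSV saturation is median
#' filtered to suppress salt noise, thresholded, morphologically closed, and
#' connected components smaller than `min_region_area_px` (in mask pixels)
#' are discarded.
#'
#' @param slide a [slide_image] (RGB).
#' @param sat_threshold saturation threshold in \[0, 1\]; a pixel is tissue
#'   iff its saturation exceeds this. Default 8/255, the usual choice for
#'   8-bit saturation thresholding in weakly supervised WSI pipelines.
#' @param min_region_area_px minimum connected-component area kept, in mask
#'   pixels.
#' @param closing_radius_px disc radius of the morphological closing, in
#'   mask pixels (0 disables closing).
#' @param downsample integer linear downsample from level 0 at which the
#'   mask is computed.
#' @param median_radius radius of the median filter applied to the
#'   saturation raster before thresholding (0 disables).
#' @return An object of class `tissue_mask`: list with `mask` (logical
#'   matrix), `downsample`, and `tissue_fraction` (positive pixels / total).
#' @export
segment_tissue <- function(slide, sat_threshold = 8 / 255,
                           min_region_area_px = 16L, closing_radius_px = 2L,
                           downsample = 16L, median_radius = 2L) {
  if (!inherits(slide, "slide_image")) {
    if (is.array(slide) && length(dim(slide)) == 3 && dim(slide)[3] == 3) {
      slide <- slide_image(slide)
    } else {
      abort("slide must be a slide_image or an H x W x 3 RGB array")
    }
  }
  small <- block_mean_rgb(slide$img, as.integer(downsample))
  sat <- saturation_of(small)
  if (median_radius > 0) {
    # pad by replication so the filter does not erode the borders
    r <- as.integer(median_radius)
    sat <- pad_replicate(sat, r)
    sat <- EBImage::medianFilter(sat, r)
    sat <- unpad(sat, r)
  }
  mask <- sat > sat_threshold
  if (closing_radius_px > 0 && any(mask)) {
    r <- as.integer(closing_radius_px)
    m <- pad_replicate(mask * 1, r + 1L)
    brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
    m <- EBImage::closing(m, brush)
    mask <- unpad(m, r + 1L) > 0.5
  }
  if (min_region_area_px > 0 && any(mask)) {
    lab <- EBImage::bwlabel(mask * 1)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_region_area_px)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  structure(
    list(mask = mask, downsample = as.integer(downsample),
         tissue_fraction = mean(mask)),
    class = "tissue_mask"
  )
}

pad_replicate <- function(m, r) {
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

unpad <- function(m, r) {
  m[(r + 1L):(nrow(m) - r), (r + 1L):(ncol(m) - r), drop = FALSE]
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> %d x %d at 1/%d  tissue fraction %.3f\n",
              ncol(x$mask), nrow(x$mask), x$downsample, x$tissue_fraction))
  invisible(x)
}

# tissue fraction of one level-0 box, measured on the downsampled mask
box_tissue_fraction <- function(mask, downsample, x, y, size) {
  r0 <- floor(y / downsample) + 1L
  r1 <- min(ceiling((y + size) / downsample), nrow(mask))
  c0 <- floor(x / downsample) + 1L
  c1 <- min(ceiling((x + size) / downsample), ncol(mask))
  mean(mask[r0:r1, c0:c1])
}

#' Enumerate the non-overlapping tissue patch grid of a slide
#'
#' Tiles the slide with non-overlapping `patch_size_level0` boxes anchored
#' at (0, 0) (0-based, half-open), discards boxes extending past the slide
#' bounds, and keeps boxes whose tissue fraction on the mask is at least
#' `min_tissue_frac`. Extraction downsamples each kept box to
#' `out_size` pixels, i.e. by the factor `patch_size_level0 / out_size`
#' (1024 at full resolution down to 256, a 4x reduction to 10x apparent
#' magnification for a 40x scan).
#'
#' @param slide a [slide_image].
#' @param mask a `tissue_mask` aligned to the slide.
#' @param patch_size_level0 patch edge in level-0 pixels.
#' @param out_size output patch edge in pixels; must divide
#'   `patch_size_level0`.
#' @param min_tissue_frac minimum tissue fraction for a patch to be kept.
#' @param stride grid stride in level-0 pixels; defaults to
#'   `patch_size_level0` (non-overlapping). Heatmapping uses
#'   `patch_size_level0 / 2` (50% overlap).
#' @return A `patch_set`: tibble with columns `slide_id`, `x`, `y`,
#'   `tissue_frac`, carrying `patch_size_level0`, `out_size`,
#'   `min_tissue_frac` and `stride` as attributes.
#' @export
extract_patch_grid <- function(slide, mask, patch_size_level0 = 1024L,
                               out_size = 256L, min_tissue_frac = 0.5,
                               stride = patch_size_level0) {
  stopifnot(inherits(mask, "tissue_mask"))
  patch_size_level0 <- as.integer(patch_size_level0)
  out_size <- as.integer(out_size)
  if (out_size < 1 || patch_size_level0 < 1 || patch_size_level0 %% out_size != 0) {
    abort("patch_size_level0 must be a positive multiple of out_size")
  }
  W <- slide_width(slide); H <- slide_height(slide)
  xs <- seq(0L, W - patch_size_level0, by = as.integer(stride))
  ys <- seq(0L, H - patch_size_level0, by = as.integer(stride))
  if (W < patch_size_level0 || H < patch_size_level0) xs <- ys <- integer(0)
  grid <- tidyr::expand_grid(x = xs, y = ys)
  if (nrow(grid) > 0) {
    grid$tissue_frac <- purrr::map2_dbl(
      grid$x, grid$y,
      function(x, y) box_tissue_fraction(mask$mask, mask$downsample, x, y,
                                         patch_size_level0))
    grid <- dplyr::filter(grid, .data$tissue_frac >= min_tissue_frac)
  } else {
    grid$tissue_frac <- numeric(0)
  }
  out <- tibble::tibble(slide_id = slide$slide_id %||% NA_character_,
                        x = as.integer(grid$x), y = as.integer(grid$y),
                        tissue_frac = grid$tissue_frac)
  structure(out,
            patch_size_level0 = patch_size_level0, out_size = out_size,
            min_tissue_frac = min_tissue_frac, stride = as.integer(stride),
            class = c("patch_set", class(out)))
}

#' Read one patch from a slide with area-average downsampling
#'
#' @param slide a [slide_image].
#' @param coord numeric pair `c(x, y)`: 0-based level-0 top-left corner.
#' @param patch_size_level0 patch edge in level-0 pixels.
#' @param out_size output edge; each output pixel is the mean of its
#'   `(patch_size_level0/out_size)^2` source block.
#' @return `out_size x out_size x 3` array.
#' @export
read_patch <- function(slide, coord, patch_size_level0 = 1024L,
                       out_size = 256L) {
  x <- as.integer(coord[[1]]); y <- as.integer(coord[[2]])
  ps <- as.integer(patch_size_level0); os <- as.integer(out_size)
  if (ps %% os != 0) abort("patch_size_level0 must be a positive multiple of out_size")
  W <- slide_width(slide); H <- slide_height(slide)
  if (x < 0 || y < 0 || x + ps > W || y + ps > H) {
    abort(sprintf("patch at (%d, %d) size %d is out of slide bounds %d x %d",
                  x, y, ps, W, H))
  }
  sub <- slide$img[(y + 1):(y + ps), (x + 1):(x + ps), , drop = FALSE]
  block_mean_rgb(sub, ps %/% os)
}
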