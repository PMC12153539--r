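#' Patch feature extractor contract
#'
#' An extractor is a triple (id, dimension, patch -> vector function). The
#' pipeline only ever talks to this contract, so a pretrained histopathology
#' encoder (e.g. a foundation model producing 1024-d embeddings) can be
#' plugged in by wrapping its forward pass; nothing in this package requires
#' one. The shipped [toy_extractor()] is a deterministic colour/texture
#' descriptor sufficient for the synthetic slides.
#'
#' @param id extractor identifier string (recorded in every bag).
#' @param dim output feature dimension.
#' @param fn function taking an `s x s x 3` RGB array and returning a
#'   length-`dim` numeric vector.
#' @return An object of class `wsi_extractor`.
#' @export
extractor <- function(id, dim, fn) {
  stopifnot(is.character(id), is.function(fn), dim >= 1)
  structure(list(id = id, dim = as.integer(dim), fn = fn),
            class = "wsi_extractor")
}

#' @export
print.wsi_extractor <- function(x, ...) {
  cat(sprintf("<wsi_extractor> %s  D = %d\n", x$id, x$dim))
  invisible(x)
}

#' Deterministic colour/texture patch descriptor (D = 62)
#'
#' Concatenates, in order: per-channel mean and standard deviation in RGB
#' (6) and HSV (6); a 16-bin grey-level histogram (proportions, 16); the
#' mean finite-difference gradient magnitude of the grey image (1); the
#' fraction of pixels darker than `dark_threshold` in grey — a surrogate
#' for nucleus density (1); 4x4 block grey means (16); and 4x4 block
#' saturation means (16). Total 62. Purely arithmetic, so identical patches
#' always map to identical vectors.
#'
#' @param patch `s x s x 3` RGB array with values in \[0, 1\]; `s` must be a
#'   multiple of 4.
#' @param dark_threshold grey level below which a pixel counts as dark.
#' @return numeric vector of length 62.
#' @export
toy_descriptor <- function(patch, dark_threshold = 0.35) {
  if (!is.array(patch) || length(dim(patch)) != 3 || dim(patch)[3] != 3) {
    abort("patch must be an s x s x 3 RGB array")
  }
  s <- dim(patch)[1]
  if (dim(patch)[2] != s || s %% 4 != 0) {
    abort("patch must be square with side a multiple of 4")
  }
  r <- patch[, , 1]; g <- patch[, , 2]; b <- patch[, , 3]
  hsv <- grDevices::rgb2hsv(rbind(as.vector(r), as.vector(g), as.vector(b)),
                            maxColorValue = 1)
  grey <- (r + g + b) / 3
  sat <- matrix(hsv[2, ], s, s)

  hist_bins <- tabulate(pmin(floor(grey * 16) + 1, 16), nbins = 16) / length(grey)
  gx <- grey[, -1, drop = FALSE] - grey[, -s, drop = FALSE]
  gy <- grey[-1, , drop = FALSE] - grey[-s, , drop = FALSE]
  grad <- mean(sqrt(gx[-s, , drop = FALSE]^2 + gy[, -s, drop = FALSE]^2))
  dark_frac <- mean(grey < dark_threshold)

  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0

  unname(c(mean(r), mean(g), mean(b), sd0(r), sd0(g), sd0(b),
           rowMeans(hsv), apply(hsv, 1, sd0),
           hist_bins, grad, dark_frac,
           as.vector(block_mean(grey, s %/% 4L)),
           as.vector(block_mean(sat, s %/% 4L))))
}

#' @rdname toy_descriptor
#' @export
toy_extractor <- function(dark_threshold = 0.35) {
  extractor("toy_colour_texture_v1", 62L,
            function(patch) toy_descriptor(patch, dark_threshold))
}

#' Extract a feature bag from a slide's patch set
#'
#' Applies the extractor to each patch raster independently, preserving the
#' patch order of `patches`, and collects the vectors into a [feature_bag].
#'
#' @param slide a [slide_image].
#' @param patches a `patch_set` from [extract_patch_grid()]; must be
#'   non-empty.
#' @param extractor a `wsi_extractor`; default [toy_extractor()].
#' @return A [feature_bag] with rows aligned to `patches`.
#' @export
extract_features <- function(slide, patches, extractor = toy_extractor()) {
  stopifnot(inherits(extractor, "wsi_extractor"))
  if (nrow(patches) == 0) abort("patch set is empty; nothing to extract")
  ps <- attr(patches, "patch_size_level0") %||% 1024L
  os <- attr(patches, "out_size") %||% 256L
  feats <- purrr::map2(patches$x, patches$y, function(x, y) {
    v <- extractor$fn(read_patch(slide, c(x, y), ps, os))
    if (length(v) != extractor$dim || !all(is.finite(v))) {
      abort(sprintf("extractor '%s' returned %d values (expected %d) or non-finite output",
                    extractor$id, length(v), extractor$dim))
    }
    v
  })
  feature_bag(slide$slide_id %||% patches$slide_id[1],
              do.call(rbind, feats),
              coords = tibble::tibble(x = patches$x, y = patches$y,
                                      patch_size_level0 = ps, out_size = os),
              extractor_id = extractor$id)
}
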