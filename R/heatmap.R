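#' Attention scores on an overlapping patch grid
#'
#' For heatmapping, patches are re-extracted on a grid with 50% overlap
#' (stride = half the level-0 patch size) and the model's attention branch
#' scores the full overlapping patch set of the slide in one pass, so the
#' scores form a valid attention vector (non-negative, summing to 1). With
#' an ensemble, member attention vectors are averaged and renormalised.
#'
#' @param model `abmil_params`, `abmil_model`, or a list of them (ensemble).
#' @param slide a [slide_image].
#' @param mask a `tissue_mask` for the slide.
#' @param extractor the `wsi_extractor` the model was trained with.
#' @param patch_size_level0,out_size patch geometry (as in
#'   [extract_patch_grid()]).
#' @param min_tissue_frac minimum tissue fraction for a patch to be scored.
#' @return tibble with columns `x`, `y`, `score` (one row per scored
#'   patch), carrying the patch geometry as attributes.
#' @export
score_overlapping_patches <- function(model, slide, mask,
                                      extractor = toy_extractor(),
                                      patch_size_level0 = 1024L,
                                      out_size = 256L,
                                      min_tissue_frac = 0.5) {
  patches <- extract_patch_grid(slide, mask,
                                patch_size_level0 = patch_size_level0,
                                out_size = out_size,
                                min_tissue_frac = min_tissue_frac,
                                stride = as.integer(patch_size_level0) %/% 2L)
  if (nrow(patches) == 0) abort("no tissue patches to score")
  bag <- extract_features(slide, patches, extractor)
  att <- if (is.list(model) && !inherits(model, c("abmil_params", "abmil_model"))) {
    a <- rowMeans(vapply(model, function(m) attention_weights(m, bag),
                         numeric(nrow(bag$features))))
    a / sum(a)
  } else {
    attention_weights(model, bag)
  }
  out <- tibble::tibble(x = patches$x, y = patches$y, score = att)
  structure(out, patch_size_level0 = as.integer(patch_size_level0),
            class = c("patch_scores", class(out)))
}

#' Blend overlapping patch scores into an attention raster
#'
#' Each raster pixel (at 1/`downsample` of level 0) takes the arithmetic
#' mean of the scores of all patches covering it; pixels covered by no
#' patch are `NA` (transparent downstream).
#'
#' @param scores tibble from [score_overlapping_patches()] (columns `x`,
#'   `y`, `score`).
#' @param slide_dim slide dimensions `c(H, W, ...)` in level-0 pixels (e.g.
#'   `dim(slide)`).
#' @param patch_size_level0 patch edge in level-0 pixels; defaults to the
#'   attribute carried by `scores`.
#' @param downsample raster downsample factor from level 0.
#' @return numeric matrix `floor(H/downsample) x floor(W/downsample)` with
#'   `NA` outside all patch footprints.
#' @export
blend_scores <- function(scores, slide_dim,
                         patch_size_level0 = attr(scores, "patch_size_level0"),
                         downsample = 16L) {
  if (nrow(scores) < 1) abort("need at least one scored patch")
  ds <- as.integer(downsample)
  nr <- slide_dim[1] %/% ds
  nc <- slide_dim[2] %/% ds
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(scores))) {
    r0 <- scores$y[i] %/% ds + 1L
    r1 <- min((scores$y[i] + patch_size_level0) %/% ds, nr)
    c0 <- scores$x[i] %/% ds + 1L
    c1 <- min((scores$x[i] + patch_size_level0) %/% ds, nc)
    acc[r0:r1, c0:c1] <- acc[r0:r1, c0:c1] + scores$score[i]
    cnt[r0:r1, c0:c1] <- cnt[r0:r1, c0:c1] + 1L
  }
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  out
}

# red-high / blue-low colour ramp (blue -> cyan -> yellow -> red)
attention_ramp <- function(v) {
  ramp <- grDevices::colorRamp(c("#2166AC", "#67D5E8", "#FEE668", "#B2182B"))
  ramp(clamp01(v)) / 255
}

#' Composite an attention raster over a slide thumbnail
#'
#' Scores are first converted to within-slide percentile ranks (raw softmax
#' attention scales like 1/N and is not comparable across slides), mapped
#' through a red-high / blue-low colour gradient, and alpha-composited onto
#' the thumbnail; uncovered pixels keep the plain thumbnail.
#'
#' @param raster attention raster from [blend_scores()] (`NA` = uncovered).
#' @param thumbnail RGB array with the same first two dimensions (e.g. from
#'   [make_thumbnail()] at the same downsample).
#' @param alpha blend weight of the heat colour in \[0, 1\].
#' @return An object of class `heatmap_overlay`: list with `overlay` (RGB
#'   array), `raster` (percentile-normalised, in \[0, 1\]), `alpha`, and
#'   `normalization` (the rank bounds used).
#' @export
render_overlay <- function(raster, thumbnail, alpha = 0.4) {
  if (!all(dim(raster) == dim(thumbnail)[1:2])) {
    abort("raster and thumbnail dimensions differ")
  }
  if (alpha < 0 || alpha > 1) abort("alpha must be in [0, 1]")
  covered <- which(!is.na(raster))
  norm <- raster
  if (length(covered) > 0) {
    v <- raster[covered]
    if (length(unique(v)) == 1) {
      norm[covered] <- 1
    } else {
      norm[covered] <- (rank(v) - 1) / (length(v) - 1)
    }
  }
  overlay <- thumbnail
  if (length(covered) > 0) {
    cols <- attention_ramp(norm[covered])
    for (k in 1:3) {
      ch <- overlay[, , k]
      ch[covered] <- (1 - alpha) * ch[covered] + alpha * cols[, k]
      overlay[, , k] <- ch
    }
  }
  structure(
    list(overlay = clamp01(overlay), raster = norm, alpha = alpha,
         normalization = list(method = "percentile_rank",
                              n_covered = length(covered))),
    class = "heatmap_overlay"
  )
}

#' @export
print.heatmap_overlay <- function(x, ...) {
  cat(sprintf("<heatmap_overlay> %d x %d, alpha = %.2f, %d covered pixels\n",
              ncol(x$raster), nrow(x$raster), x$alpha,
              x$normalization$n_covered))
  invisible(x)
}

#' Write a heatmap overlay to a PNG file
#'
#' @param overlay a `heatmap_overlay`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(overlay, path) {
  png::writePNG(overlay$overlay, path)
  invisible(path)
}

#' End-to-end attention heatmap for one slide
#'
#' Convenience wrapper: segment (or reuse a mask), score overlapping
#' patches, blend, and composite over a thumbnail at the mask downsample.
#'
#' @inheritParams score_overlapping_patches
#' @param mask optional precomputed `tissue_mask`; segmented with defaults
#'   when omitted.
#' @param alpha overlay alpha.
#' @return A `heatmap_overlay`, with the patch scores attached as attribute
#'   `"scores"`.
#' @export
slide_heatmap <- function(model, slide, mask = NULL,
                          extractor = toy_extractor(),
                          patch_size_level0 = 1024L, out_size = 256L,
                          min_tissue_frac = 0.5, alpha = 0.4) {
  mask <- mask %||% segment_tissue(slide)
  scores <- score_overlapping_patches(model, slide, mask,
                                      extractor = extractor,
                                      patch_size_level0 = patch_size_level0,
                                      out_size = out_size,
                                      min_tissue_frac = min_tissue_frac)
  raster <- blend_scores(scores, dim(slide), downsample = mask$downsample)
  thumb <- make_thumbnail(slide, mask$downsample)
  ov <- render_overlay(raster, thumb, alpha = alpha)
  attr(ov, "scores") <- scores
  ov
}
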