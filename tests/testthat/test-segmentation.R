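test_that("saturation extremes give empty and full tissue masks", {
  white <- flat_slide(c(1, 1, 1))
  expect_equal(segment_tissue(white)$tissue_fraction, 0)
  magenta <- flat_slide(c(1, 0, 1))
  expect_equal(segment_tissue(magenta)$tissue_fraction, 1)
})

test_that("segmentation recovers the generator's tissue mask", {
  g <- small_positive_slide()
  mk <- segment_tissue(g$slide)
  gt <- wsimil:::block_mean(g$tissue_mask * 1, mk$downsample) > 0.5
  jaccard <- sum(mk$mask & gt) / sum(mk$mask | gt)
  expect_gte(jaccard, 0.90)
})

test_that("non-RGB input is rejected", {
  expect_error(segment_tissue(matrix(1, 10, 10)), "RGB")
})

test_that("raising the saturation threshold never grows the mask", {
  g <- small_negative_slide()
  fr <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.5),
               function(th) segment_tissue(g$slide, sat_threshold = th)$tissue_fraction,
               numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("the non-overlapping grid matches exhaustive enumeration", {
  magenta <- flat_slide(c(1, 0, 1), size = 1024L)
  mk <- segment_tissue(magenta)
  ps <- extract_patch_grid(magenta, mk, patch_size_level0 = 256L,
                           out_size = 64L, min_tissue_frac = 0.5)
  # brute-force oracle: all grid-aligned boxes fully inside a 1024 px slide
  oracle <- expand.grid(x = seq(0L, 1024L - 256L, by = 256L),
                        y = seq(0L, 1024L - 256L, by = 256L))
  expect_equal(nrow(ps), nrow(oracle))       # floor(1024/256)^2 = 16
  expect_setequal(paste(ps$x, ps$y), paste(oracle$x, oracle$y))
  expect_true(all(ps$x %% 256L == 0 & ps$y %% 256L == 0))
})

test_that("partial edge boxes are discarded, never padded", {
  s <- slide_image(array(rep(c(1, 0, 1), each = 900 * 1024),
                         c(900, 1024, 3)))  # 900 x 1024 slide
  ps <- extract_patch_grid(s, segment_tissue(s), patch_size_level0 = 256L,
                           out_size = 64L)
  expect_equal(nrow(ps), floor(900 / 256) * floor(1024 / 256))
  expect_true(all(ps$x + 256L <= 1024L & ps$y + 256L <= 900L))
})

test_that("an empty mask yields no patches and patch counts obey the bounds", {
  white <- flat_slide(c(1, 1, 1))
  ps <- extract_patch_grid(white, segment_tissue(white))
  expect_equal(nrow(ps), 0)

  g <- small_positive_slide()
  mk <- segment_tissue(g$slide)
  counts <- vapply(c(0.1, 0.3, 0.5, 0.8),
                   function(f) nrow(extract_patch_grid(g$slide, mk,
                                                       patch_size_level0 = 256L,
                                                       out_size = 64L,
                                                       min_tissue_frac = f)),
                   numeric(1))
  # raising min_tissue_frac never increases the patch count
  expect_true(all(diff(counts) <= 0))
  # coverage bound
  expect_lte(counts[1], floor(1024 / 256)^2)
})

test_that("retained coordinates satisfy the tissue-fraction rule on recheck", {
  g <- small_positive_slide()
  mk <- segment_tissue(g$slide)
  ps <- extract_patch_grid(g$slide, mk, patch_size_level0 = 256L,
                           out_size = 64L, min_tissue_frac = 0.5)
  recheck <- vapply(seq_len(nrow(ps)), function(i) {
    wsimil:::box_tissue_fraction(mk$mask, mk$downsample, ps$x[i], ps$y[i], 256L)
  }, numeric(1))
  expect_true(all(recheck >= 0.5))
})

test_that("patch reading performs exact block-mean downsampling", {
  # 4 x 4 image with known values; factor-2 reduction is hand-computable
  vals <- matrix(c(0, 1, 0.5, 0.25,
                   1, 0, 0.5, 0.75,
                   0.2, 0.4, 0.6, 0.8,
                   0.8, 0.6, 0.4, 0.2), 4, 4, byrow = TRUE)
  img <- array(rep(vals, 3), c(4, 4, 3))
  s <- slide_image(img)
  p <- read_patch(s, c(0, 0), patch_size_level0 = 4L, out_size = 2L)
  oracle <- matrix(c(mean(vals[1:2, 1:2]), mean(vals[3:4, 1:2]),
                     mean(vals[1:2, 3:4]), mean(vals[3:4, 3:4])), 2, 2)
  expect_equal(p[, , 1], oracle)
  expect_equal(p[, , 2], oracle)

  # constant region -> constant patch; re-read is identical
  flat <- flat_slide(c(0.3, 0.6, 0.9), size = 1024L)
  p1 <- read_patch(flat, c(256, 512), 256L, 64L)
  expect_true(all(p1[, , 1] == 0.3) && all(p1[, , 3] == 0.9))
  expect_identical(p1, read_patch(flat, c(256, 512), 256L, 64L))
})

test_that("out-of-bounds reads and bad geometry are errors", {
  flat <- flat_slide(c(1, 0, 0), size = 1024L)
  expect_error(read_patch(flat, c(512, 512), patch_size_level0 = 1024L),
               "out of slide bounds")
  expect_error(read_patch(flat, c(0, 0), patch_size_level0 = 100L,
                          out_size = 33L), "multiple")
  expect_error(extract_patch_grid(flat, segment_tissue(flat),
                                  patch_size_level0 = 100L, out_size = 33L),
               "multiple")
})
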