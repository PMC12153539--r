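#' Specification for one synthetic mini-slide
#'
#' Describes a synthetic H&E-like slide: a near-white, low-saturation
#' background carrying a few high-saturation eosin-pink tissue blobs, with
#' optional tumour foci rendered inside the tissue as hue-shifted stroma
#' scattered with dark nuclei-like dots. The construction guarantees a
#' saturation gap between background and tissue, so saturation-threshold
#' segmentation can be validated against the generator's own masks, and it
#' guarantees that tumour foci carry a colour/texture signal a simple patch
#' descriptor can learn.
#'
#' All geometry is expressed through `mpp` (microns per pixel at level 0);
#' the defaults use 1 um/px so that a 100 um focus — the size of the
#' inconspicuous deposits that are hardest to detect — is a 100 px disc.
#'
#' @param canvas_size_px integer pair `c(width, height)` in level-0 pixels;
#'   each dimension must be at least 1024 (one full patch).
#' @param mpp microns per pixel at level 0.
#' @param n_tissue_blobs number of elliptical tissue blobs.
#' @param tumour_present logical; metastatic slide?
#' @param tumour_focus_diameters_um diameters (um) of the tumour foci; only
#'   used when `tumour_present` is `TRUE`.
#' @param tissue_hue_range,tumour_hue_range hue intervals in \[0, 1).
#' @param background_saturation_max upper bound on background saturation.
#' @param seed integer seed; the slide is a pure function of this spec.
#' @return An object of class `slide_spec`.
#' @export
slide_spec <- function(canvas_size_px = c(2048L, 2048L),
                       mpp = 1.0,
                       n_tissue_blobs = 3L,
                       tumour_present = FALSE,
                       tumour_focus_diameters_um =
                         if (tumour_present) c(500, 200, 100) else numeric(0),
                       tissue_hue_range = c(0.90, 0.97),
                       tumour_hue_range = c(0.78, 0.88),
                       background_saturation_max = 0.05,
                       seed = 1L) {
  canvas_size_px <- as.integer(canvas_size_px)
  if (length(canvas_size_px) != 2 || any(canvas_size_px < 1024L)) {
    abort("canvas_size_px must be a pair with each dimension >= 1024")
  }
  if (mpp <= 0) abort("mpp must be positive")
  if (n_tissue_blobs < 1) abort("need at least one tissue blob")
  if (!tumour_present && length(tumour_focus_diameters_um) > 0) {
    abort("tumour_focus_diameters_um given but tumour_present is FALSE")
  }
  if (tumour_present && length(tumour_focus_diameters_um) == 0) {
    abort("tumour_present slide needs at least one focus diameter")
  }
  if (any(tumour_focus_diameters_um <= 0)) abort("focus diameters must be positive")
  structure(
    list(canvas_size_px = canvas_size_px, mpp = mpp,
         n_tissue_blobs = as.integer(n_tissue_blobs),
         tumour_present = isTRUE(tumour_present),
         tumour_focus_diameters_um = tumour_focus_diameters_um,
         tissue_hue_range = tissue_hue_range,
         tumour_hue_range = tumour_hue_range,
         background_saturation_max = background_saturation_max,
         seed = as.integer(seed)),
    class = "slide_spec"
  )
}

# ellipse membership for a full coordinate grid
ellipse_mask <- function(W, H, cx, cy, a, b, theta) {
  x <- matrix(rep(seq_len(W), each = H), H, W) - cx
  y <- matrix(rep(seq_len(H), W), H, W) - cy
  u <- cos(theta) * x + sin(theta) * y
  v <- -sin(theta) * x + cos(theta) * y
  (u / a)^2 + (v / b)^2 <= 1
}

# local bounding-box evaluation of a disc: rows/cols indices + local mask
disc_window <- function(W, H, cx, cy, r) {
  rows <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  dx <- matrix(rep(cols - cx, each = length(rows)), length(rows))
  dy <- matrix(rep(rows - cy, length(cols)), length(rows))
  list(rows = rows, cols = cols, mask = dx^2 + dy^2 <= r^2)
}

# paint an HSV-sampled region into channel matrices held in `env`
# (env$R, env$G, env$B); local indices keep the big arrays untouched
paint_into <- function(env, mask, hue_range, sat_range, val_range) {
  n <- sum(mask)
  if (n == 0) return(invisible(NULL))
  col <- hsv_to_rgb_vec(runif(n, hue_range[1], hue_range[2]),
                        runif(n, sat_range[1], sat_range[2]),
                        runif(n, val_range[1], val_range[2]))
  env$R[mask] <- col$r
  env$G[mask] <- col$g
  env$B[mask] <- col$b
  invisible(NULL)
}


#' Generate one synthetic slide with ground-truth masks
#'
#' Renders the slide described by a [slide_spec()] and returns it with its
#' ground-truth tissue and tumour masks (logical rasters aligned to the
#' slide at level 0). Deterministic: the same spec always yields
#' bit-identical output.
#'
#' @param spec a [slide_spec()].
#' @param slide_id optional identifier stored on the slide.
#' @return A list with elements `slide` ([slide_image]), `tumour_mask` and
#'   `tissue_mask` (logical `H x W` matrices).
#' @export
generate_slide <- function(spec, slide_id = NULL) {
  stopifnot(inherits(spec, "slide_spec"))
  withr::with_seed(spec$seed, {
    W <- spec$canvas_size_px[1]; H <- spec$canvas_size_px[2]

    # near-white background; channel jitter kept well under the saturation cap
    base <- 0.965 + matrix(runif(H * W, -0.012, 0.012), H, W)
    env <- new.env(parent = emptyenv())
    env$R <- clamp01(base + runif(H * W, -0.004, 0.004))
    env$G <- clamp01(base + runif(H * W, -0.004, 0.004))
    env$B <- clamp01(base + runif(H * W, -0.004, 0.004))

    # tissue: overlapping ellipses, eosin-pink (high saturation)
    mn <- min(W, H)
    blobs <- lapply(seq_len(spec$n_tissue_blobs), function(i) {
      list(cx = runif(1, 0.35 * W, 0.65 * W),
           cy = runif(1, 0.35 * H, 0.65 * H),
           a = runif(1, 0.26 * mn, 0.40 * mn),
           b = runif(1, 0.26 * mn, 0.40 * mn),
           theta = runif(1, 0, pi))
    })
    tissue_mask <- matrix(FALSE, H, W)
    for (bl in blobs) {
      tissue_mask <- tissue_mask | ellipse_mask(W, H, bl$cx, bl$cy, bl$a, bl$b, bl$theta)
    }
    paint_into(env, tissue_mask, spec$tissue_hue_range,
               c(0.25, 0.45), c(0.85, 0.95))

    # tumour foci: hue-shifted stroma + Poisson-scattered dark nuclei dots,
    # rendered into a local window so the big channel matrices are written once
    tumour_mask <- matrix(FALSE, H, W)
    if (spec$tumour_present) {
      for (d_um in spec$tumour_focus_diameters_um) {
        r <- d_um / (2 * spec$mpp)
        fits <- vapply(blobs, function(bl) min(bl$a, bl$b) > r + 2, logical(1))
        if (!any(fits)) {
          abort(sprintf(
            "tumour focus of %g um (radius %.0f px) does not fit inside any tissue blob",
            d_um, r))
        }
        bl <- blobs[[sample_one(which(fits))]]
        # uniform point in the ellipse shrunk by r: keeps the disc inside tissue
        ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1))
        ux <- rad * (bl$a - r - 2) * cos(ang); vy <- rad * (bl$b - r - 2) * sin(ang)
        cx <- bl$cx + cos(bl$theta) * ux - sin(bl$theta) * vy
        cy <- bl$cy + sin(bl$theta) * ux + cos(bl$theta) * vy

        fw <- disc_window(W, H, cx, cy, r)
        loc <- new.env(parent = emptyenv())
        loc$R <- env$R[fw$rows, fw$cols]
        loc$G <- env$G[fw$rows, fw$cols]
        loc$B <- env$B[fw$rows, fw$cols]
        paint_into(loc, fw$mask, spec$tumour_hue_range,
                   c(0.30, 0.50), c(0.75, 0.88))
        ox <- fw$cols[1] - 1L; oy <- fw$rows[1] - 1L
        n_dots <- rpois(1, max(3, 0.002 * pi * r^2))
        for (j in seq_len(n_dots)) {
          dr <- runif(1, 4, 7)
          if (r <= dr + 1) dr <- max(1, r - 1)
          da <- runif(1, 0, 2 * pi); dd <- sqrt(runif(1)) * (r - dr)
          dw <- disc_window(ncol(loc$R), nrow(loc$R),
                            cx + dd * cos(da) - ox, cy + dd * sin(da) - oy, dr)
          dmask <- matrix(FALSE, nrow(loc$R), ncol(loc$R))
          dmask[dw$rows, dw$cols] <- dw$mask
          paint_into(loc, dmask, spec$tumour_hue_range,
                     c(0.45, 0.65), c(0.15, 0.30))
        }
        env$R[fw$rows, fw$cols] <- loc$R
        env$G[fw$rows, fw$cols] <- loc$G
        env$B[fw$rows, fw$cols] <- loc$B
        tumour_mask[fw$rows, fw$cols] <- tumour_mask[fw$rows, fw$cols] | fw$mask
      }
    }

    img <- array(c(env$R, env$G, env$B), c(H, W, 3))
    list(
      slide = slide_image(img, mpp = spec$mpp, slide_id = slide_id,
                          label = if (spec$tumour_present) "metastatic" else "benign"),
      tumour_mask = tumour_mask,
      tissue_mask = tissue_mask
    )
  })
}

#' Generate a synthetic cohort of slides with a manifest
#'
#' Writes `n_benign + n_malignant` synthetic slides (PNG) plus their
#' ground-truth tumour and tissue masks, and returns the slide manifest.
#' Slides are grouped into synthetic cases (patients): case sizes are drawn
#' uniformly from `slides_per_case`, so case-level splitting is genuinely
#' exercised downstream. All slides of a case share its label.
#'
#' @param n_benign,n_malignant number of slides per label (each >= 1).
#' @param cohort cohort name, e.g. `"omentum"` or `"lymph_node"`.
#' @param seed master seed; every slide gets an independent derived seed.
#' @param out_dir output directory (created if needed).
#' @param slides_per_case integer pair `c(min, max)` slides per case.
#' @param canvas_size_px,mpp forwarded to [slide_spec()].
#' @param focus_diameter_range_um range (um) from which per-focus diameters
#'   of malignant slides are drawn (1-3 foci per slide, sizes spanning
#'   conspicuous deposits down to ~100 um).
#' @param prefix string prefixed to slide/case ids (handy to keep two
#'   cohorts' case ids disjoint).
#' @return The manifest as a tibble with columns `slide_id`, `case_id`,
#'   `cohort`, `label`, `mpp`, `path`, `tumour_mask_path`,
#'   `tissue_mask_path`; also written to `out_dir/manifest.csv`.
#' @export
generate_cohort <- function(n_benign, n_malignant, cohort = "omentum",
                            seed = 1L, out_dir = tempfile("cohort_"),
                            slides_per_case = c(1L, 3L),
                            canvas_size_px = c(2048L, 2048L), mpp = 1.0,
                            focus_diameter_range_um = c(100, 500),
                            prefix = "") {
  if (n_benign < 1 || n_malignant < 1) {
    abort("n_benign and n_malignant must both be >= 1")
  }
  dir.create(file.path(out_dir, "slides"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create output dir: %s", out_dir))

  n_total <- n_benign + n_malignant
  plan <- withr::with_seed(as.integer(seed), {
    assign_cases <- function(n, label) {
      sizes <- integer(0)
      while (sum(sizes) < n) {
        sizes <- c(sizes, sample_one(seq(slides_per_case[1], slides_per_case[2])))
      }
      cs <- rep(seq_along(sizes), sizes)[seq_len(n)]
      tibble::tibble(label = label, case_num = cs)
    }
    pl <- dplyr::bind_rows(assign_cases(n_benign, "benign"),
                           assign_cases(n_malignant, "metastatic"))
    pl$n_foci <- ifelse(pl$label == "metastatic", sample(1:3, n_total, replace = TRUE), 0L)
    pl$foci <- lapply(pl$n_foci, function(k) {
      if (k == 0) numeric(0)
      else round(runif(k, focus_diameter_range_um[1], focus_diameter_range_um[2]))
    })
    pl$slide_seed <- sample.int(.Machine$integer.max - 1L, n_total)
    pl
  })

  rows <- purrr::pmap(
    list(plan$label, plan$case_num, plan$foci, plan$slide_seed, seq_len(n_total)),
    function(label, case_num, foci, sseed, i) {
      slide_id <- sprintf("%s%s_s%03d", prefix, cohort, i)
      case_id <- sprintf("%s%s_%s_case%03d", prefix, cohort,
                         substr(label, 1, 3), case_num)
      sp <- slide_spec(canvas_size_px = canvas_size_px, mpp = mpp,
                       tumour_present = label == "metastatic",
                       tumour_focus_diameters_um = foci, seed = sseed)
      g <- generate_slide(sp, slide_id = slide_id)
      path <- file.path(out_dir, "slides", paste0(slide_id, ".png"))
      tum_path <- file.path(out_dir, "masks", paste0(slide_id, "_tumour.png"))
      tis_path <- file.path(out_dir, "masks", paste0(slide_id, "_tissue.png"))
      write_slide(g$slide, path)
      png::writePNG(g$tumour_mask * 1.0, tum_path)
      png::writePNG(g$tissue_mask * 1.0, tis_path)
      tibble::tibble(slide_id = slide_id, case_id = case_id, cohort = cohort,
                     label = label, mpp = mpp, path = path,
                     tumour_mask_path = tum_path, tissue_mask_path = tis_path)
    })
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Read a 0/255 mask PNG back as a logical matrix
#'
#' @param path single-channel PNG path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}
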