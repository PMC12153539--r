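#' Reproducible pipeline configuration
#'
#' Bundles every tunable of the end-to-end pipeline in one object so a run
#' is fully described by (config, seed). The config is serialised verbatim
#' (JSON) into each run's output directory, and every random operation in a
#' run draws its seed from the single `seed` field.
#'
#' @param sat_threshold,min_region_area_px,closing_radius_px,mask_downsample
#'   segmentation parameters (see [segment_tissue()]).
#' @param patch_size_level0,out_size,min_tissue_frac patch grid parameters.
#' @param extractor_id identifier of the feature extractor (only the
#'   shipped `"toy_colour_texture_v1"` is constructible here; external
#'   encoders are plugged in programmatically).
#' @param train a [train_config()].
#' @param k number of cross-validation folds.
#' @param n_bootstrap bootstrap iterations for metric CIs.
#' @param heatmap_alpha overlay alpha.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sat_threshold = 8 / 255, min_region_area_px = 16L,
                            closing_radius_px = 2L, mask_downsample = 16L,
                            patch_size_level0 = 1024L, out_size = 256L,
                            min_tissue_frac = 0.5,
                            extractor_id = "toy_colour_texture_v1",
                            train = train_config(), k = 5L,
                            n_bootstrap = 10000L, heatmap_alpha = 0.4,
                            seed = 1L) {
  structure(
    list(sat_threshold = sat_threshold,
         min_region_area_px = as.integer(min_region_area_px),
         closing_radius_px = as.integer(closing_radius_px),
         mask_downsample = as.integer(mask_downsample),
         patch_size_level0 = as.integer(patch_size_level0),
         out_size = as.integer(out_size),
         min_tissue_frac = min_tissue_frac,
         extractor_id = extractor_id, train = unclass(train),
         k = as.integer(k), n_bootstrap = as.integer(n_bootstrap),
         heatmap_alpha = heatmap_alpha, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

config_extractor <- function(config) {
  if (config$extractor_id != "toy_colour_texture_v1") {
    abort(sprintf("unknown extractor_id '%s'; construct the extractor and call the stage functions directly",
                  config$extractor_id))
  }
  toy_extractor()
}

#' Compute feature bags for every slide in a manifest
#'
#' Segments each slide, extracts its non-overlapping tissue patch grid, and
#' runs the extractor, returning one [feature_bag] per slide keyed by
#' `slide_id`. A classified slide must contribute at least one instance: if
#' no grid box reaches `min_tissue_frac`, the single box with the highest
#' tissue fraction is retained instead, and a slide with no tissue at all
#' is an error.
#'
#' @param manifest slide manifest with a `path` column.
#' @param config a [pipeline_config()].
#' @return named list of [feature_bag]s.
#' @export
featurize_manifest <- function(manifest, config = pipeline_config()) {
  extractor <- config_extractor(config)
  bags <- purrr::map(seq_len(nrow(manifest)), function(i) {
    slide <- read_slide(manifest$path[i], mpp = manifest$mpp[i],
                        slide_id = manifest$slide_id[i],
                        label = manifest$label[i])
    mask <- segment_tissue(slide, sat_threshold = config$sat_threshold,
                           min_region_area_px = config$min_region_area_px,
                           closing_radius_px = config$closing_radius_px,
                           downsample = config$mask_downsample)
    patches <- extract_patch_grid(slide, mask,
                                  patch_size_level0 = config$patch_size_level0,
                                  out_size = config$out_size,
                                  min_tissue_frac = config$min_tissue_frac)
    if (nrow(patches) == 0) {
      # every bag needs >= 1 instance: fall back to the best-tissue box
      all_boxes <- extract_patch_grid(slide, mask,
                                      patch_size_level0 = config$patch_size_level0,
                                      out_size = config$out_size,
                                      min_tissue_frac = 0)
      all_boxes <- all_boxes[all_boxes$tissue_frac > 0, ]
      if (nrow(all_boxes) == 0) {
        abort(sprintf("slide %s contains no tissue", manifest$slide_id[i]))
      }
      patches <- structure(all_boxes[which.max(all_boxes$tissue_frac), ],
                           patch_size_level0 = config$patch_size_level0,
                           out_size = config$out_size)
    }
    extract_features(slide, patches, extractor)
  })
  names(bags) <- manifest$slide_id
  bags
}

#' One-command synthetic demonstration of the full pipeline
#'
#' Generates a small synthetic omentum-like cohort plus a disjoint hold-out
#' cohort, runs segmentation, patching, feature extraction, case-level
#' stratified k-fold cross-validation, ensembled hold-out testing, and
#' renders an attention heatmap for one metastatic hold-out slide. All
#' artifacts (config, manifests, fold assignment, predictions, metric
#' reports, heatmap PNG) are written under `out_dir`; reruns with the same
#' seed reproduce them byte for byte.
#'
#' @param out_dir output directory.
#' @param seed master seed for the whole run.
#' @param n_train number of training slides per class.
#' @param n_holdout number of hold-out slides per class (one slide per
#'   case, mirroring a hold-out set of one WSI per patient).
#' @param config a [pipeline_config()]; the demo default scales training
#'   epochs down to match the tiny cohort.
#' @return list with `train_manifest`, `holdout_manifest`, `cv`
#'   (`wsimil_cv`), `holdout` (`wsimil_holdout`), `heatmap`
#'   (`heatmap_overlay` or `NULL`), `paths`.
#' @export
run_demo <- function(out_dir = tempfile("wsimil_demo_"), seed = 1L,
                     n_train = 16L, n_holdout = 4L,
                     config = pipeline_config(
                       train = train_config(max_epochs = 60L, min_epochs = 20L,
                                            patience = 10L),
                       n_bootstrap = 10000L)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config$seed <- as.integer(seed)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  train_manifest <- generate_cohort(
    n_train, n_train, cohort = "omentum", seed = seed,
    out_dir = file.path(out_dir, "train"), prefix = "tr_")
  holdout_manifest <- generate_cohort(
    n_holdout, n_holdout, cohort = "omentum", seed = seed + 1L,
    out_dir = file.path(out_dir, "holdout"), slides_per_case = c(1L, 1L),
    prefix = "ho_")

  bags <- featurize_manifest(dplyr::bind_rows(train_manifest, holdout_manifest),
                             config)

  tc <- do.call(train_config, config$train[setdiff(names(config$train), "seed")])
  tc$seed <- config$seed
  cv <- run_cross_validation(train_manifest, bags, config = tc, k = config$k,
                             n_bootstrap = config$n_bootstrap,
                             seed = config$seed)
  ho <- run_holdout(cv, holdout_manifest, bags,
                    n_bootstrap = config$n_bootstrap, seed = config$seed)

  # heatmap for the first metastatic hold-out slide
  hm <- NULL
  met <- which(holdout_manifest$label == "metastatic")
  if (length(met) > 0) {
    i <- met[1]
    slide <- read_slide(holdout_manifest$path[i],
                        mpp = holdout_manifest$mpp[i],
                        slide_id = holdout_manifest$slide_id[i])
    hm <- slide_heatmap(cv$models, slide, extractor = config_extractor(config),
                        patch_size_level0 = config$patch_size_level0,
                        out_size = config$out_size,
                        min_tissue_frac = config$min_tissue_frac,
                        alpha = config$heatmap_alpha)
    write_overlay(hm, file.path(out_dir, "heatmap.png"))
  }

  utils::write.csv(cv$folds, file.path(out_dir, "folds.csv"), row.names = FALSE)
  utils::write.csv(cv$predictions, file.path(out_dir, "cv_predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(ho$predictions, file.path(out_dir, "holdout_predictions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(cross_validation = c(list(counts = cv$report$counts),
                              list(summary = cv$report$summary)),
         holdout = c(list(counts = ho$report$counts),
                     list(summary = ho$report$summary))),
    file.path(out_dir, "metrics.json"), digits = NA, pretty = TRUE)

  list(train_manifest = train_manifest, holdout_manifest = holdout_manifest,
       cv = cv, holdout = ho, heatmap = hm,
       paths = list(
         out_dir = out_dir,
         metrics = file.path(out_dir, "metrics.json"),
         cv_predictions = file.path(out_dir, "cv_predictions.csv"),
         holdout_predictions = file.path(out_dir, "holdout_predictions.csv"),
         heatmap = if (!is.null(hm)) file.path(out_dir, "heatmap.png") else NULL))
}
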