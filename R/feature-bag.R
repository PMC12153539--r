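#' Feature bag: the MIL instance container for one slide
#'
#' A bag holds one `N x D` matrix of per-patch feature vectors for a single
#' slide, with an aligned table of level-0 patch coordinates (row `i` of
#' `features` describes the patch at `coords[i, ]`). Bags simulated directly
#' in feature space (see [generate_feature_bags()]) may omit coordinates.
#'
#' @param slide_id slide identifier.
#' @param features numeric `N x D` matrix, all finite, `N >= 1`.
#' @param coords optional tibble/data.frame with columns `x`, `y` (level-0
#'   top-left corners) and one row per feature row.
#' @param extractor_id identifier of the extractor that produced the rows.
#' @param witness_idx optional integer indices of ground-truth witness
#'   (tumour-bearing) instances; used by the synthetic generator.
#' @return An object of class `feature_bag`.
#' @export
feature_bag <- function(slide_id, features, coords = NULL,
                        extractor_id = "unknown", witness_idx = NULL) {
  features <- as.matrix(features)
  if (nrow(features) < 1) abort("a feature bag must contain at least one instance")
  if (!all(is.finite(features))) abort("feature bag contains non-finite values")
  if (!is.null(coords)) {
    coords <- tibble::as_tibble(coords)
    if (!all(c("x", "y") %in% names(coords))) abort("coords needs columns x and y")
    if (nrow(coords) != nrow(features)) {
      abort("coords must have one row per feature row")
    }
  }
  if (!is.null(witness_idx)) {
    witness_idx <- as.integer(witness_idx)
    if (length(witness_idx) > 0 &&
        (min(witness_idx) < 1 || max(witness_idx) > nrow(features))) {
      abort("witness_idx out of range")
    }
  }
  structure(
    list(slide_id = slide_id, features = features, coords = coords,
         extractor_id = extractor_id, feature_dim = ncol(features),
         witness_idx = witness_idx),
    class = "feature_bag"
  )
}

#' @export
print.feature_bag <- function(x, ...) {
  cat(sprintf("<feature_bag> %s  %d instances x %d dims  extractor: %s\n",
              x$slide_id %||% "(unnamed)", nrow(x$features), x$feature_dim,
              x$extractor_id))
  invisible(x)
}

#' @export
dim.feature_bag <- function(x) dim(x$features)

#' Save / load a feature bag as a JSON container
#'
#' The bag (features, coordinates, extractor identity) round-trips
#' losslessly through a single plain-text JSON file.
#'
#' @param bag a [feature_bag].
#' @param path output `.json` path.
#' @return `path` invisibly for `save_bag`; a [feature_bag] for `load_bag`.
#' @export
save_bag <- function(bag, path) {
  stopifnot(inherits(bag, "feature_bag"))
  payload <- list(
    slide_id = bag$slide_id,
    extractor_id = bag$extractor_id,
    feature_dim = bag$feature_dim,
    n_instances = nrow(bag$features),
    features = bag$features,
    coords = bag$coords,
    witness_idx = bag$witness_idx
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname save_bag
#' @param expected_dim if given, loading errors unless the stored feature
#'   dimension matches (guards a model against bags from another extractor).
#' @export
load_bag <- function(path, expected_dim = NULL) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- matrix(as.numeric(p$features), nrow = p$n_instances,
                  ncol = p$feature_dim, byrow = FALSE)
  # jsonlite simplifies row-major written matrices back to a matrix already
  if (is.matrix(p$features)) feats <- p$features
  if (!is.null(expected_dim) && ncol(feats) != expected_dim) {
    abort(sprintf("bag feature dimension %d does not match expected %d",
                  ncol(feats), expected_dim))
  }
  coords <- if (!is.null(p$coords) && length(p$coords) > 0) {
    tibble::as_tibble(p$coords)
  } else NULL
  wit <- if (!is.null(p$witness_idx) && length(p$witness_idx) > 0) {
    as.integer(p$witness_idx)
  } else NULL
  feature_bag(p$slide_id, feats, coords = coords,
              extractor_id = p$extractor_id, witness_idx = wit)
}
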