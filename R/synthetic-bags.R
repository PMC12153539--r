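#' Specification for simulated MIL feature bags
#'
#' Describes a feature-space simulation of the weakly supervised MIL setting:
#' background instances are standard multivariate normal draws; witness
#' instances (the tumour-bearing patches of a positive slide) come from the
#' same distribution with every coordinate's mean shifted by `effect_size`
#' standard deviations. Negative bags contain no witnesses; positive bags
#' contain at least one, with the witness indices recorded as ground truth so
#' attention recovery can be measured.
#'
#' @param n_bags_per_class bags per class.
#' @param bag_size integer pair `c(min, max)`; sizes drawn uniformly.
#' @param feature_dim instance feature dimension.
#' @param effect_size mean shift of witness instances, in units of the
#'   per-dimension standard deviation.
#' @param witness_count fixed number of witnesses per positive bag
#'   (mutually exclusive with `witness_rate`).
#' @param witness_rate per-instance witness probability in (0, 1\]; bags are
#'   redrawn until at least one witness is present.
#' @param seed integer seed.
#' @return An object of class `bag_sim_spec`.
#' @export
bag_sim_spec <- function(n_bags_per_class = 50L, bag_size = c(20L, 50L),
                         feature_dim = 32L, effect_size = 2,
                         witness_count = 3L, witness_rate = NULL,
                         seed = 1L) {
  if (n_bags_per_class < 1) abort("n_bags_per_class must be >= 1")
  bag_size <- as.integer(bag_size)
  if (length(bag_size) != 2 || bag_size[1] < 1 || bag_size[2] < bag_size[1]) {
    abort("bag_size must be c(min, max) with 1 <= min <= max")
  }
  if (!is.null(witness_rate)) {
    if (witness_rate <= 0 || witness_rate > 1) abort("witness_rate must be in (0, 1]")
    witness_count <- NULL
  } else {
    witness_count <- as.integer(witness_count)
    if (witness_count < 1) abort("witness_count must be >= 1")
    if (witness_count > bag_size[1]) {
      abort("witness_count exceeds the minimum bag size")
    }
  }
  structure(
    list(n_bags_per_class = as.integer(n_bags_per_class), bag_size = bag_size,
         feature_dim = as.integer(feature_dim), effect_size = effect_size,
         witness_count = witness_count, witness_rate = witness_rate,
         seed = as.integer(seed)),
    class = "bag_sim_spec"
  )
}

#' Generate synthetic feature bags with known witnesses
#'
#' @param spec a [bag_sim_spec()].
#' @return A list with `bags` (list of [feature_bag], witness indices
#'   recorded on positive bags), `labels` (character, aligned), and `spec`.
#' @export
generate_feature_bags <- function(spec) {
  stopifnot(inherits(spec, "bag_sim_spec"))
  withr::with_seed(spec$seed, {
    D <- spec$feature_dim
    make_bag <- function(id, positive) {
      n <- sample_one(seq(spec$bag_size[1], spec$bag_size[2]))
      X <- matrix(rnorm(n * D), n, D)
      wit <- integer(0)
      if (positive) {
        k <- if (!is.null(spec$witness_count)) {
          spec$witness_count
        } else {
          kk <- 0L
          while (kk == 0L) kk <- stats::rbinom(1, n, spec$witness_rate)
          kk
        }
        if (k > n) abort("witness count exceeds bag size")
        wit <- sort(sample.int(n, k))
        X[wit, ] <- X[wit, ] + spec$effect_size
      }
      feature_bag(id, X, extractor_id = "simulated", witness_idx = wit)
    }
    n_per <- spec$n_bags_per_class
    labels <- rep(c("benign", "metastatic"), each = n_per)
    # seed embedded in the id so bags from different draws never collide
    ids <- sprintf("bag%d_%s_%03d", spec$seed, substr(labels, 1, 3),
                   c(seq_len(n_per), seq_len(n_per)))
    bags <- purrr::map2(ids, labels == "metastatic", make_bag)
    names(bags) <- ids
    list(bags = bags, labels = labels, spec = spec)
  })
}
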