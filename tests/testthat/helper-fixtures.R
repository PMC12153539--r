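# shared fixtures, built once per test run and cached
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small positive slide (1024 px canvas, one 100 um and one 250 um focus)
small_positive_slide <- function() {
  fixture("small_positive", function() {
    generate_slide(slide_spec(canvas_size_px = c(1024, 1024),
                              tumour_present = TRUE,
                              tumour_focus_diameters_um = c(250, 100),
                              seed = 301), slide_id = "pos1")
  })
}

small_negative_slide <- function() {
  fixture("small_negative", function() {
    generate_slide(slide_spec(canvas_size_px = c(1024, 1024), seed = 302),
                   slide_id = "neg1")
  })
}

# fast training configuration for unit tests (full-size runs live in the
# acceptance suite)
quick_config <- function(seed = 1L) {
  train_config(max_epochs = 30L, min_epochs = 10L, patience = 8L, seed = seed)
}

# small simulated bag cohort for model/cv unit tests
small_sim <- function() {
  fixture("small_sim", function() {
    list(tr = generate_feature_bags(bag_sim_spec(n_bags_per_class = 15L,
                                                 bag_size = c(10L, 20L),
                                                 feature_dim = 16L, seed = 401)),
         va = generate_feature_bags(bag_sim_spec(n_bags_per_class = 6L,
                                                 bag_size = c(10L, 20L),
                                                 feature_dim = 16L, seed = 402)),
         te = generate_feature_bags(bag_sim_spec(n_bags_per_class = 6L,
                                                 bag_size = c(10L, 20L),
                                                 feature_dim = 16L, seed = 403)))
  })
}

# manifest pairing simulated bags into 2-slide cases, for split/cv tests
sim_manifest <- function(sim_part, prefix = "") {
  labels <- sim_part$labels
  n <- length(labels)
  case_of <- character(n)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    case_of[idx] <- paste0(prefix, substr(cl, 1, 3), "_case",
                           (seq_along(idx) + 1) %/% 2)
  }
  tibble::tibble(slide_id = names(sim_part$bags), case_id = case_of,
                 cohort = "sim", label = labels, mpp = 1,
                 path = NA_character_)
}

# uniform-colour slide helper
flat_slide <- function(rgb, size = 1024L) {
  slide_image(array(rep(rgb, each = size * size), c(size, size, 3)),
              slide_id = "flat")
}

# craft zero-network parameters whose prediction is softmax(bc): handy for
# hand-computable classifier and ensemble examples
const_prob_params <- function(p_metastatic, D = 4L) {
  params <- abmil_init(D, hidden = c(3L, 2L), seed = 1L)
  params$W1[] <- 0; params$b1[] <- 0
  params$Wc[] <- 0
  params$bc <- log(c(1 - p_metastatic, p_metastatic))
  params
}
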