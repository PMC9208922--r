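# Shared small fixtures, built in code and memoized for the test run.

local_fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(local_fixture_cache[[key]])) local_fixture_cache[[key]] <- build()
  local_fixture_cache[[key]]
}

# A small labeled cohort: 14 diagnosis bags, 20 discovery nodules.
tiny_cohort <- function() {
  memo("tiny_cohort", function() {
    generate_cohort(synthetic_spec(n_patients = 14, positive_fraction = 0.5,
                                   n_discovery = 20, noise_sd = 0.2, seed = 404))
  })
}

# An untrained compact extractor with a reduced feature dimension, enough to
# exercise every MIL code path quickly.
tiny_extractor <- function(seed = 7, d = 48L) {
  tinycnn_init(channels = c(2L, 3L, 4L), d_out = d, seed = seed)
}

# A latent nodule with fully specified scores (other fields drawn under a
# fixed seed) so renders are comparable across score settings.
fixed_latent <- function(scores, seed = 11, image_size = 64L) {
  spec <- synthetic_spec(n_patients = 5, n_discovery = 1, image_size = image_size,
                         seed = seed)
  base <- sample_attribute_scores(0.5)
  base[names(scores)] <- unlist(scores)
  withr::with_seed(seed, milcascade:::latent_nodule(0.5, spec, scores = base))
}

# Random feature grids standing in for extracted attribute features.
random_feature_bag <- function(n, m, d = 64L) {
  array(rnorm(n * m * d), c(n, m, d))
}

# A minimal mil_model wired to given subnets/head without touching pixels.
feature_model <- function(variant, m, d = 64L, seed = 1L) {
  ext <- lapply(seq_len(max(1L, if (variant == "cascaded") m else 1L)),
                function(i) tiny_extractor(seed + i, d = d))
  names(ext) <- paste0("a", seq_along(ext))
  mil_model(variant, ext, seed = seed)
}
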