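# Synthetic nodule cohort generator.
#
# Emulates the statistical structure that the MIL pipeline assumes: a shared
# per-nodule malignancy latent drives correlated semantic attribute scores
# (linear maps with clipping, plus optional independent jitter), patch
# appearance encodes the true scores (eccentricity, boundary spikes, edge
# blur, internal heterogeneity, bright core, contrast), patients are bags of
# 1-10 nodules, and a bag is positive iff it contains at least one malignant
# nodule. Defaults mirror the real diagnosis-group composition this pipeline
# targets: 117 labeled patients (86 positive, 31 negative) plus a larger
# unlabeled discovery group.

# Direction of each attribute's linear latent -> score map. "int" (internal
# structure) is near-constant: real cohorts consist almost exclusively of
# soft-tissue nodules, so its score carries almost no signal.
ATTR_INCREASING <- c("mal", "lob", "spi", "sub")
ATTR_DECREASING <- c("sph", "mar", "tex", "cal")

#' Specification of a synthetic cohort
#'
#' @param n_patients Number of labeled (diagnosis-group) patients.
#' @param positive_fraction Fraction of diagnosis patients with a positive
#'   pathologic label; strictly between 0 and 1.
#' @param bag_size_range Integer interval for nodules per patient, within
#'   \[1, 10\].
#' @param malignant_per_positive_bag Number of truly malignant nodules planted
#'   in each positive bag (at least 1).
#' @param noise_sd Standard deviation of the independent score jitter added on
#'   top of the latent-driven attribute scores (0 = noise-free).
#' @param image_size Patch side length in pixels (default 64).
#' @param n_discovery Number of unlabeled discovery-group nodules (each is its
#'   own synthetic patient so the two groups never share a patient).
#' @param decoupled_attributes Attributes whose scores are drawn uniformly at
#'   random in their legal range, independent of the malignancy latent. Used
#'   to build cohorts where only some attributes are informative about the
#'   bag label.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A list of class `synthetic_spec`.
#' @export
#' @examples
#' spec <- synthetic_spec(n_patients = 10, n_discovery = 20, seed = 1)
synthetic_spec <- function(n_patients = 117L,
                           positive_fraction = 86 / 117,
                           bag_size_range = c(1L, 10L),
                           malignant_per_positive_bag = 1L,
                           noise_sd = 0.25,
                           image_size = 64L,
                           n_discovery = 2L * n_patients,
                           decoupled_attributes = character(),
                           seed = 1L) {
  stopifnot_scalar_prob(positive_fraction, "positive_fraction")
  bag_size_range <- as.integer(bag_size_range)
  if (length(bag_size_range) != 2L || bag_size_range[1] < 1L ||
      bag_size_range[2] < bag_size_range[1] || bag_size_range[2] > 10L) {
    abort("`bag_size_range` must be an integer interval within [1, 10]",
          class = "milcascade_config_error")
  }
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative", class = "milcascade_config_error")
  if (image_size < 16) abort("`image_size` must be at least 16", class = "milcascade_config_error")
  if (malignant_per_positive_bag < 1L) {
    abort("`malignant_per_positive_bag` must be >= 1", class = "milcascade_config_error")
  }
  bad <- setdiff(decoupled_attributes, MIL_ATTRIBUTES)
  if (length(bad)) abort(paste("unknown attributes:", paste(bad, collapse = ", ")),
                         class = "milcascade_config_error")
  structure(list(n_patients = as.integer(n_patients),
                 positive_fraction = positive_fraction,
                 bag_size_range = bag_size_range,
                 malignant_per_positive_bag = as.integer(malignant_per_positive_bag),
                 noise_sd = noise_sd,
                 image_size = as.integer(image_size),
                 n_discovery = as.integer(n_discovery),
                 decoupled_attributes = decoupled_attributes,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Sample semantic attribute scores from a malignancy latent
#'
#' Noise-free scores are linear in the latent `t` in \[0, 1\]:
#' `mal`, `lob`, `spi`, `sub` increase as `1 + 4t`; `sph`, `mar`, `tex`
#' decrease as `5 - 4t`; `cal` decreases as `6 - 5t` over its \[1, 6\] range;
#' `int` stays at 1 (soft tissue). Independent Gaussian jitter of standard
#' deviation `noise_sd` is added and scores are clipped to their legal range.
#' Attributes listed in `decoupled` are instead drawn uniformly in their
#' range, independent of the latent.
#'
#' @param malignancy_latent Number in \[0, 1\] (0 = clearly benign).
#' @param noise_sd Nonnegative jitter standard deviation.
#' @param decoupled Character vector of attributes decoupled from the latent.
#' @return Named numeric vector over the nine attributes.
#' @export
#' @examples
#' sample_attribute_scores(0.5)          # mal = 3, sph = 3, cal = 3.5, ...
#' sample_attribute_scores(1)["mal"]     # 5, the malignant end
sample_attribute_scores <- function(malignancy_latent, noise_sd = 0,
                                    decoupled = character()) {
  if (!is.numeric(malignancy_latent) || length(malignancy_latent) != 1L ||
      is.na(malignancy_latent) || malignancy_latent < 0 || malignancy_latent > 1) {
    abort("`malignancy_latent` must be a single number in [0, 1]",
          class = "milcascade_domain_error")
  }
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative", class = "milcascade_domain_error")
  t <- malignancy_latent
  s <- c(tex = 5 - 4 * t, sph = 5 - 4 * t, mal = 1 + 4 * t,
         lob = 1 + 4 * t, spi = 1 + 4 * t, mar = 5 - 4 * t,
         cal = 6 - 5 * t, sub = 1 + 4 * t, int = 1)
  for (a in intersect(decoupled, MIL_ATTRIBUTES)) {
    r <- attribute_range(a)
    s[[a]] <- runif(1L, r[1], r[2])
  }
  if (noise_sd > 0) {
    jitter <- rnorm(9L, sd = noise_sd)
    jitter[match("int", names(s))] <- jitter[match("int", names(s))] * 0.1
    s <- s + jitter
  }
  for (a in names(s)) {
    r <- attribute_range(a)
    s[[a]] <- clip(s[[a]], r[1], r[2])
  }
  s[MIL_ATTRIBUTES]
}

# A latent nodule: the ground truth behind one rendered patch. Appearance
# nuisance parameters (position, size, orientation, texture phases) are drawn
# here so that render_patch() is a pure function of the latent.
latent_nodule <- function(malignancy_latent, spec,
                          scores = sample_attribute_scores(malignancy_latent,
                                                           spec$noise_sd,
                                                           spec$decoupled_attributes)) {
  sz <- spec$image_size
  structure(list(
    malignancy_latent = malignancy_latent,
    true_scores = scores,
    center = c(sz / 2 + runif(1L, -2, 2), sz / 2 + runif(1L, -2, 2)),
    radius = runif(1L, 0.12, 0.16) * sz,
    orient = runif(1L, 0, pi),
    phases = runif(2L, 0, 2 * pi),
    appearance_seed = sample.int(2147483600L, 1L)
  ), class = "latent_nodule")
}

# Smoothed unit-variance noise field, used for background and internal texture.
smooth_noise <- function(n, sigma = 2) {
  half <- 3L
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  m <- matrix(rnorm(n * n), n, n)
  m <- apply(m, 2L, function(col) stats::filter(col, k, circular = TRUE))
  m <- t(apply(t(m), 2L, function(col) stats::filter(col, k, circular = TRUE)))
  m / stats::sd(m)
}

#' Render a synthetic nodule patch from its latent description
#'
#' Produces a grayscale patch in \[0, 1\] whose measurable appearance encodes
#' the true attribute scores: blob eccentricity falls with sphericity,
#' boundary lobes/spikes grow with lobulation/spiculation, the edge blurs as
#' margin drops, internal heterogeneity grows as texture drops, a uniform
#' bright core appears at high calcification, contrast against the
#' background rises with subtlety, and the effective blob diameter grows
#' with the subjective malignancy score (the classic size cue). Rendering is
#' deterministic given the latent (nuisance noise is re-seeded from the
#' latent's appearance seed).
#'
#' @param latent A `latent_nodule` object.
#' @param image_size Patch side length in pixels (at least 16).
#' @return `image_size` x `image_size` numeric matrix in \[0, 1\].
#' @export
render_patch <- function(latent, image_size = 64L) {
  if (image_size < 16) abort("`image_size` must be at least 16", class = "milcascade_domain_error")
  s <- latent$true_scores
  n <- as.integer(image_size)
  withr::with_seed(latent$appearance_seed, {
    bnoise <- smooth_noise(n, sigma = 3)
    tnoise <- smooth_noise(n, sigma = 1.5)
  })
  rows <- matrix(seq_len(n), n, n) - latent$center[1]
  cols <- matrix(seq_len(n), n, n, byrow = TRUE) - latent$center[2]
  co <- cos(latent$orient); si <- sin(latent$orient)
  xr <- co * cols + si * rows
  yr <- -si * cols + co * rows
  # effective size grows with subjective malignancy (the diameter cue)
  radius <- latent$radius * (0.6 + 0.8 * (s[["mal"]] - 1) / 4)
  # axis ratio grows as sphericity drops (sph = 5 -> circle)
  ax <- 1 + 1.4 * (5 - s[["sph"]]) / 4
  q <- sqrt((xr / (radius * sqrt(ax)))^2 + (yr * sqrt(ax) / radius)^2)
  theta <- atan2(yr, xr)
  a_lob <- 0.22 * (s[["lob"]] - 1) / 4
  a_spi <- 0.12 * (s[["spi"]] - 1) / 4
  boundary <- 1 + a_lob * cos(4 * theta + latent$phases[1]) +
    a_spi * cos(11 * theta + latent$phases[2])
  # edge softness in units of normalized radius; sharp at mar = 5
  w_q <- (0.35 + 2.2 * (5 - s[["mar"]]) / 4) / radius
  profile <- plogis((boundary - q) / w_q)
  t_amp <- 0.45 * (5 - s[["tex"]]) / 4
  contrast <- 0.40 + 0.50 * (s[["sub"]] - 1) / 4
  core <- 0.35 * (s[["cal"]] - 1) / 5 * plogis((0.35 - q) / 0.05)
  img <- 0.12 + 0.04 * bnoise + contrast * profile * pmax(1 + t_amp * tnoise, 0) + core
  clip(img, 0, 1)
}

#' Generate one patient bag
#'
#' Draws a bag size uniformly from `spec$bag_size_range`, plants
#' `spec$malignant_per_positive_bag` malignant nodules (latent in
#' \[0.7, 1\]) in positive bags, fills the rest with benign nodules (latent
#' in \[0, 0.3\]), and renders each patch. The bag label always equals the
#' logical OR of the per-nodule malignancy indicators.
#'
#' @param bag_label 0 (negative) or 1 (positive).
#' @param spec A [synthetic_spec()].
#' @param patient_id Identifier for the generated patient.
#' @return A list of class `nodule_bag` with elements `patient_id`, `pixels`
#'   (list of matrices), `scores` (tibble, one row per nodule), `label`,
#'   `latents`, and `malignant` (generator ground truth).
#' @export
generate_bag <- function(bag_label, spec, patient_id = "P0001") {
  if (!bag_label %in% c(0, 1)) {
    abort("`bag_label` must be 0 or 1", class = "milcascade_domain_error")
  }
  n <- sample(seq(spec$bag_size_range[1], spec$bag_size_range[2]), 1L)
  if (bag_label == 1) n <- max(n, spec$malignant_per_positive_bag)
  if (n < spec$bag_size_range[1] || n > max(spec$bag_size_range[2], spec$malignant_per_positive_bag)) {
    abort("internal error: bag size outside range", class = "milcascade_internal_error")
  }
  malignant <- rep(FALSE, n)
  if (bag_label == 1) malignant[sample.int(n, spec$malignant_per_positive_bag)] <- TRUE
  latents <- ifelse(malignant, runif(n, 0.7, 1), runif(n, 0, 0.3))
  nodules <- lapply(latents, latent_nodule, spec = spec)
  pixels <- lapply(nodules, render_patch, image_size = spec$image_size)
  scores <- dplyr::bind_rows(lapply(nodules, function(x) tibble::as_tibble_row(as.list(x$true_scores))))
  scores <- dplyr::mutate(scores,
                          nodule_id = sprintf("%s_N%02d", patient_id, seq_len(n)),
                          .before = 1L)
  structure(list(patient_id = patient_id, pixels = pixels, scores = scores,
                 label = as.integer(any(latents > 0.5)),
                 latents = latents, malignant = latents > 0.5),
            class = "nodule_bag")
}

#' Generate a full synthetic cohort
#'
#' Produces an unlabeled discovery group of single-nodule patients and a
#' labeled diagnosis group of patient bags, with disjoint patient ids. The
#' number of positive diagnosis bags is the exact stratified count
#' `round(n_patients * positive_fraction)`.
#'
#' @param spec A [synthetic_spec()].
#' @return A `nodule_cohort`: list with a `manifest` tibble (one row per
#'   nodule: ids, nine attribute scores, `group`, `pmal`, plus generator
#'   ground-truth columns `latent` and `is_malignant`) and `pixels`, a named
#'   list of patch matrices keyed by `nodule_id`.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_spec(n_patients = 6, n_discovery = 8, seed = 7))
#' dplyr::count(cohort$manifest, group, pmal)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n_pos <- round(spec$n_patients * spec$positive_fraction)
  if (n_pos < 1L || n_pos > spec$n_patients - 1L) {
    abort("`positive_fraction` leaves a diagnosis class empty", class = "milcascade_config_error")
  }
  labels <- sample(c(rep(1L, n_pos), rep(0L, spec$n_patients - n_pos)))
  rows <- list(); pixels <- list()
  for (i in seq_len(spec$n_patients)) {
    pid <- sprintf("P%04d", i)
    bag <- generate_bag(labels[i], spec, patient_id = pid)
    rows[[length(rows) + 1L]] <- dplyr::mutate(bag$scores,
      patient_id = pid, group = "diagnosis", pmal = bag$label,
      latent = bag$latents, is_malignant = bag$malignant, .before = 1L)
    names(bag$pixels) <- bag$scores$nodule_id
    pixels <- c(pixels, bag$pixels)
  }
  for (i in seq_len(spec$n_discovery)) {
    pid <- sprintf("D%04d", i)
    t <- runif(1L)
    nod <- latent_nodule(t, spec)
    nid <- sprintf("%s_N01", pid)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      patient_id = pid, group = "discovery", pmal = NA_integer_,
      latent = t, is_malignant = t > 0.5, nodule_id = nid,
      !!!as.list(nod$true_scores))
    pixels[[nid]] <- render_patch(nod, spec$image_size)
  }
  manifest <- dplyr::bind_rows(rows)
  manifest <- dplyr::select(manifest, "patient_id", "nodule_id",
                            dplyr::all_of(MIL_ATTRIBUTES), "group", "pmal",
                            "latent", "is_malignant")
  structure(list(manifest = manifest, pixels = pixels, image_size = spec$image_size),
            class = "nodule_cohort")
}

#' @export
print.nodule_cohort <- function(x, ...) {
  m <- x$manifest
  cat("<nodule_cohort> ", nrow(m), " nodules, ",
      dplyr::n_distinct(m$patient_id), " patients\n", sep = "")
  cat("  discovery: ", sum(m$group == "discovery"), " nodules\n", sep = "")
  dg <- dplyr::distinct(m[m$group == "diagnosis", ], .data$patient_id, .data$pmal)
  cat("  diagnosis: ", sum(m$group == "diagnosis"), " nodules in ", nrow(dg),
      " bags (", sum(dg$pmal == 1), " positive / ", sum(dg$pmal == 0), " negative)\n", sep = "")
  invisible(x)
}

#' Assemble the labeled diagnosis group into patient bags
#'
#' @param cohort A `nodule_cohort`.
#' @return List of `nodule_bag` objects (one per labeled patient), each with
#'   `patient_id`, `pixels`, `scores`, `label` and, when the cohort is
#'   synthetic, the generator's ground-truth `malignant` flags.
#' @export
diagnosis_bags <- function(cohort) {
  m <- cohort$manifest[cohort$manifest$group == "diagnosis", ]
  lapply(split(m, m$patient_id), function(d) {
    d <- d[order(d$nodule_id), ]
    structure(list(patient_id = d$patient_id[1],
                   pixels = cohort$pixels[d$nodule_id],
                   scores = dplyr::select(d, "nodule_id", dplyr::all_of(MIL_ATTRIBUTES)),
                   label = d$pmal[1],
                   latents = if ("latent" %in% names(d)) d$latent else NULL,
                   malignant = if ("is_malignant" %in% names(d)) d$is_malignant else NULL),
              class = "nodule_bag")
  })
}

#' Extract the unlabeled discovery group as patches plus scores
#'
#' @param cohort A `nodule_cohort`.
#' @return List with `pixels` (list of matrices) and `scores` (tibble with
#'   `nodule_id` and the nine attribute columns).
#' @export
discovery_patches <- function(cohort) {
  m <- cohort$manifest[cohort$manifest$group == "discovery", ]
  list(pixels = cohort$pixels[m$nodule_id],
       scores = dplyr::select(m, "nodule_id", dplyr::all_of(MIL_ATTRIBUTES)))
}
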