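# Manifest interchange format: one directory holding 8-bit grayscale PNG
# patches plus a manifest CSV with columns patient_id, nodule_id, path, the
# nine attribute scores, group (discovery/diagnosis), and pmal (0/1/NA).
# This schema is the single interchange point between real ingested data and
# the synthetic generator; synthetic cohorts carry two extra ground-truth
# columns (latent, is_malignant) that round-trip when present.

MANIFEST_REQUIRED <- c("patient_id", "nodule_id", "path", MIL_ATTRIBUTES, "group", "pmal")

#' Save a cohort to a manifest directory
#'
#' Writes `manifest.csv` plus one 8-bit grayscale PNG per nodule under
#' `patches/`. Pixels are quantized to 8 bits at this boundary only; in
#' memory the package always works with \[0, 1\] doubles.
#'
#' @param cohort A `nodule_cohort`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_manifest <- function(cohort, path) {
  stopifnot(inherits(cohort, "nodule_cohort"))
  dir.create(file.path(path, "patches"), recursive = TRUE, showWarnings = FALSE)
  m <- cohort$manifest
  m$path <- file.path("patches", paste0(m$nodule_id, ".png"))
  for (i in seq_len(nrow(m))) {
    png::writePNG(cohort$pixels[[m$nodule_id[i]]], file.path(path, m$path[i]))
  }
  keep <- c(MANIFEST_REQUIRED, intersect(c("latent", "is_malignant"), names(m)))
  readr::write_csv(m[, keep], file.path(path, "manifest.csv"))
  invisible(path)
}

validate_manifest <- function(m) {
  missing <- setdiff(setdiff(MANIFEST_REQUIRED, "path"), names(m))
  if (length(missing)) {
    abort(paste("manifest is missing columns:", paste(missing, collapse = ", ")),
          class = "milcascade_validation_error")
  }
  if (!all(m$group %in% c("discovery", "diagnosis"))) {
    bad <- which(!m$group %in% c("discovery", "diagnosis"))[1]
    abort(paste0("row ", bad, " (", m$nodule_id[bad], "): group must be discovery or diagnosis"),
          class = "milcascade_validation_error")
  }
  for (a in MIL_ATTRIBUTES) {
    r <- attribute_range(a)
    bad <- which(!is.finite(m[[a]]) | m[[a]] < r[1] | m[[a]] > r[2])
    if (length(bad)) {
      abort(sprintf("row %d (%s): %s = %s outside legal range [%g, %g]",
                    bad[1], m$nodule_id[bad[1]], a, format(m[[a]][bad[1]]), r[1], r[2]),
            class = "milcascade_validation_error")
    }
  }
  bad <- which(m$group == "discovery" & !is.na(m$pmal))
  if (length(bad)) {
    abort(paste0("row ", bad[1], " (", m$nodule_id[bad[1]], "): discovery rows must have pmal = NA"),
          class = "milcascade_validation_error")
  }
  bad <- which(m$group == "diagnosis" & !(m$pmal %in% c(0L, 1L)))
  if (length(bad)) {
    abort(paste0("row ", bad[1], " (", m$nodule_id[bad[1]], "): diagnosis rows need pmal in {0, 1}"),
          class = "milcascade_validation_error")
  }
  mixed <- dplyr::summarise(dplyr::group_by(m, .data$patient_id),
                            n_groups = dplyr::n_distinct(.data$group))
  mixed <- mixed$patient_id[mixed$n_groups > 1L]
  if (length(mixed)) {
    abort(paste0("patient ", mixed[1], " appears in both discovery and diagnosis groups"),
          class = "milcascade_validation_error")
  }
  if (anyDuplicated(m$nodule_id)) {
    abort(paste0("duplicated nodule_id: ", m$nodule_id[duplicated(m$nodule_id)][1]),
          class = "milcascade_validation_error")
  }
  invisible(m)
}

#' Load a cohort from a manifest directory
#'
#' Reads and validates `manifest.csv` and the referenced PNG patches. A
#' save/load round trip reproduces the cohort exactly up to the 8-bit PNG
#' quantization of pixel values.
#'
#' @param path Directory written by [save_manifest()] (or by an external
#'   ingestion step that emits the same schema).
#' @return A `nodule_cohort`.
#' @export
load_manifest <- function(path) {
  f <- file.path(path, "manifest.csv")
  if (!file.exists(f)) abort(paste("no manifest.csv under", path), class = "milcascade_validation_error")
  m <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
  validate_manifest(m)
  pixels <- list()
  for (i in seq_len(nrow(m))) {
    img <- png::readPNG(file.path(path, m$path[i]))
    if (length(dim(img)) == 3L) img <- img[, , 1L]   # tolerate non-grayscale PNGs
    pixels[[m$nodule_id[i]]] <- img
  }
  sizes <- unique(vapply(pixels, nrow, integer(1)))
  structure(list(manifest = m, pixels = pixels, image_size = sizes[1]),
            class = "nodule_cohort")
}
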