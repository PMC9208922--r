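# Coefficient-based interpretability: which nodule decided the bag, and
# which attributes decided each nodule.

#' Explain a bag prediction through its recalibration coefficients
#'
#' Runs a recalibrated or cascaded model on one bag and returns a tidy
#' table with one row per nodule: the nodule coefficient `beta`, the
#' attribute coefficients (`alpha_<attr>`, cascaded models only), the
#' radiologist scores, the bag probability, and a flag on the key nodule
#' (the argmax of `beta`; exact ties are flagged on the first index with a
#' tie note).
#'
#' @param model A `mil_model` of variant `"cascaded"` or `"recalibrated"`.
#' @param bag A `nodule_bag`.
#' @return A tibble, one row per nodule.
#' @export
explain_bag <- function(model, bag) {
  stopifnot(inherits(model, "mil_model"))
  if (!model$variant %in% c("cascaded", "recalibrated")) {
    abort("instance-space and embedding-space models expose no recalibration coefficients",
          class = "milcascade_unsupported_error")
  }
  pred <- forward_cascaded(model, bag)
  rc <- pred$recalibration
  n <- length(rc$beta)
  is_tie <- sum(abs(rc$beta - max(rc$beta)) < 1e-12) > 1L
  out <- tibble::tibble(
    patient_id = bag$patient_id %||% NA_character_,
    nodule_id = if (!is.null(bag$scores)) bag$scores$nodule_id else sprintf("N%02d", seq_len(n)),
    beta = rc$beta,
    key_nodule = seq_len(n) == rc$key_nodule,
    tie = is_tie)
  if (model$variant == "cascaded") {
    alpha <- rc$alpha
    colnames(alpha) <- paste0("alpha_", model$attributes)
    out <- dplyr::bind_cols(out, tibble::as_tibble(alpha))
  }
  if (!is.null(bag$scores)) {
    out <- dplyr::left_join(out,
                            dplyr::select(bag$scores, "nodule_id", dplyr::any_of(MIL_ATTRIBUTES)),
                            by = "nodule_id")
  }
  out$bag_probability <- pred$probability
  out$bag_label_pred <- pred$label
  out$bag_label_true <- bag$label %||% NA_integer_
  out
}

#' Coefficient report over many bags
#'
#' @param model A cascaded or recalibrated `mil_model`.
#' @param bags List of `nodule_bag`s.
#' @param path Optional CSV output path (`explain.csv` layout).
#' @return A tibble (one row per nodule over all bags).
#' @export
explain_cohort <- function(model, bags, path = NULL) {
  out <- purrr::map_dfr(bags, explain_bag, model = model)
  if (!is.null(path)) readr::write_csv(out, path)
  out
}

#' Plot nodule recalibration coefficients per patient
#'
#' @param explained A tibble from [explain_cohort()] / [explain_bag()].
#' @return A ggplot object.
#' @export
plot_coefficients <- function(explained) {
  ggplot2::ggplot(explained,
                  ggplot2::aes(x = .data$nodule_id, y = .data$beta,
                               fill = .data$key_nodule)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~patient_id, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                               name = "key nodule") +
    ggplot2::labs(x = NULL, y = "nodule coefficient (beta)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
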