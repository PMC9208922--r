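# Evaluation metrics and fold aggregation.

check_pred_args <- function(probabilities, labels) {
  if (length(probabilities) != length(labels) || length(labels) < 1L) {
    abort("`probabilities` and `labels` must have equal length >= 1",
          class = "milcascade_domain_error")
  }
}

#' Classification accuracy at a probability threshold
#'
#' A probability of at least `threshold` is called positive (a predicted
#' confidence below 0.5 means negative; ties at the threshold are positive).
#'
#' @param probabilities Numeric vector in \[0, 1\].
#' @param labels 0/1 vector of the same length.
#' @param threshold Decision threshold (default 0.5).
#' @return Fraction of correct predictions.
#' @export
#' @examples
#' accuracy(c(0.9, 0.1), c(1, 0))  # 1
accuracy <- function(probabilities, labels, threshold = 0.5) {
  check_pred_args(probabilities, labels)
  mean(as.integer(probabilities >= threshold) == labels)
}

#' Area under the ROC curve (rank statistic)
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative, with ties counted one half — the Mann-Whitney
#' formulation, invariant to any strictly monotone transform of the scores.
#'
#' @inheritParams accuracy
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc(c(0.5, 0.5, 0.7), c(0, 1, 1))  # 0.75
auc <- function(probabilities, labels) {
  check_pred_args(probabilities, labels)
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    abort("AUC needs both classes present", class = "milcascade_domain_error")
  }
  r <- rank(probabilities, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro-averaged F1 score
#'
#' Unweighted mean of the positive-class F1 and the negative-class F1 (the
#' negative class is treated as "positive" for its own score). A class F1
#' with no predicted and no actual members is defined as 0.
#'
#' @inheritParams accuracy
#' @return Macro F1 in \[0, 1\].
#' @export
#' @examples
#' f1_macro(c(0.9, 0.8, 0.7), c(1, 1, 0))  # pos F1 0.8, neg F1 0 -> 0.4
f1_macro <- function(probabilities, labels, threshold = 0.5) {
  check_pred_args(probabilities, labels)
  pred <- as.integer(probabilities >= threshold)
  class_f1 <- function(cls) {
    tp <- sum(pred == cls & labels == cls)
    fp <- sum(pred == cls & labels != cls)
    fn <- sum(pred != cls & labels == cls)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  (class_f1(1L) + class_f1(0L)) / 2
}

#' Aggregate per-fold metrics into a mean-and-SD report
#'
#' @param per_fold Data frame with numeric columns `accuracy`, `auc`, `f1`
#'   (one row per fold, at least two folds). Extra columns are kept in the
#'   per-fold table.
#' @return Object of class `mil_metrics` with `per_fold` and `mean_sd`
#'   (arithmetic mean and sample standard deviation, n - 1 denominator).
#' @export
#' @examples
#' aggregate_folds(data.frame(accuracy = c(0.7, 0.9), auc = c(0.8, 0.8),
#'                            f1 = c(0.6, 0.8)))
aggregate_folds <- function(per_fold) {
  need <- c("accuracy", "auc", "f1")
  if (!is.data.frame(per_fold) || !all(need %in% names(per_fold)) || nrow(per_fold) < 2L) {
    abort("`per_fold` needs columns accuracy/auc/f1 and at least two folds",
          class = "milcascade_domain_error")
  }
  mean_sd <- tidyr::pivot_longer(tibble::as_tibble(per_fold)[need],
                                 dplyr::all_of(need),
                                 names_to = "metric", values_to = "value")
  mean_sd <- dplyr::summarise(dplyr::group_by(mean_sd, .data$metric),
                              mean = mean(.data$value), sd = stats::sd(.data$value),
                              .groups = "drop")
  mean_sd <- mean_sd[match(need, mean_sd$metric), ]
  structure(list(per_fold = tibble::as_tibble(per_fold), mean_sd = mean_sd),
            class = "mil_metrics")
}

#' @export
print.mil_metrics <- function(x, ...) {
  cat("<mil_metrics> ", nrow(x$per_fold), " folds\n", sep = "")
  for (i in seq_len(nrow(x$mean_sd))) {
    cat(sprintf("  %-8s %.3f +/- %.3f\n", x$mean_sd$metric[i],
                x$mean_sd$mean[i], x$mean_sd$sd[i]))
  }
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.mil_metrics <- function(x, ...) x$per_fold

#' @rdname tidiers
#' @export
glance.mil_metrics <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$mean_sd, names_from = "metric",
                             values_from = c("mean", "sd"),
                             names_glue = "{metric}_{.value}")
  wide$n_folds <- nrow(x$per_fold)
  wide
}

#' Broom-style tidiers
#'
#' `tidy()` returns the per-unit table of a result (per-fold metrics, the
#' per-iteration loss trace, or the ranked attribute table); `glance()`
#' returns a one-row summary.
#'
#' @param x A `mil_metrics`, `mil_fit`, or `attribute_ranking` object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.mil_fit <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$loss), loss = x$loss)
}

#' @rdname tidiers
#' @export
glance.mil_fit <- function(x, ...) {
  tibble::tibble(variant = x$model$variant,
                 attributes = paste(x$model$attributes, collapse = "+"),
                 iterations = length(x$loss),
                 final_loss = if (length(x$loss)) x$loss[length(x$loss)] else NA_real_)
}

#' @rdname tidiers
#' @export
tidy.attribute_ranking <- function(x, ...) tibble::as_tibble(x)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Write a metrics report to JSON
#'
#' Serializes a `mil_metrics` report together with the run description
#' (variant, attribute sources, k, seed, and a hash of the configuration)
#' in a stable machine-readable layout.
#'
#' @param metrics A `mil_metrics` object.
#' @param path Output file.
#' @param variant,attributes,k,seed Run description fields.
#' @param config Configuration list hashed into `config_hash`.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path, variant = "cascaded",
                               attributes = character(), k = length(attributes),
                               seed = NA_integer_, config = NULL) {
  payload <- list(
    variant = variant,
    attributes = as.list(attributes),
    k = k,
    per_fold = lapply(seq_len(nrow(metrics$per_fold)), function(i) {
      as.list(metrics$per_fold[i, c("accuracy", "auc", "f1")])
    }),
    mean_sd = stats::setNames(lapply(seq_len(nrow(metrics$mean_sd)), function(i) {
      list(mean = metrics$mean_sd$mean[i], sd = metrics$mean_sd$sd[i])
    }), metrics$mean_sd$metric),
    seed = seed,
    config_hash = fnv1a_hash(paste(deparse(config), collapse = "")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot the training loss trace of a MIL fit
#'
#' @param object A `mil_fit`.
#' @param window Width of the rolling-mean smoothing window.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mil_fit <- function(object, window = 50L, ...) {
  df <- tidy.mil_fit(object)
  df$smooth <- as.numeric(stats::filter(df$loss, rep(1 / window, window), sides = 1L))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$loss), alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smooth), na.rm = TRUE) +
    ggplot2::labs(x = "iteration (one bag per step)", y = "binary cross-entropy",
                  title = paste(object$model$variant, "MIL training loss")) +
    ggplot2::theme_minimal()
}

#' Plot an attribute ranking
#'
#' @param object An `attribute_ranking`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.attribute_ranking <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$attribute <- stats::reorder(df$attribute, -df$rank)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f1, y = .data$attribute)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "mean F1 (single-attribute recalibrated MIL)", y = NULL,
                  title = "Attribute source ranking") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
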