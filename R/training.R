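# Three-step training protocol: (I) attribute-specific models on the
# discovery group, (II) per-attribute recalibrated-MIL ranking on the
# diagnosis group, (III) cascaded-recalibrated training with the top-k
# attribute sources — plus class-balanced bag sampling and stratified
# patient-level k-fold cross-validation.

#' Training configuration for MIL bag classifiers
#'
#' Defaults follow the standard recipe for this pipeline: SGD with one bag
#' per step, learning rate 0.001, weight decay 1e-4, 2000 iterations over a
#' class-balanced alternating bag stream.
#'
#' @param iterations Number of single-bag gradient steps.
#' @param lr Learning rate.
#' @param optimizer `"sgd"` (default) or `"adam"`.
#' @param momentum Classical SGD momentum coefficient (SGD only).
#' @param weight_decay L2 penalty coupled into the SGD update.
#' @param batch Bags per step; fixed at 1 (larger values are rejected).
#' @param seed Integer seed controlling sampling and initialization.
#' @param frozen_extractors Keep attribute extractors fixed during MIL
#'   training (default TRUE).
#' @return List of class `mil_train_config`.
#' @export
mil_train_config <- function(iterations = 2000L, lr = 0.001,
                             optimizer = c("sgd", "adam"), momentum = 0.9,
                             weight_decay = 1e-4, batch = 1L, seed = 1L,
                             frozen_extractors = TRUE) {
  if (batch != 1L) {
    abort("`batch` is fixed at 1 bag per step", class = "milcascade_config_error")
  }
  structure(list(iterations = as.integer(iterations), lr = lr,
                 optimizer = match.arg(optimizer), momentum = momentum,
                 weight_decay = weight_decay, batch = 1L,
                 seed = as.integer(seed), frozen_extractors = isTRUE(frozen_extractors)),
            class = "mil_train_config")
}

bag_labels <- function(bags) vapply(bags, function(b) as.integer(b$label), integer(1))

#' Class-balanced alternating bag stream
#'
#' Returns a generator function that strictly alternates positive and
#' negative bags (positive first), sampling uniformly with replacement
#' within each class. This is the imbalance counter-measure used during MIL
#' training.
#'
#' @param bags List of labeled `nodule_bag`s (both classes must be present).
#' @return A function; each call returns the index (into `bags`) of the next
#'   bag, with the bag itself attached as attribute `"bag"`.
#' @export
balanced_bag_stream <- function(bags) {
  labels <- bag_labels(bags)
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  if (!length(pos) || !length(neg)) {
    abort("both a positive and a negative bag are required",
          class = "milcascade_config_error")
  }
  count <- 0L
  function() {
    count <<- count + 1L
    idx <- if (count %% 2L == 1L) pos[sample.int(length(pos), 1L)]
           else neg[sample.int(length(neg), 1L)]
    structure(idx, bag = bags[[idx]])
  }
}

#' Train a MIL bag classifier
#'
#' Runs `config$iterations` single-bag SGD steps of the binary cross-entropy
#' loss over the class-balanced alternating bag stream. With frozen
#' extractors (the default), attribute features are computed once per bag
#' and cached; with trainable extractors, gradients flow through the
#' backbone as well.
#'
#' @param model A [mil_model()].
#' @param bags List of labeled `nodule_bag`s.
#' @param config A [mil_train_config()].
#' @param features Optional precomputed feature grids (list of `(n, m, d)`
#'   arrays parallel to `bags`), valid only with frozen extractors.
#' @return Object of class `mil_fit`: the trained `model`, the per-iteration
#'   `loss` trace, and the `config`.
#' @export
train_mil <- function(model, bags, config = mil_train_config(), features = NULL) {
  stopifnot(inherits(model, "mil_model"))
  frozen <- model$frozen && config$frozen_extractors
  if (!is.null(features) && !frozen) {
    abort("precomputed features require frozen extractors", class = "milcascade_config_error")
  }
  if (config$iterations > 0L) {
    labels <- bag_labels(bags)
    if (!any(labels == 1L) || !any(labels == 0L)) {
      abort("training needs at least one bag of each class", class = "milcascade_config_error")
    }
  }
  if (frozen && is.null(features) && config$iterations > 0L) {
    features <- lapply(bags, extract_attribute_features, extractors = model$extractors)
  }
  trace <- numeric(config$iterations)
  st <- list(head = NULL, nodule = NULL, attr = NULL,
             ext = vector("list", model$m))
  if (config$iterations > 0L) withr::with_seed(derive_seed(config$seed, "mil-train"), {
    stream <- balanced_bag_stream(bags)
    for (it in seq_len(config$iterations)) {
      idx <- as.integer(stream())
      bag <- bags[[idx]]
      if (frozen) {
        U <- features[[idx]]
        ext_caches <- NULL
      } else {
        n <- length(bag$pixels)
        U <- array(0, c(n, model$m, model$d))
        ext_caches <- vector("list", model$m)
        batch <- patches_to_batch(bag$pixels)
        for (j in seq_len(model$m)) {
          fj <- cnn_forward(model$extractors[[j]], batch, cache = TRUE)
          U[, j, ] <- fj$out
          ext_caches[[j]] <- fj$cache
        }
      }
      fw <- mil_forward(model, U, cache = TRUE)
      bw <- mil_backward(model, fw, U, bag$label, need_dU = !frozen)
      if (!is.finite(bw$loss)) {
        abort(sprintf("MIL training diverged at iteration %d", it),
              class = "milcascade_divergence_error")
      }
      trace[it] <- bw$loss
      cfg <- list(optimizer = config$optimizer, lr = config$lr,
                  momentum = config$momentum,
                  weight_decay = config$weight_decay, t = it)
      up <- mlp_update(model$head, bw$grads$head, cfg, st$head)
      model$head <- up$net; st$head <- up$st
      if (!is.null(model$subnet_nodule)) {
        up <- mlp_update(model$subnet_nodule, bw$grads$nodule, cfg, st$nodule)
        model$subnet_nodule <- up$net; st$nodule <- up$st
      }
      if (!is.null(model$subnet_attr)) {
        up <- mlp_update(model$subnet_attr, bw$grads$attr, cfg, st$attr)
        model$subnet_attr <- up$net; st$attr <- up$st
      }
      if (!frozen) {
        for (j in seq_len(model$m)) {
          cb <- cnn_backward(model$extractors[[j]], ext_caches[[j]],
                             matrix(bw$dU[, j, ], nrow = dim(U)[1L]))
          up <- cnn_update(model$extractors[[j]], cb$grads, cfg, st$ext[[j]])
          model$extractors[[j]] <- up$net; st$ext[[j]] <- up$st
        }
      }
    }
  })
  structure(list(model = model, loss = trace, config = config), class = "mil_fit")
}

#' @export
print.mil_fit <- function(x, ...) {
  cat("<mil_fit> ", x$model$variant, " MIL, ", length(x$loss), " iterations", sep = "")
  if (length(x$loss) >= 50L) {
    cat("; mean loss first 50 = ", signif(mean(head(x$loss, 50L)), 4),
        ", last 50 = ", signif(mean(utils::tail(x$loss, 50L)), 4), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Stratified patient-level cross-validation folds
#'
#' Partitions labeled bags into `k` folds at the patient level, stratified
#' by the bag label so every fold keeps both classes, with fold sizes as
#' equal as the class counts allow.
#'
#' @param bags List of labeled `nodule_bag`s, or a data frame with
#'   `patient_id` and `label` columns.
#' @param k Number of folds (at least 2).
#' @param seed Integer seed; identical seeds give identical folds.
#' @return Tibble of class `fold_split` with `patient_id`, `label`, `fold`.
#' @export
make_folds <- function(bags, k = 5L, seed = 1L) {
  if (k < 2L) abort("`k` must be at least 2", class = "milcascade_config_error")
  df <- if (is.data.frame(bags)) {
    tibble::as_tibble(bags[, c("patient_id", "label")])
  } else {
    tibble::tibble(patient_id = vapply(bags, function(b) b$patient_id, character(1)),
                   label = bag_labels(bags))
  }
  pos <- df$patient_id[df$label == 1L]
  neg <- df$patient_id[df$label == 0L]
  if (length(pos) < k || length(neg) < k) {
    abort("need at least k bags of each class for stratified folds",
          class = "milcascade_config_error")
  }
  withr::with_seed(as.integer(seed), {
    pos <- sample(pos); neg <- sample(neg)
  })
  # largest-remainder class counts; positive surplus goes to the first folds,
  # negative surplus to the last, keeping total fold sizes maximally even
  pos_counts <- rep(length(pos) %/% k, k); extra <- length(pos) %% k
  if (extra) pos_counts[seq_len(extra)] <- pos_counts[seq_len(extra)] + 1L
  neg_counts <- rep(length(neg) %/% k, k); extra <- length(neg) %% k
  if (extra) neg_counts[k - seq_len(extra) + 1L] <- neg_counts[k - seq_len(extra) + 1L] + 1L
  assign_folds <- function(ids, counts) {
    rep(seq_len(k), counts)[seq_along(ids)]
  }
  out <- dplyr::bind_rows(
    tibble::tibble(patient_id = pos, label = 1L, fold = assign_folds(pos, pos_counts)),
    tibble::tibble(patient_id = neg, label = 0L, fold = assign_folds(neg, neg_counts)))
  out <- out[order(out$fold, out$patient_id), ]
  class(out) <- c("fold_split", class(out))
  out
}

# Evaluate a trained model on held-out bags using cached features.
eval_bags <- function(model, bags, features) {
  probs <- vapply(seq_along(bags), function(i) {
    mil_forward(model, features[[i]])$probability
  }, numeric(1))
  tibble::tibble(patient_id = vapply(bags, function(b) b$patient_id, character(1)),
                 probability = probs, label = bag_labels(bags))
}

fold_metrics <- function(preds) {
  tibble::tibble(accuracy = accuracy(preds$probability, preds$label),
                 auc = auc(preds$probability, preds$label),
                 f1 = f1_macro(preds$probability, preds$label))
}

# Shared cross-validated train/evaluate loop for one extractor set.
cv_mil <- function(variant, extractors, bags, folds, config, keep_models = FALSE) {
  feats <- lapply(bags, extract_attribute_features, extractors = extractors)
  pid <- vapply(bags, function(b) b$patient_id, character(1))
  per_fold <- list(); models <- list(); preds_all <- list()
  for (f in sort(unique(folds$fold))) {
    test_ids <- folds$patient_id[folds$fold == f]
    tr <- which(!pid %in% test_ids); te <- which(pid %in% test_ids)
    model <- mil_model(variant, extractors,
                       seed = derive_seed(config$seed, paste0("fold-", f)))
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("train-fold-", f))
    fit <- train_mil(model, bags[tr], cfg, features = feats[tr])
    preds <- eval_bags(fit$model, bags[te], feats[te])
    preds$fold <- f
    per_fold[[f]] <- dplyr::mutate(fold_metrics(preds), fold = f)
    preds_all[[f]] <- preds
    if (keep_models) models[[f]] <- fit
  }
  list(per_fold = dplyr::bind_rows(per_fold),
       predictions = dplyr::bind_rows(preds_all),
       models = models)
}

#' Rank attribute sources by single-attribute MIL performance
#'
#' For each attribute, trains a single-attribute recalibrated MIL model per
#' cross-validation fold on the diagnosis group and ranks the attributes by
#' mean F1 (ties broken by mean accuracy, then mean AUC, then attribute
#' name). The fold split and all derived seeds are shared across attributes,
#' so attributes with identical extractors tie exactly and the tie-break is
#' deterministic.
#'
#' @param cohort A `nodule_cohort` with a labeled diagnosis group.
#' @param attribute_models Named list of `attribute_model`s (or extractors),
#'   one per candidate attribute.
#' @param config A [mil_train_config()].
#' @param k Number of cross-validation folds.
#' @return Tibble of class `attribute_ranking`: one row per attribute with
#'   mean `f1`, `accuracy`, `auc`, and `rank`; per-fold detail in
#'   `attr(, "per_fold")`.
#' @export
rank_attributes <- function(cohort, attribute_models, config = mil_train_config(), k = 5L) {
  if (is.null(names(attribute_models)) || any(names(attribute_models) == "")) {
    abort("`attribute_models` must be a named list", class = "milcascade_config_error")
  }
  bags <- diagnosis_bags(cohort)
  folds <- make_folds(bags, k = k, seed = derive_seed(config$seed, "folds"))
  rows <- list(); detail <- list()
  for (a in names(attribute_models)) {
    res <- cv_mil("recalibrated", stats::setNames(attribute_models[a], a),
                  bags, folds, config)
    rows[[a]] <- tibble::tibble(attribute = a,
                                f1 = mean(res$per_fold$f1),
                                accuracy = mean(res$per_fold$accuracy),
                                auc = mean(res$per_fold$auc))
    detail[[a]] <- dplyr::mutate(res$per_fold, attribute = a)
  }
  out <- dplyr::bind_rows(rows)
  out <- out[order(-out$f1, -out$accuracy, -out$auc, out$attribute), ]
  out$rank <- seq_len(nrow(out))
  attr(out, "per_fold") <- dplyr::bind_rows(detail)
  class(out) <- c("attribute_ranking", class(out))
  out
}

#' Train and evaluate the cascaded model on the top-k attribute sources
#'
#' Selects the `k_top` best-ranked attributes and trains a
#' cascaded-recalibrated MIL model per cross-validation fold, reporting
#' accuracy, AUC, and macro F1 as mean and standard deviation over folds.
#' With `k_top = 1` and shared seeds this reproduces the recalibrated-MIL
#' run of the top attribute exactly.
#'
#' @param cohort A `nodule_cohort` with a labeled diagnosis group.
#' @param attribute_models Named list of `attribute_model`s covering at
#'   least the ranked attributes.
#' @param ranking An [rank_attributes()] result (or a character vector of
#'   attribute names, best first).
#' @param k_top Number of top-ranked attribute sources to use.
#' @param config A [mil_train_config()].
#' @param k Number of cross-validation folds.
#' @return List of class `topk_result`: `attributes` used, per-fold fitted
#'   models, held-out `predictions`, and `metrics` (a `mil_metrics` report).
#' @export
run_top_k <- function(cohort, attribute_models, ranking, k_top = 3L,
                      config = mil_train_config(), k = 5L) {
  order_names <- if (is.character(ranking)) ranking else ranking$attribute
  if (k_top < 1L || k_top > length(order_names)) {
    abort("`k_top` must be between 1 and the number of ranked attributes",
          class = "milcascade_config_error")
  }
  sel <- order_names[seq_len(k_top)]
  missing <- setdiff(sel, names(attribute_models))
  if (length(missing)) {
    abort(paste("no extractor for attribute(s):", paste(missing, collapse = ", ")),
          class = "milcascade_config_error")
  }
  bags <- diagnosis_bags(cohort)
  folds <- make_folds(bags, k = k, seed = derive_seed(config$seed, "folds"))
  res <- cv_mil("cascaded", attribute_models[sel], bags, folds, config,
                keep_models = TRUE)
  structure(list(attributes = sel, folds = folds, models = res$models,
                 predictions = res$predictions,
                 metrics = aggregate_folds(res$per_fold),
                 config = config),
            class = "topk_result")
}

#' @export
print.topk_result <- function(x, ...) {
  cat("<topk_result> cascaded MIL on", paste(x$attributes, collapse = " + "), "\n")
  print(x$metrics)
  invisible(x)
}
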