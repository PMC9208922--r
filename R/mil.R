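# Multiple-instance bag classifiers over nodule patches.
#
# Four poolings are provided: instance-space (max over per-nodule
# probabilities), embedding-space (elementwise max over nodule embeddings),
# recalibrated (softmax attention over nodules), and cascaded-recalibrated
# (softmax attention first over each nodule's attribute features, then over
# the resulting nodule embeddings). The recalibration coefficients are
# returned with every forward pass for interpretability.

#' Create a recalibration subnetwork
#'
#' A 512-128-32-1 fully connected network (ReLU on the first three layers,
#' linear output) that squeezes a feature embedding into one recalibration
#' logit. Softmax over the logits of a group (a nodule's attributes, or a
#' bag's nodules) yields the recalibration coefficients.
#'
#' @param d Input feature dimension.
#' @param widths Full layer-width vector; override for reduced test networks.
#' @param seed Optional integer seed for reproducible initialization.
#' @return An MLP usable with [attribute_recalibrate()] / [nodule_recalibrate()].
#' @export
recal_subnet <- function(d = 512L, widths = c(d, 128L, 32L, 1L), seed = NULL) {
  mlp_init(widths, seed = seed)
}

#' Create a bag classification head
#'
#' A 512-32-1 fully connected network (ReLU on the first two layers) whose
#' logistic output is the bag-positive probability.
#'
#' @inheritParams recal_subnet
#' @return An MLP usable with [classify_bag()].
#' @export
classifier_head <- function(d = 512L, widths = c(d, 32L, 1L), seed = NULL) {
  mlp_init(widths, seed = seed)
}

as_extractors <- function(extractors) {
  if (inherits(extractors, "milcascade_cnn")) extractors <- list(extractors)
  extractors <- lapply(extractors, function(e) {
    if (inherits(e, "attribute_model")) e$extractor else e
  })
  d <- unique(vapply(extractors, function(e) e$d_out, numeric(1)))
  if (length(d) != 1L) {
    abort("all extractors must share the same output dimension",
          class = "milcascade_config_error")
  }
  extractors
}

#' Construct a MIL bag classifier
#'
#' @param variant One of `"cascaded"`, `"recalibrated"`, `"instance"`,
#'   `"embedding"`. The latter three use exactly one attribute source.
#' @param extractors Named list of trained attribute extractors (or
#'   `attribute_model`s); names give the attribute order `1..m`.
#' @param seed Integer seed; the head and each subnetwork draw their
#'   initialization from independent derived seeds, so a cascaded model and a
#'   recalibrated model built from the same seed share identical
#'   nodule-level subnet and head weights.
#' @param frozen Keep the extractors fixed during MIL training (default).
#' @return Object of class `mil_model`.
#' @export
mil_model <- function(variant = c("cascaded", "recalibrated", "instance", "embedding"),
                      extractors, seed = 1L, frozen = TRUE) {
  variant <- match.arg(variant)
  extractors <- as_extractors(extractors)
  m <- length(extractors)
  if (m < 1L) abort("at least one extractor is required", class = "milcascade_config_error")
  if (variant != "cascaded" && m != 1L) {
    abort(paste0("variant '", variant, "' uses exactly one attribute source"),
          class = "milcascade_config_error")
  }
  d <- extractors[[1L]]$d_out
  model <- list(variant = variant, attributes = names(extractors) %||% rep("", m),
                extractors = extractors, d = d, m = m, frozen = frozen,
                seed = as.integer(seed),
                head = classifier_head(d, seed = derive_seed(seed, "head")))
  if (variant %in% c("cascaded", "recalibrated")) {
    model$subnet_nodule <- recal_subnet(d, seed = derive_seed(seed, "nodule"))
  }
  if (variant == "cascaded") {
    model$subnet_attr <- recal_subnet(d, seed = derive_seed(seed, "attr"))
  }
  structure(model, class = "mil_model")
}

#' @export
print.mil_model <- function(x, ...) {
  cat("<mil_model> ", x$variant, " MIL, attributes: ",
      paste(x$attributes, collapse = ", "),
      " (d = ", x$d, ", extractors ", if (x$frozen) "frozen" else "trainable", ")\n",
      sep = "")
  invisible(x)
}

#' Extract the n x m grid of attribute features for one bag
#'
#' Applies each of the `m` frozen attribute extractors to each of the bag's
#' `n` nodule patches.
#'
#' @param bag A `nodule_bag` (or any list with a `pixels` list of matrices).
#' @param extractors List of extractors sharing one output dimension.
#' @return Numeric array of shape `(n, m, d)`.
#' @export
extract_attribute_features <- function(bag, extractors) {
  extractors <- as_extractors(extractors)
  n <- length(bag$pixels)
  if (n < 1L) abort("bag must contain at least one nodule", class = "milcascade_domain_error")
  d <- extractors[[1L]]$d_out
  U <- array(0, c(n, length(extractors), d))
  for (j in seq_along(extractors)) {
    U[, j, ] <- cnn_features(extractors[[j]], bag$pixels)
  }
  U
}

#' Attribute-level recalibration of one nodule's features
#'
#' Softmax over the subnetwork logits of the `m` attribute features gives
#' nonnegative coefficients summing to one; the nodule embedding is the
#' coefficient-weighted sum of the attribute features.
#'
#' @param features_row `m x d` matrix of attribute features for one nodule
#'   (a single vector is treated as `m = 1`).
#' @param subnet A [recal_subnet()].
#' @return List with `alpha` (length `m`) and `v` (length `d`).
#' @export
attribute_recalibrate <- function(features_row, subnet) {
  if (is.null(dim(features_row))) features_row <- matrix(features_row, nrow = 1L)
  if (nrow(features_row) < 1L) {
    abort("at least one attribute feature is required", class = "milcascade_domain_error")
  }
  alpha <- softmax(mlp_forward(subnet, features_row)$out[, 1L])
  list(alpha = alpha, v = as.numeric(crossprod(features_row, alpha)))
}

#' Nodule-level recalibration of a bag's nodule embeddings
#'
#' @param nodule_embeddings `n x d` matrix of nodule embeddings.
#' @param subnet A [recal_subnet()].
#' @return List with `beta` (length `n`) and `z` (length `d`), the bag
#'   embedding.
#' @export
nodule_recalibrate <- function(nodule_embeddings, subnet) {
  if (is.null(dim(nodule_embeddings))) nodule_embeddings <- matrix(nodule_embeddings, nrow = 1L)
  if (nrow(nodule_embeddings) < 1L) {
    abort("at least one nodule embedding is required", class = "milcascade_domain_error")
  }
  beta <- softmax(mlp_forward(subnet, nodule_embeddings)$out[, 1L])
  list(beta = beta, z = as.numeric(crossprod(nodule_embeddings, beta)))
}

# Numerically safe binary cross-entropy from the logit.
bce_from_logit <- function(logit, label) {
  softplus <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
  if (label == 1) softplus(-logit) else softplus(logit)
}

#' Classify a bag embedding
#'
#' Logistic output of the classification head; a probability of at least 0.5
#' is called positive. When a ground-truth label is supplied, the binary
#' cross-entropy loss is attached.
#'
#' @param z Bag embedding of length `d`.
#' @param head A [classifier_head()].
#' @param label Optional 0/1 ground truth.
#' @return List of class `bag_prediction` with `probability`, `label`
#'   (predicted), and optionally `loss` and `label_true`.
#' @export
classify_bag <- function(z, head, label = NULL) {
  if (!all(is.finite(z))) abort("non-finite bag embedding", class = "milcascade_numeric_error")
  logit <- mlp_forward(head, matrix(z, nrow = 1L))$out[1L, 1L]
  out <- list(probability = plogis(logit), label = as.integer(plogis(logit) >= 0.5))
  if (!is.null(label)) {
    out$loss <- bce_from_logit(logit, label)
    out$label_true <- label
  }
  structure(out, class = "bag_prediction")
}

#' @export
print.bag_prediction <- function(x, ...) {
  cat("<bag_prediction> p =", signif(x$probability, 4),
      "->", if (x$label == 1) "positive" else "negative", "\n")
  if (!is.null(x$recalibration)) {
    cat("  beta:", paste(signif(x$recalibration$beta, 3), collapse = " "), "\n")
  }
  invisible(x)
}

# ---- unified forward/backward over a cached feature grid -------------------

# U: (n, m, d) feature array. Returns probability plus coefficients; with
# cache = TRUE also everything needed for the backward pass.
mil_forward <- function(model, U, cache = FALSE) {
  n <- dim(U)[1L]; m <- dim(U)[2L]; d <- dim(U)[3L]
  out <- list(n = n, m = m)
  if (model$variant == "instance") {
    inst <- matrix(U[, 1L, ], nrow = n)
    hf <- mlp_forward(model$head, inst, cache = cache)
    probs <- plogis(hf$out[, 1L])
    i_star <- which.max(hf$out[, 1L])
    out <- c(out, list(probability = probs[i_star], logit = hf$out[i_star, 1L],
                       instance_probabilities = probs, key = i_star,
                       head_cache = hf$cache))
  } else if (model$variant == "embedding") {
    inst <- matrix(U[, 1L, ], nrow = n)
    z <- apply(inst, 2L, max)
    argmax <- max.col(t(inst), ties.method = "first")   # per-dimension source row
    hf <- mlp_forward(model$head, matrix(z, nrow = 1L), cache = cache)
    out <- c(out, list(probability = plogis(hf$out[1L, 1L]), logit = hf$out[1L, 1L],
                       z = z, argmax = argmax, head_cache = hf$cache))
  } else {
    if (model$variant == "cascaded") {
      Uflat <- matrix(aperm(U, c(2L, 1L, 3L)), n * m, d)   # rows: (j within i)
      af <- mlp_forward(model$subnet_attr, Uflat, cache = cache)
      logits_a <- matrix(af$out[, 1L], nrow = n, byrow = TRUE)
      alpha <- t(apply(logits_a, 1L, softmax))
      if (m == 1L) alpha <- matrix(alpha, nrow = n)
      V <- matrix(0, n, d)
      for (i in seq_len(n)) V[i, ] <- crossprod(matrix(U[i, , ], nrow = m), alpha[i, ])
      out$alpha <- alpha
      out$attr_cache <- af$cache
      out$Uflat <- if (cache) Uflat else NULL
    } else {
      V <- matrix(U[, 1L, ], nrow = n)
      out$alpha <- matrix(1, n, 1L)
    }
    nf <- mlp_forward(model$subnet_nodule, V, cache = cache)
    beta <- softmax(nf$out[, 1L])
    z <- as.numeric(crossprod(V, beta))
    hf <- mlp_forward(model$head, matrix(z, nrow = 1L), cache = cache)
    out <- c(out, list(probability = plogis(hf$out[1L, 1L]), logit = hf$out[1L, 1L],
                       beta = beta, z = z, V = V,
                       nodule_cache = nf$cache, head_cache = hf$cache,
                       key = which.max(beta)))
  }
  out$label <- as.integer(out$probability >= 0.5)
  out
}

# Backward pass for one bag. Returns component gradients, the loss, and the
# gradient with respect to the feature grid (for unfrozen extractors).
mil_backward <- function(model, fw, U, label, need_dU = FALSE) {
  n <- fw$n; m <- fw$m; d <- dim(U)[3L]
  loss <- bce_from_logit(fw$logit, label)
  dlogit <- plogis(fw$logit) - label
  grads <- list()
  dU <- if (need_dU) array(0, dim(U)) else NULL
  if (model$variant == "instance") {
    dout <- matrix(0, n, 1L)
    dout[fw$key, 1L] <- dlogit
    hb <- mlp_backward(model$head, fw$head_cache, dout)
    grads$head <- hb$grads
    if (need_dU) dU[, 1L, ] <- hb$dX
  } else if (model$variant == "embedding") {
    hb <- mlp_backward(model$head, fw$head_cache, matrix(dlogit, 1L, 1L))
    grads$head <- hb$grads
    if (need_dU) {
      for (k in seq_len(d)) dU[fw$argmax[k], 1L, k] <- hb$dX[1L, k]
    }
  } else {
    hb <- mlp_backward(model$head, fw$head_cache, matrix(dlogit, 1L, 1L))
    grads$head <- hb$grads
    dz <- hb$dX[1L, ]
    beta <- fw$beta; V <- fw$V
    dbeta <- as.numeric(V %*% dz)
    dV <- outer(beta, dz)
    dg <- beta * (dbeta - sum(beta * dbeta))           # softmax jacobian
    nb <- mlp_backward(model$subnet_nodule, fw$nodule_cache, matrix(dg, ncol = 1L))
    grads$nodule <- nb$grads
    dV <- dV + nb$dX
    if (model$variant == "cascaded") {
      alpha <- fw$alpha
      dalpha <- matrix(0, n, m)
      for (i in seq_len(n)) {
        Ui <- matrix(U[i, , ], nrow = m)
        dalpha[i, ] <- Ui %*% dV[i, ]
        if (need_dU) dU[i, , ] <- dU[i, , ] + outer(alpha[i, ], dV[i, ])
      }
      da <- alpha * (dalpha - rowSums(alpha * dalpha))
      ab <- mlp_backward(model$subnet_attr, fw$attr_cache,
                         matrix(as.numeric(t(da)), ncol = 1L))
      grads$attr <- ab$grads
      if (need_dU) {
        dU <- dU + aperm(array(as.numeric(ab$dX), c(m, n, d)), c(2L, 1L, 3L))
      }
    } else if (need_dU) {
      dU[, 1L, ] <- dU[, 1L, ] + dV
    }
  }
  list(grads = grads, loss = loss, dU = dU)
}

forward_on_bag <- function(model, bag) {
  U <- extract_attribute_features(bag, model$extractors)
  fw <- mil_forward(model, U)
  res <- structure(list(probability = fw$probability, label = fw$label),
                   class = "bag_prediction")
  if (!is.null(fw$beta)) {
    res$recalibration <- list(alpha = fw$alpha, beta = fw$beta,
                              nodule_embeddings = fw$V, bag_embedding = fw$z,
                              key_nodule = fw$key)
  }
  if (!is.null(fw$instance_probabilities)) {
    res$instance_probabilities <- fw$instance_probabilities
    res$key_nodule <- fw$key
  }
  res
}

#' Forward pass of the cascaded-recalibrated MIL model
#'
#' Extracts the `n x m` attribute feature grid, recalibrates each nodule's
#' attribute features into a nodule embedding, recalibrates the nodule
#' embeddings into the bag embedding, and classifies it. With a single
#' attribute source this is weight-for-weight identical to the recalibrated
#' model: the lone attribute coefficient is 1 and the attribute embedding
#' already is the nodule embedding.
#'
#' @param model A `mil_model` (variant `"cascaded"` or `"recalibrated"`).
#' @param bag A `nodule_bag`.
#' @return A `bag_prediction` including the recalibration coefficients.
#' @export
forward_cascaded <- function(model, bag) {
  stopifnot(inherits(model, "mil_model"))
  if (!model$variant %in% c("cascaded", "recalibrated")) {
    abort("model must be a cascaded or recalibrated MIL variant",
          class = "milcascade_config_error")
  }
  forward_on_bag(model, bag)
}

#' Forward pass of the instance-space MIL baseline
#'
#' Each nodule gets its own malignancy probability from a logistic head on
#' its feature embedding; the bag probability is the maximum over nodules.
#'
#' @param model A `mil_model` of variant `"instance"`.
#' @param bag A `nodule_bag`.
#' @return A `bag_prediction` with per-instance probabilities.
#' @export
forward_instance_space <- function(model, bag) {
  stopifnot(inherits(model, "mil_model"), model$variant == "instance")
  forward_on_bag(model, bag)
}

#' Forward pass of the embedding-space MIL baseline
#'
#' The bag embedding is the elementwise maximum over the nodule feature
#' embeddings, classified as a whole.
#'
#' @param model A `mil_model` of variant `"embedding"`.
#' @param bag A `nodule_bag`.
#' @return A `bag_prediction`.
#' @export
forward_embedding_space <- function(model, bag) {
  stopifnot(inherits(model, "mil_model"), model$variant == "embedding")
  forward_on_bag(model, bag)
}

#' Predict bag probabilities for a list of bags
#'
#' @param object A `mil_model`.
#' @param bags List of `nodule_bag`s.
#' @param ... Unused.
#' @return Tibble with `patient_id`, `probability`, `label_pred`, and (when
#'   the bags carry labels) `label_true`.
#' @export
predict.mil_model <- function(object, bags, ...) {
  purrr::map_dfr(bags, function(bag) {
    pred <- forward_on_bag(object, bag)
    tibble::tibble(patient_id = bag$patient_id %||% NA_character_,
                   probability = pred$probability,
                   label_pred = pred$label,
                   label_true = bag$label %||% NA_integer_)
  })
}
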