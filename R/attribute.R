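# Attribute-specific feature learning: one (extractor, regression head) pair
# per semantic attribute, trained by mean-squared-error score regression on
# the unlabeled discovery group. The trained extractors are the transferable
# feature sources for the MIL stage.

#' Training configuration for attribute-specific models
#'
#' Defaults are the desk-scale recipe for the bundled compact backbone:
#' Adam at learning rate 0.003, batch size 32, 40 epochs, weight decay
#' 1e-4. The classical fine-tuning recipe (plain SGD with momentum, batch
#' 64, learning rate 0.01 divided by 10 every 20 epochs, 60 epochs) is
#' available via `optimizer = "sgd"`.
#'
#' @param epochs Number of passes over the discovery set.
#' @param batch_size Patches per SGD step.
#' @param lr Initial learning rate.
#' @param lr_decay_every,lr_decay_factor Step learning-rate schedule.
#' @param optimizer `"adam"` (default; when `lr` is not given, Adam uses
#'   0.001) or `"sgd"` with classical momentum.
#' @param momentum Classical SGD momentum coefficient (SGD only).
#' @param weight_decay L2 penalty coupled into the SGD update.
#' @param seed Integer seed controlling initialization and batch order.
#' @param backbone Feature extractor architecture; `"tinycnn"` is the compact
#'   CPU backbone bundled with the package.
#' @param channels Convolution widths of the tinycnn backbone.
#' @param d_out Feature dimension (512 matches every downstream head).
#' @return List of class `attr_train_config`.
#' @export
attr_train_config <- function(epochs = 40L, batch_size = 32L, lr = 0.01,
                              lr_decay_every = 30L, lr_decay_factor = 0.1,
                              optimizer = c("adam", "sgd"), momentum = 0.9,
                              weight_decay = 1e-4, seed = 1L,
                              backbone = "tinycnn", channels = c(8L, 16L, 32L),
                              d_out = 512L) {
  if (!identical(backbone, "tinycnn")) {
    abort("the bundled engine provides the 'tinycnn' backbone", class = "milcascade_config_error")
  }
  optimizer <- match.arg(optimizer)
  if (optimizer == "adam" && missing(lr)) lr <- 0.003
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, lr_decay_every = as.integer(lr_decay_every),
                 lr_decay_factor = lr_decay_factor, optimizer = optimizer,
                 momentum = momentum, weight_decay = weight_decay,
                 seed = as.integer(seed), backbone = backbone,
                 channels = as.integer(channels), d_out = as.integer(d_out)),
            class = "attr_train_config")
}

as_discovery <- function(discovery) {
  if (inherits(discovery, "nodule_cohort")) discovery <- discovery_patches(discovery)
  if (!is.list(discovery) || is.null(discovery$pixels) || is.null(discovery$scores)) {
    abort("`discovery` must be a nodule_cohort or a list(pixels, scores)",
          class = "milcascade_domain_error")
  }
  discovery
}

#' Train an attribute-specific model by score regression
#'
#' Jointly optimizes a convolutional feature extractor and a 512-32-1
#' regression head to minimize the mean squared error between predicted and
#' radiologist-assigned scores of one semantic attribute over the discovery
#' group.
#'
#' @param discovery A `nodule_cohort` (its discovery group is used) or a
#'   list with `pixels` (list of patch matrices) and `scores` (tibble with
#'   the attribute columns).
#' @param attribute One of the nine attribute abbreviations.
#' @param config An [attr_train_config()].
#' @return Object of class `attribute_model`: the extractor, the head, the
#'   attribute name, the config, and the per-epoch training loss trace.
#' @export
train_attribute_model <- function(discovery, attribute, config = attr_train_config()) {
  if (!attribute %in% MIL_ATTRIBUTES) {
    abort(paste0("unknown attribute '", attribute, "'"), class = "milcascade_config_error")
  }
  discovery <- as_discovery(discovery)
  n <- length(discovery$pixels)
  if (n == 0L) abort("empty discovery set", class = "milcascade_domain_error")
  y <- discovery$scores[[attribute]]
  seed <- derive_seed(config$seed, paste0("attr-", attribute))
  extractor <- tinycnn_init(config$channels, config$d_out, seed = seed)
  head <- mlp_init(c(config$d_out, 32L, 1L), seed = derive_seed(seed, "head"))
  trace <- numeric(0)
  st_head <- NULL; st_cnn <- NULL; t_step <- 0L
  if (config$epochs > 0L) {
    withr::with_seed(derive_seed(seed, "order"), {
      for (epoch in seq_len(config$epochs)) {
        lr <- config$lr * config$lr_decay_factor^((epoch - 1L) %/% config$lr_decay_every)
        idx <- sample.int(n)
        ep_loss <- 0
        for (start in seq(1L, n, by = config$batch_size)) {
          b <- idx[start:min(start + config$batch_size - 1L, n)]
          fwd <- cnn_forward(extractor, patches_to_batch(discovery$pixels[b]), cache = TRUE)
          hf <- mlp_forward(head, fwd$out, cache = TRUE)
          resid <- hf$out[, 1L] - y[b]
          loss <- mean(resid^2)
          if (!is.finite(loss)) {
            abort(sprintf("training diverged at epoch %d (non-finite loss)", epoch),
                  class = "milcascade_divergence_error")
          }
          ep_loss <- ep_loss + loss * length(b)
          hb <- mlp_backward(head, hf$cache, matrix(2 * resid / length(b), ncol = 1L))
          cb <- cnn_backward(extractor, fwd$cache, hb$dX)
          t_step <- t_step + 1L
          cfg <- list(optimizer = config$optimizer, lr = lr,
                      momentum = config$momentum,
                      weight_decay = config$weight_decay, t = t_step)
          up <- mlp_update(head, hb$grads, cfg, st_head)
          head <- up$net; st_head <- up$st
          up <- cnn_update(extractor, cb$grads, cfg, st_cnn)
          extractor <- up$net; st_cnn <- up$st
        }
        trace <- c(trace, ep_loss / n)
      }
    })
  }
  structure(list(attribute = attribute, extractor = extractor, head = head,
                 config = config, loss = trace),
            class = "attribute_model")
}

#' @export
print.attribute_model <- function(x, ...) {
  cat("<attribute_model> ", x$attribute, " (", x$extractor$backbone,
      ", d = ", x$extractor$d_out, ")", sep = "")
  if (length(x$loss)) cat(", final training MSE ", signif(x$loss[length(x$loss)], 4), sep = "")
  cat("\n")
  invisible(x)
}

#' Predict attribute scores for a set of patches
#'
#' Deterministic inference pass through a trained (or freshly initialized)
#' attribute model.
#'
#' @param model An `attribute_model`.
#' @param patches List of patch matrices (possibly empty).
#' @return Numeric vector of score estimates, one per patch.
#' @export
predict_scores <- function(model, patches) {
  stopifnot(inherits(model, "attribute_model"))
  if (length(patches) == 0L) return(numeric(0))
  feat <- cnn_features(model$extractor, patches)
  mlp_forward(model$head, feat)$out[, 1L]
}

#' Mean absolute error between predicted and true scores
#'
#' @param predicted,truth Equal-length numeric vectors.
#' @return Mean of absolute differences.
#' @export
#' @examples
#' mae(c(1, 5), c(2, 3))  # 1.5
mae <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(predicted) < 1L) {
    abort("`predicted` and `truth` must have equal length >= 1",
          class = "milcascade_domain_error")
  }
  mean(abs(predicted - truth))
}

#' Interobserver variation of radiologist ratings
#'
#' For each nodule rated by at least two radiologists, the mean absolute
#' difference over all unordered rater pairs is computed; these per-nodule
#' values are then averaged. Nodules with a single rating carry no pair and
#' are skipped.
#'
#' @param per_nodule_ratings List of numeric vectors, one per nodule.
#' @return Mean pairwise absolute rating difference.
#' @export
#' @examples
#' interobserver_variation(list(c(1, 2), c(4, 4)))  # 0.5
interobserver_variation <- function(per_nodule_ratings) {
  per_nodule <- vapply(per_nodule_ratings, function(r) {
    if (length(r) < 2L) return(NA_real_)
    mean(as.numeric(stats::dist(matrix(r, ncol = 1L))))
  }, numeric(1))
  per_nodule <- per_nodule[!is.na(per_nodule)]
  if (!length(per_nodule)) {
    abort("no nodule has two or more ratings; interobserver variation undefined",
          class = "milcascade_domain_error")
  }
  mean(per_nodule)
}
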