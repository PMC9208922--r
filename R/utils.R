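# Internal helpers: scoped seeds, numerics, small validators.

# Deterministically derive a child seed from a master seed and a stage tag.
# Keeps every value in [1, 2^31 - 2] so it is always a valid R integer seed.
derive_seed <- function(seed, tag) {
  h <- 0
  for (k in utf8ToInt(as.character(tag))) h <- (h * 131 + k) %% 1987654321
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483629 + 1)
}

#' Numerically stable softmax
#'
#' Computes `exp(x) / sum(exp(x))` after subtracting the maximum logit, so
#' arbitrarily large logits from untrained subnetworks cannot overflow.
#'
#' @param logits Numeric vector.
#' @return Numeric vector of the same length, nonnegative, summing to 1.
#' @export
#' @examples
#' softmax(c(0, log(3)))  # 0.25, 0.75
softmax <- function(logits) {
  if (length(logits) == 0L) {
    abort("softmax of an empty logit vector is undefined", class = "milcascade_domain_error")
  }
  e <- exp(logits - max(logits))
  e / sum(e)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# FNV-1a hash of a character scalar, returned as 8 hex digits. Used only to
# stamp configuration blocks in metrics files.
fnv1a_hash <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(paste(x, collapse = "\x1f"))) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), as.integer(b))
    h <- (as.numeric(h + 2^30) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    abort(paste0("`", name, "` must be a single number strictly between 0 and 1"),
          class = "milcascade_config_error")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
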