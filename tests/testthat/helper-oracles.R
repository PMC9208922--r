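# Independent brute-force oracles, kept free of the package's internals.

# Plain exp/sum softmax (no stabilization) — safe for the moderate logits
# used in tests.
softmax_bruteforce <- function(x) exp(x) / sum(exp(x))

# Naive forward pass of a package MLP: explicit loops over layers, ReLU on
# the input and hidden layers, linear output. Reads only the weight lists.
mlp_bruteforce <- function(net, x) {
  a <- pmax(x, 0)
  L <- length(net$W)
  for (l in seq_len(L)) {
    z <- as.numeric(t(net$W[[l]]) %*% a) + net$b[[l]]
    a <- if (l < L) pmax(z, 0) else z
  }
  a
}

# Brute-force recalibration of one group of feature vectors: per-vector
# logit via mlp_bruteforce, exp/sum coefficients, elementwise weighted sum.
recalibrate_bruteforce <- function(features, subnet) {
  logits <- apply(features, 1L, function(u) mlp_bruteforce(subnet, u))
  coef <- softmax_bruteforce(logits)
  pooled <- numeric(ncol(features))
  for (i in seq_len(nrow(features))) pooled <- pooled + coef[i] * features[i, ]
  list(coef = coef, pooled = pooled)
}

# Image-moment eccentricity of a grayscale patch: the blob mask is pixels
# clearly above the background level (median + 0.18, comfortably between the
# background noise band and the minimum blob contrast); eccentricity is that
# of the ellipse with the mask's second central moments.
moment_eccentricity <- function(img) {
  w <- img > stats::median(img) + 0.18
  w <- w / sum(w)
  r <- row(img); c <- col(img)
  mr <- sum(w * r); mc <- sum(w * c)
  srr <- sum(w * (r - mr)^2)
  scc <- sum(w * (c - mc)^2)
  src <- sum(w * (r - mr) * (c - mc))
  ev <- eigen(matrix(c(srr, src, src, scc), 2L), symmetric = TRUE)$values
  sqrt(1 - ev[2] / ev[1])
}
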