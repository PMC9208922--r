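# Minimal feed-forward neural-network engine.
#
# Everything the pipeline trains is small: a compact CNN backbone for 64x64
# grayscale patches, 512-128-32-1 recalibration subnetworks, and 512-32-1
# heads. Layers are stored as plain R matrices; convolutions go through an
# im2col lowering so the heavy lifting is a BLAS matrix product. Activations
# are held as (C, H, W, N) arrays (channel fastest), which lets im2col and
# col2im be plain sub-array copies.

# ---- multilayer perceptrons -------------------------------------------------

# widths: neuron counts per layer, e.g. c(512, 128, 32, 1). ReLU is applied to
# the input layer and every hidden layer; the final layer is linear. The input
# activation is idempotent for features coming out of the (post-ReLU) CNN
# backbone but is part of the module contract, so it is applied always.
mlp_init <- function(widths, seed = NULL, input_relu = TRUE) {
  stopifnot(length(widths) >= 2)
  make <- function() {
    W <- list(); b <- list()
    for (l in seq_len(length(widths) - 1L)) {
      fan_in <- widths[l]
      W[[l]] <- matrix(rnorm(fan_in * widths[l + 1L], sd = sqrt(2 / fan_in)),
                       nrow = fan_in, ncol = widths[l + 1L])
      b[[l]] <- numeric(widths[l + 1L])
    }
    structure(list(widths = widths, input_relu = input_relu, W = W, b = b),
              class = "milcascade_mlp")
  }
  if (is.null(seed)) make() else withr::with_seed(as.integer(seed), make())
}

# X: n_samples x widths[1]. Returns list(out = n x widths[last], cache).
mlp_forward <- function(net, X, cache = FALSE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  L <- length(net$W)
  acts <- vector("list", L + 1L)
  a <- if (net$input_relu) pmax(X, 0) else X
  acts[[1L]] <- a
  for (l in seq_len(L)) {
    z <- a %*% net$W[[l]] + rep(net$b[[l]], each = nrow(a))
    a <- if (l < L) pmax(z, 0) else z
    acts[[l + 1L]] <- a
  }
  list(out = a, cache = if (cache) list(X = X, acts = acts) else NULL)
}

# dout: gradient wrt the network output. Returns list(grads, dX).
mlp_backward <- function(net, cache, dout) {
  L <- length(net$W)
  acts <- cache$acts
  dW <- vector("list", L); db <- vector("list", L)
  d <- dout
  for (l in rev(seq_len(L))) {
    if (l < L) d <- d * (acts[[l + 1L]] > 0)   # ReLU mask of hidden layer l
    dW[[l]] <- crossprod(acts[[l]], d)
    db[[l]] <- colSums(d)
    d <- d %*% t(net$W[[l]])
  }
  if (net$input_relu) d <- d * (cache$X > 0)
  list(grads = list(W = dW, b = db), dX = d)
}

# ---- optimizers -------------------------------------------------------------

# One first-order step for a single parameter array. `cfg` carries optimizer
# ("sgd" with optional momentum, or "adam"), lr (already scheduled), momentum,
# weight_decay, and the 1-based step counter t (for Adam bias correction).
# `st` is the opaque per-parameter state (NULL on the first call).
step_param <- function(p, g, st, cfg) {
  g <- g + cfg$weight_decay * p
  if (identical(cfg$optimizer, "adam")) {
    if (is.null(st)) st <- list(m = p * 0, v = p * 0)
    st$m <- 0.9 * st$m + 0.1 * g
    st$v <- 0.999 * st$v + 0.001 * g * g
    mhat <- st$m / (1 - 0.9^cfg$t)
    vhat <- st$v / (1 - 0.999^cfg$t)
    p <- p - cfg$lr * mhat / (sqrt(vhat) + 1e-8)
  } else if (cfg$momentum > 0) {
    if (is.null(st)) st <- list(v = p * 0)
    st$v <- cfg$momentum * st$v + g
    p <- p - cfg$lr * st$v
  } else {
    p <- p - cfg$lr * g
  }
  list(p = p, st = st)
}

# `st` mirrors the net's parameter lists; NULL-initialized lazily.
mlp_update <- function(net, grads, cfg, st = NULL) {
  if (is.null(st)) st <- list(W = vector("list", length(net$W)),
                              b = vector("list", length(net$b)))
  for (l in seq_along(net$W)) {
    u <- step_param(net$W[[l]], grads$W[[l]], st$W[[l]], cfg)
    net$W[[l]] <- u$p; st$W[[l]] <- u$st
    u <- step_param(net$b[[l]], grads$b[[l]], st$b[[l]], cfg)
    net$b[[l]] <- u$p; st$b[[l]] <- u$st
  }
  list(net = net, st = st)
}

# ---- convolution and pooling (compiled kernels) -----------------------------

# 3x3 same-padded convolution lowered to a BLAS matrix product by an im2col
# transform (src/convops.cpp). weight W2d: (Cout, 9*Cin), columns matching
# the im2col row order (channel fastest within each of the 9 offsets). The
# backward kernel recomputes the lowering from the cached layer input.
conv3_forward <- function(x, W2d, b) .conv3_fwd(x, W2d, b)

conv3_backward <- function(x, W2d, dy) .conv3_bwd(x, W2d, dy)

# 2x2 max pooling with stored argmax for the backward routing; ties go to the
# first window position, deterministically.
maxpool2_forward <- function(x) .maxpool2_fwd(x)

maxpool2_backward <- function(cache, dy) .maxpool2_bwd(cache$which, dy, cache$dims)

# ---- compact CNN backbone ---------------------------------------------------

#' Initialize a compact convolutional backbone
#'
#' Three 3x3 convolution blocks (each conv + ReLU + 2x2 max pool), global
#' average pooling, and a fully connected projection with ReLU to a
#' `d_out`-dimensional feature vector. Designed so a full attribute-regression
#' run on 64x64 grayscale patches trains in minutes on one CPU core while
#' still exposing the standard 512-dimensional feature interface expected by
#' every downstream head.
#'
#' @param channels Integer vector of the three convolution widths.
#' @param d_out Output feature dimension (512 matches the downstream heads).
#' @param in_channels Number of input image channels (1 for grayscale).
#' @param seed Optional integer; when given, initialization is reproducible.
#' @return An object of class `milcascade_cnn`.
#' @export
tinycnn_init <- function(channels = c(8L, 16L, 32L), d_out = 512L,
                         in_channels = 1L, seed = NULL) {
  make <- function() {
    cins <- c(in_channels, channels[-length(channels)])
    conv <- purrr::map2(cins, channels, function(ci, co) {
      fan_in <- 9L * ci
      list(W = matrix(rnorm(co * fan_in, sd = sqrt(2 / fan_in)), co, fan_in),
           b = numeric(co))
    })
    fc_in <- channels[length(channels)]
    structure(list(backbone = "tinycnn", channels = channels, d_out = d_out,
                   in_channels = in_channels, conv = conv,
                   fc = list(W = matrix(rnorm(fc_in * d_out, sd = sqrt(2 / fc_in)),
                                        fc_in, d_out),
                             b = numeric(d_out))),
              class = "milcascade_cnn")
  }
  if (is.null(seed)) make() else withr::with_seed(as.integer(seed), make())
}

# Stack a list of H x W patch matrices into a (1, H, W, N) batch array.
patches_to_batch <- function(patches) {
  H <- nrow(patches[[1L]]); W <- ncol(patches[[1L]])
  for (p in patches) {
    if (!is.matrix(p) || nrow(p) != H || ncol(p) != W) {
      abort("all patches must be matrices of identical size",
            class = "milcascade_domain_error")
    }
  }
  # unlist fills (h, w, n) with h fastest; with a singleton channel dimension
  # first, that is exactly the (1, H, W, N) column-major layout.
  array(unlist(patches, use.names = FALSE), c(1L, H, W, length(patches)))
}

# x: (C, H, W, N) batch. Returns list(out = N x d_out feature matrix, cache).
# Each block applies conv, then 2x2 max pool, then ReLU; pooling before the
# (monotone) ReLU is algebraically identical to the usual conv-ReLU-pool
# order but rectifies a 4x smaller array.
cnn_forward <- function(net, x, cache = FALSE) {
  caches <- list()
  a <- x
  for (l in seq_along(net$conv)) {
    z <- conv3_forward(a, net$conv[[l]]$W, net$conv[[l]]$b)
    pf <- maxpool2_forward(z)
    if (cache) caches[[l]] <- list(input = a, relu = pf$out > 0, pool = pf[c("which", "dims")])
    a <- pmax(pf$out, 0)
  }
  d <- dim(a); C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  gap <- t(colMeans(aperm(array(a, c(C, HW, N)), c(2L, 1L, 3L))))  # N x C
  z_fc <- gap %*% net$fc$W + rep(net$fc$b, each = N)
  feat <- pmax(z_fc, 0)
  list(out = feat,
       cache = if (cache) list(blocks = caches, gap = gap, gap_dims = d, fc_mask = z_fc > 0) else NULL)
}

# dout: N x d_out gradient. Returns list(grads, dx (optional)).
cnn_backward <- function(net, cache, dout, need_dx = FALSE) {
  d_fc <- dout * cache$fc_mask
  gW <- crossprod(cache$gap, d_fc)
  gb <- colSums(d_fc)
  dgap <- d_fc %*% t(net$fc$W)                       # N x C
  dd <- cache$gap_dims; C <- dd[1]; HW <- dd[2] * dd[3]; N <- dd[4]
  v <- t(dgap) / HW                                   # C x N
  dy <- array(aperm(array(as.vector(v), c(C, N, HW)), c(1L, 3L, 2L)), dd)
  gconv <- vector("list", length(net$conv))
  for (l in rev(seq_along(net$conv))) {
    bl <- cache$blocks[[l]]
    dy <- maxpool2_backward(bl$pool, dy * bl$relu)
    cb <- conv3_backward(bl$input, net$conv[[l]]$W, dy)
    gconv[[l]] <- list(W = cb$dW, b = cb$db)
    if (l > 1L || need_dx) dy <- cb$dx
  }
  list(grads = list(conv = gconv, fc = list(W = gW, b = gb)),
       dx = if (need_dx) dy else NULL)
}

cnn_update <- function(net, grads, cfg, st = NULL) {
  if (is.null(st)) st <- list(conv = vector("list", length(net$conv)),
                              fcW = NULL, fcb = NULL)
  for (l in seq_along(net$conv)) {
    if (is.null(st$conv[[l]])) st$conv[[l]] <- list(W = NULL, b = NULL)
    u <- step_param(net$conv[[l]]$W, grads$conv[[l]]$W, st$conv[[l]]$W, cfg)
    net$conv[[l]]$W <- u$p; st$conv[[l]]$W <- u$st
    u <- step_param(net$conv[[l]]$b, grads$conv[[l]]$b, st$conv[[l]]$b, cfg)
    net$conv[[l]]$b <- u$p; st$conv[[l]]$b <- u$st
  }
  u <- step_param(net$fc$W, grads$fc$W, st$fcW, cfg)
  net$fc$W <- u$p; st$fcW <- u$st
  u <- step_param(net$fc$b, grads$fc$b, st$fcb, cfg)
  net$fc$b <- u$p; st$fcb <- u$st
  list(net = net, st = st)
}

# Feature extraction convenience: patches (list of matrices) -> N x d matrix.
cnn_features <- function(net, patches, batch_size = 128L) {
  n <- length(patches)
  if (n == 0L) return(matrix(0, 0L, net$d_out))
  out <- matrix(0, n, net$d_out)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx, ] <- cnn_forward(net, patches_to_batch(patches[idx]))$out
  }
  out
}
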