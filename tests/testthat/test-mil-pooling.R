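# The recalibration poolings: coefficient normalization, hand-derivable
# softmax cases, degeneracies, permutation invariance, and gradient flow.

test_that("softmax matches exp/sum and known values", {
  expect_equal(softmax(c(0, log(3))), c(0.25, 0.75))
  expect_equal(softmax(log(c(1, 2, 5))), c(0.125, 0.25, 0.625))
  expect_equal(softmax(5), 1)
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(sample(1:8, 1), sd = 3)
    expect_equal(softmax(x), softmax_bruteforce(x), tolerance = 1e-12)
  }
  # stabilized: huge logits do not overflow
  expect_equal(sum(softmax(c(1000, 1001))), 1)
})

test_that("attribute recalibration reproduces hand-evaluated coefficients", {
  # a linear 2 -> 1 subnet with weights (0, log 3): logits 0 and log 3 on the
  # unit basis vectors, so alpha = (0.25, 0.75) and v = 0.25 e1 + 0.75 e2
  subnet <- milcascade:::mlp_init(c(2, 1), seed = 1)
  subnet$W[[1]] <- matrix(c(0, log(3)), 2, 1)
  subnet$b[[1]] <- 0
  out <- attribute_recalibrate(diag(2), subnet)
  expect_equal(out$alpha, c(0.25, 0.75))
  expect_equal(out$v, c(0.25, 0.75))
})

test_that("nodule recalibration reproduces hand-evaluated coefficients", {
  subnet <- milcascade:::mlp_init(c(3, 1), seed = 1)
  subnet$W[[1]] <- matrix(log(c(1, 2, 5)), 3, 1)
  subnet$b[[1]] <- 0
  out <- nodule_recalibrate(diag(3), subnet)
  expect_equal(out$beta, c(0.125, 0.25, 0.625))
  expect_equal(out$z, c(0.125, 0.25, 0.625))
})

test_that("single-member groups and identical members give degenerate softmaxes", {
  d <- 32L
  subnet <- recal_subnet(d, seed = 4)
  u <- matrix(rnorm(d), 1, d)
  one <- attribute_recalibrate(u, subnet)
  expect_equal(one$alpha, 1)
  expect_equal(one$v, as.numeric(u))
  same <- attribute_recalibrate(u[rep(1, 3), ], subnet)
  expect_equal(same$alpha, rep(1 / 3, 3))
  expect_equal(same$v, as.numeric(u))
  single <- nodule_recalibrate(u, subnet)
  expect_equal(single$beta, 1)
  expect_equal(single$z, as.numeric(u))
})

test_that("recalibration agrees with the brute-force oracle to 1e-10", {
  set.seed(12)
  for (trial in 1:10) {
    d <- 64L
    n <- sample(1:6, 1); m <- sample(1:5, 1)
    subnet_a <- recal_subnet(d, widths = c(d, 16L, 8L, 1L), seed = 100 + trial)
    subnet_n <- recal_subnet(d, widths = c(d, 16L, 8L, 1L), seed = 200 + trial)
    U <- matrix(rnorm(m * d), m, d)
    got <- attribute_recalibrate(U, subnet_a)
    want <- recalibrate_bruteforce(U, subnet_a)
    expect_lt(max(abs(got$alpha - want$coef)), 1e-10)
    expect_lt(max(abs(got$v - want$pooled)), 1e-10)
    V <- matrix(rnorm(n * d), n, d)
    got <- nodule_recalibrate(V, subnet_n)
    want <- recalibrate_bruteforce(V, subnet_n)
    expect_lt(max(abs(got$beta - want$coef)), 1e-10)
    expect_lt(max(abs(got$z - want$pooled)), 1e-10)
  }
})

test_that("coefficients are normalized for random weights and bag shapes", {
  set.seed(13)
  for (trial in 1:50) {
    d <- 48L
    model <- feature_model("cascaded", m = sample(1:4, 1), d = d, seed = trial)
    U <- random_feature_bag(sample(1:8, 1), model$m, d)
    fw <- milcascade:::mil_forward(model, U)
    expect_true(all(fw$alpha >= 0))
    expect_lt(max(abs(rowSums(fw$alpha) - 1)), 1e-6)
    expect_true(all(fw$beta >= 0))
    expect_lt(abs(sum(fw$beta) - 1), 1e-6)
    expect_gte(fw$probability, 0); expect_lte(fw$probability, 1)
  }
})

test_that("bag classification is a logistic head with cross-entropy loss", {
  d <- 32L
  head <- classifier_head(d, seed = 3)
  head$W[[2]][] <- 0; head$b[[2]] <- 0       # zeroed final layer
  pred <- classify_bag(rnorm(d), head, label = 1)
  expect_equal(pred$probability, 0.5)
  expect_equal(pred$loss, log(2))
  expect_equal(pred$label, 1L)               # ties at 0.5 are positive
  # saturated negative: probability ~ 0, loss ~ 0 at label 0
  head$b[[2]] <- -30
  pred0 <- classify_bag(rnorm(d), head, label = 0)
  expect_lt(pred0$probability, 1e-10)
  expect_lt(pred0$loss, 1e-10)
  expect_error(classify_bag(c(NaN, rnorm(d - 1)), head), class = "milcascade_numeric_error")
})

test_that("cascaded with one attribute equals the recalibrated model weight-for-weight", {
  d <- 48L
  ext <- list(mal = tiny_extractor(5, d = d))
  casc <- mil_model("cascaded", ext, seed = 9)
  recal <- mil_model("recalibrated", ext, seed = 9)
  expect_identical(casc$head, recal$head)
  expect_identical(casc$subnet_nodule, recal$subnet_nodule)
  set.seed(21)
  for (i in 1:20) {
    U <- random_feature_bag(sample(1:10, 1), 1, d)
    pc <- milcascade:::mil_forward(casc, U)
    pr <- milcascade:::mil_forward(recal, U)
    expect_lt(abs(pc$probability - pr$probability), 1e-6)
    expect_lt(max(abs(pc$beta - pr$beta)), 1e-6)
  }
})

test_that("bag probability is invariant to nodule order in all four variants", {
  set.seed(22)
  d <- 48L
  for (variant in c("cascaded", "recalibrated", "instance", "embedding")) {
    m <- if (variant == "cascaded") 3L else 1L
    model <- feature_model(variant, m = m, d = d, seed = 31)
    for (i in 1:10) {
      n <- sample(2:8, 1)
      U <- random_feature_bag(n, m, d)
      perm <- sample(n)
      f1 <- milcascade:::mil_forward(model, U)
      f2 <- milcascade:::mil_forward(model, U[perm, , , drop = FALSE])
      expect_lt(abs(f1$probability - f2$probability), 1e-6)
      if (!is.null(f1$beta)) expect_lt(max(abs(f1$beta[perm] - f2$beta)), 1e-6)
    }
  }
})

test_that("cascaded pooling is equivariant to attribute order", {
  set.seed(23)
  d <- 48L
  model <- feature_model("cascaded", m = 4L, d = d, seed = 7)
  U <- random_feature_bag(5, 4, d)
  perm <- c(3, 1, 4, 2)
  m2 <- model
  m2$extractors <- model$extractors[perm]
  f1 <- milcascade:::mil_forward(model, U)
  f2 <- milcascade:::mil_forward(m2, U[, perm, , drop = FALSE])
  expect_lt(abs(f1$probability - f2$probability), 1e-6)
  expect_lt(max(abs(f1$alpha[, perm] - f2$alpha)), 1e-6)
})

test_that("a duplicated nodule splits beta evenly and leaves the embedding unchanged", {
  d <- 48L
  model <- feature_model("cascaded", m = 2L, d = d, seed = 11)
  set.seed(3)
  U1 <- random_feature_bag(1, 2, d)
  k <- 4L
  Uk <- U1[rep(1, k), , , drop = FALSE]
  f1 <- milcascade:::mil_forward(model, U1)
  fk <- milcascade:::mil_forward(model, Uk)
  expect_equal(fk$beta, rep(1 / k, k))
  expect_lt(max(abs(fk$z - f1$z)), 1e-10)
  expect_lt(abs(fk$probability - f1$probability), 1e-10)
})

test_that("instance-space pooling takes the max probability over nodules", {
  d <- 48L
  model <- feature_model("instance", m = 1L, d = d, seed = 13)
  set.seed(5)
  U <- random_feature_bag(4, 1, d)
  fw <- milcascade:::mil_forward(model, U)
  expect_equal(fw$probability, max(fw$instance_probabilities))
  expect_equal(fw$key, which.max(fw$instance_probabilities))
  single <- milcascade:::mil_forward(model, U[2, , , drop = FALSE])
  expect_equal(single$probability, fw$instance_probabilities[2])
  same <- milcascade:::mil_forward(model, U[rep(2, 3), , , drop = FALSE])
  expect_equal(same$probability, fw$instance_probabilities[2])
})

test_that("embedding-space pooling is an idempotent coordinatewise max", {
  d <- 48L
  model <- feature_model("embedding", m = 1L, d = d, seed = 17)
  set.seed(6)
  U <- random_feature_bag(5, 1, d)
  fw <- milcascade:::mil_forward(model, U)
  inst <- matrix(U[, 1, ], nrow = 5)
  expect_equal(fw$z, apply(inst, 2, max))
  expect_true(all(sweep(inst, 2, fw$z, `<=`)))
  dup <- milcascade:::mil_forward(model, U[c(1:5, 3), , , drop = FALSE])
  expect_equal(dup$z, fw$z)
  expect_equal(dup$probability, fw$probability)
})

test_that("raising one recalibration logit raises its coefficient and lowers the rest", {
  set.seed(9)
  logits <- rnorm(6)
  base <- softmax(logits)
  for (delta in c(0.1, 1, 5)) {
    bumped <- logits; bumped[3] <- bumped[3] + delta
    s <- softmax(bumped)
    expect_gt(s[3], base[3])
    expect_true(all(s[-3] < base[-3]))
  }
})

test_that("gradients reach the subnets and head, and the backbone when unfrozen", {
  d <- 48L
  model <- feature_model("cascaded", m = 2L, d = d, seed = 19)
  set.seed(7)
  U <- random_feature_bag(3, 2, d)
  fw <- milcascade:::mil_forward(model, U, cache = TRUE)
  bw <- milcascade:::mil_backward(model, fw, U, label = 1, need_dU = TRUE)
  grad_norm <- function(g) sum(vapply(g$W, function(w) sum(abs(w)), numeric(1)))
  expect_true(is.finite(bw$loss))
  expect_gt(grad_norm(bw$grads$head), 0)
  expect_gt(grad_norm(bw$grads$nodule), 0)
  expect_gt(grad_norm(bw$grads$attr), 0)
  expect_true(all(is.finite(bw$dU)))
  expect_gt(sum(abs(bw$dU)), 0)
  # unfrozen end-to-end: a training step changes backbone weights
  co <- tiny_cohort()
  bags <- diagnosis_bags(co)
  model2 <- mil_model("recalibrated", list(mal = tiny_extractor(23)), seed = 3,
                      frozen = FALSE)
  fit <- train_mil(model2, bags, mil_train_config(iterations = 4, seed = 5,
                                                  frozen_extractors = FALSE))
  expect_false(identical(fit$model$extractors[[1]]$conv[[1]]$W,
                         model2$extractors[[1]]$conv[[1]]$W))
})

test_that("forward wrappers enforce their variants and report coefficients", {
  co <- tiny_cohort()
  bag <- diagnosis_bags(co)[[1]]
  ext <- list(mal = tiny_extractor(29))
  rec <- mil_model("recalibrated", ext, seed = 2)
  pred <- forward_cascaded(rec, bag)
  expect_s3_class(pred, "bag_prediction")
  expect_equal(sum(pred$recalibration$beta), 1, tolerance = 1e-6)
  inst <- mil_model("instance", ext, seed = 2)
  pi <- forward_instance_space(inst, bag)
  expect_length(pi$instance_probabilities, length(bag$pixels))
  emb <- mil_model("embedding", ext, seed = 2)
  pe <- forward_embedding_space(emb, bag)
  expect_gte(pe$probability, 0)
  expect_error(forward_cascaded(inst, bag), class = "milcascade_config_error")
  expect_error(mil_model("instance", list(a = ext$mal, b = ext$mal)),
               class = "milcascade_config_error")
})
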