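fake_bag <- function(id, label) {
  structure(list(patient_id = id, pixels = NULL, scores = NULL, label = label),
            class = "nodule_bag")
}

test_that("the balanced stream strictly alternates classes from both pools", {
  bags <- c(lapply(1:3, function(i) fake_bag(paste0("P", i), 1L)),
            lapply(4:5, function(i) fake_bag(paste0("P", i), 0L)))
  set.seed(2)
  stream <- balanced_bag_stream(bags)
  draws <- replicate(2000, as.integer(stream()))
  labels <- vapply(bags, `[[`, integer(1), "label")[draws]
  expect_identical(labels[1:10], rep(c(1L, 0L), 5))
  expect_identical(labels, rep(c(1L, 0L), 1000))
  expect_identical(sum(labels == 1L), 1000L)
  # every pool member is eventually drawn
  expect_setequal(unique(draws[labels == 1L]), 1:3)
  expect_setequal(unique(draws[labels == 0L]), 4:5)
  # degenerate pools: the two bags simply alternate
  two <- balanced_bag_stream(bags[c(1, 4)])
  expect_identical(replicate(6, as.integer(two())), rep(c(1L, 2L), 3))
  expect_error(balanced_bag_stream(bags[1:3]), class = "milcascade_config_error")
})

test_that("stratified folds partition patients with balanced class counts", {
  df <- data.frame(patient_id = sprintf("P%03d", 1:117),
                   label = rep(c(1L, 0L), c(86, 31)))
  folds <- make_folds(df, k = 5, seed = 11)
  expect_setequal(folds$patient_id, df$patient_id)
  expect_identical(anyDuplicated(folds$patient_id), 0L)
  sizes <- table(folds$fold)
  expect_true(all(sizes %in% c(23L, 24L)))
  negs <- table(folds$fold[folds$label == 0L])
  expect_true(all(negs >= 6L))
  expect_identical(make_folds(df, k = 5, seed = 11), folds)
  expect_false(identical(make_folds(df, k = 5, seed = 12)$patient_id,
                         folds$patient_id))
  expect_error(make_folds(df, k = 1), class = "milcascade_config_error")
  expect_error(make_folds(df[c(1:4, 87:117), ], k = 5),
               class = "milcascade_config_error")
})

test_that("MIL training is a no-op at zero iterations and reproducible by seed", {
  d <- 48L
  ext <- list(mal = tiny_extractor(41, d = d))
  bags <- c(lapply(1:4, function(i) fake_bag(paste0("A", i), 1L)),
            lapply(5:8, function(i) fake_bag(paste0("B", i), 0L)))
  set.seed(10)
  feats <- lapply(seq_along(bags), function(i) random_feature_bag(3, 1, d))
  model <- mil_model("recalibrated", ext, seed = 5)
  fit0 <- train_mil(model, bags, mil_train_config(iterations = 0, seed = 1),
                    features = feats)
  expect_length(fit0$loss, 0)
  expect_identical(fit0$model$head, model$head)
  expect_identical(fit0$model$subnet_nodule, model$subnet_nodule)
  cfg <- mil_train_config(iterations = 150, seed = 33)
  fit1 <- train_mil(model, bags, cfg, features = feats)
  fit2 <- train_mil(model, bags, cfg, features = feats)
  expect_identical(fit1$loss, fit2$loss)
  expect_identical(fit1$model$head, fit2$model$head)
  expect_length(fit1$loss, 150)
})

test_that("MIL training drives the balanced-stream loss down on separable features", {
  d <- 48L
  ext <- list(mal = tiny_extractor(43, d = d))
  set.seed(20)
  mkbag <- function(i, label) fake_bag(paste0("P", i), label)
  bags <- lapply(1:12, function(i) mkbag(i, as.integer(i <= 6)))
  # positive bags contain one shifted instance — a learnable signature
  feats <- lapply(1:12, function(i) {
    U <- random_feature_bag(4, 1, d)
    if (i <= 6) U[1, 1, ] <- U[1, 1, ] + 2
    U
  })
  fit <- train_mil(mil_model("recalibrated", ext, seed = 3), bags,
                   mil_train_config(iterations = 400, seed = 9), features = feats)
  expect_lt(mean(tail(fit$loss, 50)), mean(head(fit$loss, 50)))
  expect_true(all(is.finite(fit$loss)))
})

test_that("batch sizes other than one bag are rejected", {
  expect_error(mil_train_config(batch = 2), class = "milcascade_config_error")
})

test_that("attribute ranking is deterministic and breaks exact ties by name", {
  co <- tiny_cohort()
  ext <- tiny_extractor(47)
  # two candidate attributes share the identical extractor: metrics tie
  models <- list(sph = ext, mal = ext)
  cfg <- mil_train_config(iterations = 30, seed = 13)
  rk1 <- rank_attributes(co, models, cfg, k = 2)
  rk2 <- rank_attributes(co, models, cfg, k = 2)
  expect_identical(as.data.frame(rk1), as.data.frame(rk2))
  expect_identical(rk1$f1[1], rk1$f1[2])
  expect_identical(rk1$attribute, c("mal", "sph"))   # alphabetical tie-break
  expect_identical(rk1$rank, 1:2)
})

test_that("top-1 cascaded training reproduces the single-attribute ranking run", {
  co <- tiny_cohort()
  models <- list(mal = tiny_extractor(53), sph = tiny_extractor(54))
  cfg <- mil_train_config(iterations = 40, seed = 17)
  rk <- rank_attributes(co, models, cfg, k = 2)
  top1 <- run_top_k(co, models, rk, k_top = 1, config = cfg, k = 2)
  per_fold <- attr(rk, "per_fold")
  lead <- per_fold[per_fold$attribute == rk$attribute[1], c("accuracy", "auc", "f1")]
  expect_equal(as.data.frame(top1$metrics$per_fold[, c("accuracy", "auc", "f1")]),
               as.data.frame(lead), tolerance = 1e-12)
  expect_error(run_top_k(co, models, rk, k_top = 3, config = cfg, k = 2),
               class = "milcascade_config_error")
  # boundary: all ranked attributes used
  expect_identical(run_top_k(co, models, rk, k_top = 2, config = cfg, k = 2)$attributes,
                   rk$attribute)
})

test_that("no patient leaks between a fold's training and test bags", {
  co <- tiny_cohort()
  bags <- diagnosis_bags(co)
  folds <- make_folds(bags, k = 3, seed = 3)
  pid <- vapply(bags, function(b) b$patient_id, character(1))
  for (f in 1:3) {
    test_ids <- folds$patient_id[folds$fold == f]
    expect_length(intersect(pid[!pid %in% test_ids], test_ids), 0)
  }
  expect_setequal(folds$patient_id, unname(pid))
})
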