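test_that("accuracy thresholds at 0.5 with ties called positive", {
  expect_equal(accuracy(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(accuracy(0.5, 1), 1)
  expect_equal(accuracy(0.5, 0), 0)
  expect_equal(accuracy(c(0.6, 0.6, 0.4, 0.4), c(1, 0, 1, 0)), 0.5)
  expect_error(accuracy(c(0.1, 0.2), 1), class = "milcascade_domain_error")
})

test_that("AUC is the tie-aware rank statistic", {
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(auc(c(0.4, 0.6), c(1, 0)), 0)
  expect_equal(auc(c(0.5, 0.5, 0.7), c(0, 1, 1)), 0.75)
  expect_error(auc(c(0.2, 0.8), c(1, 1)), class = "milcascade_domain_error")
})

test_that("AUC agrees with an established implementation on random data", {
  skip_if_not_installed("pROC")
  set.seed(14)
  for (i in 1:10) {
    labels <- c(0, 1, rbinom(30, 1, 0.4))
    probs <- runif(32)
    probs[sample(32, 8)] <- 0.5          # force ties
    ref <- as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc(probs, labels), ref, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone transforms of the scores", {
  set.seed(15)
  probs <- runif(40)
  labels <- rbinom(40, 1, 0.5); labels[1:2] <- c(0, 1)
  base <- auc(probs, labels)
  expect_equal(auc(plogis(5 * probs - 2), labels), base)
  expect_equal(auc(probs^3, labels), base)
})

test_that("macro F1 averages both one-vs-rest scores with zero for empty classes", {
  expect_equal(f1_macro(c(0.9, 0.8, 0.2), c(1, 1, 0)), 1)
  expect_equal(f1_macro(c(0.9, 0.9, 0.9), c(1, 1, 0)), 0.4)  # pos 0.8, neg 0
  # swapping the roles of the classes leaves the macro average unchanged
  expect_equal(f1_macro(c(0.9, 0.1), c(1, 0)), f1_macro(c(0.1, 0.9), c(0, 1)))
})

test_that("threshold metrics depend on scores only through the predicted labels", {
  set.seed(16)
  probs <- runif(30)
  labels <- rbinom(30, 1, 0.5)
  hard <- as.numeric(probs >= 0.5)
  expect_equal(accuracy(probs, labels), accuracy(hard, labels))
  expect_equal(f1_macro(probs, labels), f1_macro(hard, labels))
})

test_that("a random predictor on balanced labels concentrates near AUC 0.5", {
  set.seed(17)
  aucs <- replicate(1000, {
    labels <- rep(c(0, 1), 20)
    auc(runif(40), labels)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("fold aggregation reports mean and sample standard deviation", {
  rep5 <- aggregate_folds(data.frame(accuracy = rep(0.8, 5), auc = rep(0.8, 5),
                                     f1 = rep(0.8, 5)))
  expect_equal(rep5$mean_sd$mean, rep(0.8, 3))
  expect_equal(rep5$mean_sd$sd, rep(0, 3))
  two <- aggregate_folds(data.frame(accuracy = c(0.7, 0.9), auc = c(0.7, 0.9),
                                    f1 = c(0.7, 0.9)))
  expect_equal(two$mean_sd$mean, rep(0.8, 3))
  expect_equal(two$mean_sd$sd, rep(sqrt(0.02), 3), tolerance = 1e-12)
  shuffled <- aggregate_folds(data.frame(accuracy = c(0.9, 0.7), auc = c(0.9, 0.7),
                                         f1 = c(0.9, 0.7)))
  expect_equal(shuffled$mean_sd, two$mean_sd)
  expect_error(aggregate_folds(data.frame(accuracy = 0.8, auc = 0.8, f1 = 0.8)),
               class = "milcascade_domain_error")
})

test_that("tidiers expose per-fold tables and one-row summaries", {
  rep5 <- aggregate_folds(data.frame(accuracy = c(0.7, 0.9), auc = c(0.8, 0.8),
                                     f1 = c(0.6, 0.7)))
  expect_identical(nrow(tidy(rep5)), 2L)
  g <- glance(rep5)
  expect_identical(nrow(g), 1L)
  expect_equal(g$accuracy_mean, 0.8)
  expect_equal(g$n_folds, 2L)
})

test_that("coefficient reports flag the key nodule and echo normalization", {
  co <- tiny_cohort()
  bag <- diagnosis_bags(co)[[2]]
  ext <- list(mal = tiny_extractor(61), sph = tiny_extractor(62))
  model <- mil_model("cascaded", ext, seed = 8)
  ex <- explain_bag(model, bag)
  expect_identical(nrow(ex), length(bag$pixels))
  expect_equal(sum(ex$beta), 1, tolerance = 1e-6)
  alpha_cols <- paste0("alpha_", c("mal", "sph"))
  expect_true(all(alpha_cols %in% names(ex)))
  expect_equal(rowSums(as.matrix(ex[, alpha_cols])), rep(1, nrow(ex)),
               tolerance = 1e-6)
  expect_identical(which(ex$key_nodule), which.max(ex$beta))
  inst <- mil_model("instance", ext["mal"], seed = 8)
  expect_error(explain_bag(inst, bag), class = "milcascade_unsupported_error")
})

test_that("a bag of identical nodules yields uniform beta with a tie note", {
  co <- tiny_cohort()
  bag <- diagnosis_bags(co)[[1]]
  k <- 3L
  bag$pixels <- bag$pixels[rep(1, k)]
  bag$scores <- bag$scores[rep(1, k), ]
  bag$scores$nodule_id <- paste0("N", 1:k)
  model <- mil_model("recalibrated", list(mal = tiny_extractor(63)), seed = 4)
  ex <- explain_bag(model, bag)
  expect_equal(ex$beta, rep(1 / k, k))
  expect_true(all(ex$tie))
  expect_identical(which(ex$key_nodule), 1L)   # first index flagged on ties
})

test_that("metrics JSON serialization is stable and machine-readable", {
  rep5 <- aggregate_folds(data.frame(accuracy = c(0.7, 0.9), auc = c(0.8, 0.8),
                                     f1 = c(0.6, 0.7)))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(rep5, f1, variant = "cascaded", attributes = c("mal", "sph"),
                     k = 2, seed = 9, config = list(iterations = 10))
  write_metrics_json(rep5, f2, variant = "cascaded", attributes = c("mal", "sph"),
                     k = 2, seed = 9, config = list(iterations = 10))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  parsed <- jsonlite::read_json(f1)
  expect_identical(parsed$variant, "cascaded")
  expect_length(parsed$per_fold, 2)
  expect_equal(parsed$mean_sd$accuracy$mean, 0.8)
  expect_match(parsed$config_hash, "^[0-9a-f]{8}$")
})
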