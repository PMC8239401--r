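test_that("the architecture family enforces its coupling constraints", {
  spec <- architecture_spec(500, pool_1 = 10)
  expect_equal(hidden_input_size(spec), 640)  # 500/100 * 128
  expect_equal(model_name(spec), "CNN-10")
  expect_equal(model_name(architecture_spec(500, pool_1 = 10, n_filters_1 = 90)),
               "CNN-10(90)")
  expect_equal(model_name(architecture_spec(500, pool_1 = 10, n_filters_1 = 90,
                                            filter_size_1 = 9)),
               "CNN_9-10(90)")

  expect_error(architecture_spec(500, pool_1 = 3, pool_2 = 33), "100")
  expect_error(architecture_spec(487), "divisible")

  # the seven legal pool pairs share the hidden-layer input size
  specs <- pool_sweep_specs(500)
  expect_equal(names(specs),
               c("CNN-1", "CNN-2", "CNN-4", "CNN-10", "CNN-25", "CNN-50",
                 "CNN-100"))
  expect_true(all(vapply(specs, function(s) s$pool_1 * s$pool_2, 0) == 100))
  expect_equal(unique(vapply(specs, hidden_input_size, 0L)), 640L)

  expect_equal(vapply(filter_count_sweep_specs(500), function(s) s$n_filters_1,
                      0L, USE.NAMES = FALSE), c(30L, 60L, 90L, 120L))
  expect_equal(vapply(filter_size_sweep_specs(500), function(s) s$filter_size_1,
                      0L, USE.NAMES = FALSE), c(9L, 19L, 29L))
})

test_that("a forward pass runs for every pool configuration", {
  set.seed(3)
  x <- one_hot_encode(random_dna(500))
  for (spec in pool_sweep_specs(500)) {
    m <- build_architecture(spec, seed = 2)
    p <- predict(m, x)
    expect_length(p, 1)
    expect_true(p > 0 && p < 1)
  }
})

test_that("binary cross-entropy matches its closed forms and a hand summation", {
  expect_equal(binary_cross_entropy(c(1, 0), c(1, 0)), 0, tolerance = 1e-9)
  expect_equal(binary_cross_entropy(c(1, 0, 1), rep(0.5, 3)), log(2))
  expect_equal(binary_cross_entropy(1, 0.75), -log(0.75))
  set.seed(11)
  for (i in 1:10) {
    z <- sample(0:1, 20, replace = TRUE)
    y <- runif(20, 0.01, 0.99)
    by_hand <- -sum(vapply(seq_along(z), function(j) {
      z[j] * log(y[j]) + (1 - z[j]) * log(1 - y[j])
    }, 0)) / length(z)
    expect_equal(binary_cross_entropy(z, y), by_hand, tolerance = 1e-10)
  }
  expect_error(binary_cross_entropy(c(1, 0), 0.5), "length")
})

test_that("AUC equals the brute-force pairwise oracle", {
  expect_equal(compute_auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(compute_auroc(c(1, 0, 1, 0), rep(0.4, 4)), 0.5)
  expect_error(compute_auroc(c(1, 1), c(0.1, 0.2)), "both classes")
  set.seed(23)
  for (i in 1:30) {
    n <- sample(4:50, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    expect_equal(compute_auroc(labels, scores), brute_force_auc(labels, scores))
  }
})

test_that("split arithmetic reproduces the published train/test sizes", {
  expect_equal(split_sizes(65765), c(train = 59189L, test = 6576L))
  expect_equal(split_sizes(6862), c(train = 6176L, test = 686L))
  # stratified split hits those totals with class proportions intact
  labels <- rep(c(1, 0), c(1884, 4978))
  set.seed(1)
  ho <- bidirtss:::stratified_holdout(labels, 0.9)
  expect_length(ho$train, 6176)
  expect_length(ho$test, 686)
  expect_equal(sum(labels[ho$train]), 1696)  # 0.9 * 1884 rounded half up
})

test_that("fivefold fold sizes are balanced within one sequence", {
  labels <- rep(c(1, 0), c(1696, 4480))  # the 90% training portion
  set.seed(2)
  f <- cv_folds(labels, 5)
  expect_equal(sort(as.vector(table(f)), decreasing = TRUE),
               c(1236, 1235, 1235, 1235, 1235))
  # stratification: each fold's class-1 count differs by at most one
  t1 <- table(f[labels == 1])
  expect_lte(max(t1) - min(t1), 1)
  expect_error(cv_folds(labels, 1), "at least 2")
})

test_that("training is deterministic and fits separable data", {
  data <- separable_dataset(20, 100)
  arch <- tiny_arch()
  fit1 <- train_model(data, arch, tiny_training(epochs = 2, seed = 5))
  fit2 <- train_model(data, arch, tiny_training(epochs = 2, seed = 5))
  expect_identical(fit1$weights, fit2$weights)
  expect_identical(predict(fit1, data), predict(fit2, data))

  # all-G promoters vs all-A enhancers, the published regime (40 epochs)
  big <- separable_dataset(100, 100)
  fit <- train_model(big, tiny_arch(), training_spec(seed = 3))
  expect_gte(compute_auroc(big$labels, predict(fit, big)), 0.99)

  expect_error(train_model(separable_dataset(5, 100)[1:5], arch,
                           tiny_training()), "single class")
  expect_error(train_model(big, architecture_spec(500), tiny_training()),
               "input_length")
})

test_that("prediction is a sigmoid probability and deterministic", {
  m <- build_architecture(tiny_arch(), seed = 8)
  set.seed(9)
  seqs <- replicate(6, random_dna(100))
  p <- predict(m, c(seqs, seqs[1]))
  expect_true(all(p > 0 & p < 1))
  expect_identical(p[7], p[1])  # duplicated input, identical probability

  # all-zero final layer pins the output at sigmoid(0) = 0.5
  m$weights$Wo[] <- 0
  m$weights$bo <- 0
  expect_equal(unname(predict(m, seqs)), rep(0.5, 6))

  expect_error(predict(m, random_dna(200)), "length")
})

test_that("cross-validation evaluates every fold on the hold-out set", {
  set.seed(31)
  seqs <- c(replicate(30, random_dna(100, gc = 0.75)),
            replicate(30, random_dna(100, gc = 0.25)))
  data <- tss_dataset(seqs, rep(c(1, 0), each = 30))
  cv <- cross_validate(data, tiny_arch(), tiny_training(epochs = 2, seed = 4),
                       k = 3)
  expect_s3_class(cv, "tss_cv")
  expect_equal(nrow(cv$folds), 3)
  expect_equal(cv$n_holdout, 6)
  expect_true(all(cv$folds$auc_val >= 0 & cv$folds$auc_val <= 1))
  expect_gte(cv$auc_val_mean, min(cv$folds$auc_val))
  expect_lte(cv$auc_val_mean, max(cv$folds$auc_val))
  expect_equal(cv$auc_combined, mean(c(cv$auc_val_mean, cv$auc_holdout_mean)))
  expect_error(cross_validate(data, tiny_arch(), tiny_training(), k = 1),
               "at least 2")
})

test_that("an architecture sweep tabulates one row per model", {
  set.seed(32)
  seqs <- c(replicate(24, random_dna(100, gc = 0.8)),
            replicate(24, random_dna(100, gc = 0.2)))
  data <- tss_dataset(seqs, rep(c(1, 0), each = 24))
  specs <- list(tiny_arch(pool_1 = 10), tiny_arch(pool_1 = 4))
  tab <- run_architecture_sweep(data, specs,
                                tiny_training(epochs = 2, seed = 4), k = 2)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$pool_1 * tab$pool_2, c(100, 100))
  expect_true(all(c("model", "auc_val_mean", "auc_holdout_mean",
                    "auc_combined") %in% names(tab)))
})
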