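test_that("input gradients match central finite differences", {
  set.seed(51)
  arch <- tiny_arch()
  model <- build_architecture(arch, seed = 17)
  for (rep in 1:3) {
    s <- random_dna(100)
    x <- one_hot_encode(s)
    raw <- compute_saliency(model, x)[1, ]
    active <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    for (i in sample(100, 8)) {
      fd <- fd_score_grad(model, x, i, active[i])
      if (is.na(fd)) next  # oracle abstains at a ReLU/pool kink
      expect_equal(raw[i], abs(fd), tolerance = 1e-3)
    }
  }
})

test_that("zero-weight models give zero raw scores, uniform normalized scores", {
  model <- build_architecture(tiny_arch(), seed = 1)
  for (nm in names(model$weights)) model$weights[[nm]][] <- 0
  raw <- compute_saliency(model, strrep("A", 100))
  expect_equal(unname(raw[1, ]), rep(0, 100))
  expect_equal(unname(normalize_scores(raw[1, ])), rep(1 / 100, 100))
})

test_that("saliency is invariant to a shift of the output bias", {
  set.seed(52)
  model <- build_architecture(tiny_arch(), seed = 3)
  x <- one_hot_encode(random_dna(100))
  s1 <- compute_saliency(model, x)
  model$weights$bo <- model$weights$bo + 5
  expect_identical(compute_saliency(model, x), s1)
})

test_that("normalization conserves mass and handles degenerate input", {
  expect_equal(normalize_scores(c(1, 1, 1, 1)), rep(0.25, 4))
  expect_equal(normalize_scores(c(2, 0, 0)), c(1, 0, 0))
  expect_equal(normalize_scores(numeric(500)), rep(0.002, 500))
  expect_error(normalize_scores(c(-1, 2)), "non-negative")
  set.seed(53)
  m <- matrix(runif(5 * 50), 5, 50)
  expect_equal(unname(rowSums(normalize_scores(m))), rep(1, 5))
})

test_that("important positions strictly exceed the 1/l threshold", {
  expect_equal(saliency_threshold(500), 0.002)
  expect_equal(saliency_threshold(600), 1 / 600, tolerance = 1e-12)
  expect_length(call_important_positions(rep(1 / 500, 500)), 0)
  one_hot_mass <- c(1, rep(0, 499))
  expect_identical(call_important_positions(one_hot_mass), 1L)
  # fewer than l positions can ever exceed the mean
  set.seed(54)
  for (i in 1:10) {
    v <- normalize_scores(runif(80))
    expect_lt(length(call_important_positions(v)), 80)
  }
})

test_that("top-prediction selection filters, orders and truncates", {
  set.seed(55)
  seqs <- c(replicate(40, random_dna(100, gc = 0.8)),
            replicate(40, random_dna(100, gc = 0.2)))
  data <- tss_dataset(seqs, rep(c(1, 0), each = 40))
  fit <- train_model(data, tiny_arch(), training_spec(epochs = 25, seed = 6))
  p <- predict(fit, data)
  cutoff <- sort(p, decreasing = TRUE)[15]  # ensure some qualify, some not
  top <- select_top_predictions(fit, data, prob_min = cutoff, top_n = 10)
  expect_equal(top$n, 10)
  probs <- attr(top, "probabilities")
  expect_true(all(probs > cutoff))
  expect_true(all(diff(probs) <= 0))
  expect_identical(sort(p, decreasing = TRUE)[seq_len(top$n)], unname(probs))

  # nothing qualifies at an impossible threshold
  expect_warning(none <- select_top_predictions(fit, data, prob_min = 1),
                 "no sequence")
  expect_equal(none$n, 0)
})

test_that("aggregate maps are midpoint-relative with uniform baseline 1/l", {
  u <- matrix(1 / 500, 50, 500)
  map <- aggregate_saliency(u)
  expect_equal(dim(map$scores), c(50, 500))
  expect_equal(colnames(map$scores)[1], "-250")
  expect_equal(colnames(map$scores)[500], "249")
  expect_equal(region_mean(map, 20, 120), 0.002)
  expect_equal(region_mean(map, -250, 0), 0.002)
  expect_length(region_mean(map, 20, 120, per_sequence = TRUE), 50)
  expect_error(aggregate_saliency(matrix(1, 2, 10)), "sum")
})
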