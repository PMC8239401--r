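# Glorot-uniform initialization, drawn from R's RNG so training is
# reproducible under set.seed().
glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

init_weights <- function(arch) {
  k1 <- arch$filter_size_1; f1 <- arch$n_filters_1
  k2 <- arch$filter_size_2; f2 <- arch$n_filters_2
  flat <- hidden_input_size(arch); h <- arch$hidden_units
  list(W1 = glorot(k1 * 4, f1, k1 * 4, k1 * f1), b1 = numeric(f1),
       W2 = glorot(k2 * f1, f2, k2 * f1, k2 * f2), b2 = numeric(f2),
       Wh = glorot(flat, h, flat, h), bh = numeric(h),
       Wo = glorot(h, 1, h, 1), bo = 0)
}

#' Build (initialize) a model from an architecture
#'
#' Validates the architecture and returns an untrained model handle with
#' Glorot-uniform weights. [train_model()] does this internally; building
#' explicitly is useful for probing the architecture (parameter counts,
#' saliency of random models) without training.
#'
#' @param spec An [architecture_spec()].
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `tss_cnn`.
#' @export
build_architecture <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"))
  set.seed(seed)
  structure(list(arch = spec, weights = init_weights(spec), training = NULL,
                 history = NULL),
            class = "tss_cnn")
}

#' Binary cross-entropy loss
#'
#' `L = -(1/N) * sum(z * log(y) + (1 - z) * log(1 - y))` over `N`
#' predictions, with `z` the true 0/1 labels and `y` the predicted sigmoid
#' probabilities, clipped to `[1e-12, 1 - 1e-12]` before the logarithm.
#'
#' @param true_labels 0/1 vector.
#' @param predicted Probability vector of the same length.
#' @return Non-negative loss scalar.
#' @export
#' @examples
#' binary_cross_entropy(c(1, 0), c(0.5, 0.5))  # log(2)
binary_cross_entropy <- function(true_labels, predicted) {
  if (length(true_labels) != length(predicted)) {
    stop("label and prediction vectors differ in length")
  }
  stopifnot(all(true_labels %in% c(0, 1)))
  y <- pmin(pmax(predicted, 1e-12), 1 - 1e-12)
  -mean(true_labels * log(y) + (1 - true_labels) * log(1 - y))
}

adam_init <- function(w) {
  zeros <- lapply(w, function(x) x * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(w, state, grads, lr, decay, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  lr_t <- lr / (1 + decay * state$t)
  for (nm in names(w)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    w[[nm]] <- w[[nm]] - lr_t * mhat / (sqrt(vhat) + eps)
  }
  list(w = w, state = state)
}

arch_dims <- function(arch) {
  list(k1 = arch$filter_size_1, p1 = arch$pool_1,
       k2 = arch$filter_size_2, p2 = arch$pool_2)
}

#' Train a convolutional promoter/enhancer classifier
#'
#' Mini-batch Adam on binary cross-entropy with the regime in
#' [training_spec()]: shuffled mini-batches, exactly `epochs` passes,
#' inverted dropout active only during training. With a fixed seed two runs
#' on identical inputs produce bit-identical parameters.
#'
#' @param data A [tss_dataset()] containing both classes.
#' @param arch An [architecture_spec()] whose `input_length` matches the
#'   data.
#' @param tr A [training_spec()].
#' @param verbose If `TRUE`, message the mean loss each epoch.
#' @return A trained model of class `tss_cnn` with a per-epoch loss
#'   `history`.
#' @export
train_model <- function(data, arch, tr = training_spec(), verbose = FALSE) {
  stopifnot(inherits(data, "tss_dataset"), inherits(arch, "architecture_spec"),
            inherits(tr, "training_spec"))
  if (data$l != arch$input_length) {
    stop(sprintf("data length %d does not match architecture input_length %d",
                 data$l, arch$input_length))
  }
  if (length(unique(data$labels)) < 2) {
    stop("training set contains a single class")
  }
  set.seed(tr$seed)
  w <- init_weights(arch)
  opt <- adam_init(w)
  d <- arch_dims(arch)
  history <- numeric(tr$epochs)
  n <- data$n
  for (e in seq_len(tr$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = tr$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + tr$batch_size - 1, n)]
      out <- cnn_core(data$onehot[, , idx, drop = FALSE], w,
                      d$k1, d$p1, d$k2, d$p2,
                      labels = as.numeric(data$labels[idx]),
                      dropout_p = tr$dropout, input_grad = FALSE)
      step <- adam_step(w, opt, out$grads, tr$learning_rate, tr$lr_decay)
      w <- step$w
      opt <- step$state
      ep_loss <- ep_loss + out$loss * length(idx)
    }
    history[e] <- ep_loss / n
    if (verbose) message(sprintf("epoch %d/%d loss %.4f", e, tr$epochs, history[e]))
  }
  structure(list(arch = arch, weights = w, training = tr, history = history),
            class = "tss_cnn")
}

#' @export
print.tss_cnn <- function(x, ...) {
  cat(sprintf("%s model (%s, %d parameters)\n", model_name(x$arch),
              if (is.null(x$training)) "untrained" else "trained",
              n_parameters(x$arch)))
  invisible(x)
}

# Coerce prediction inputs to an l x 4 x n array.
as_input_array <- function(newdata, l) {
  if (inherits(newdata, "tss_dataset")) newdata <- newdata$onehot
  if (is.character(newdata)) {
    arr <- array(0, dim = c(nchar(newdata[1]), 4, length(newdata)))
    for (i in seq_along(newdata)) arr[, , i] <- one_hot_encode(newdata[i])
    newdata <- arr
  }
  if (is.matrix(newdata)) newdata <- array(newdata, dim = c(dim(newdata), 1))
  stopifnot(is.array(newdata), length(dim(newdata)) == 3)
  if (dim(newdata)[1] != l) {
    stop(sprintf("sequence length %d does not match model input_length %d",
                 dim(newdata)[1], l))
  }
  newdata
}

#' Predict promoter probabilities
#'
#' One sigmoid probability P(promoter) per sequence; `type = "score"`
#' returns the pre-sigmoid score instead.
#'
#' @param object A `tss_cnn` model.
#' @param newdata A [tss_dataset()], an `l x 4 x n` array, a single `l x 4`
#'   matrix, or a character vector of sequences.
#' @param type `"prob"` (default) or `"score"`.
#' @param batch_size Sequences per forward pass.
#' @param ... Ignored.
#' @return Numeric vector.
#' @export
predict.tss_cnn <- function(object, newdata, type = c("prob", "score"),
                            batch_size = 128, ...) {
  type <- match.arg(type)
  x <- as_input_array(newdata, object$arch$input_length)
  d <- arch_dims(object$arch)
  n <- dim(x)[3]
  out <- numeric(n)
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, n)
    res <- cnn_core(x[, , idx, drop = FALSE], object$weights,
                    d$k1, d$p1, d$k2, d$p2, labels = NULL, dropout_p = 0,
                    input_grad = FALSE)
    out[idx] <- if (type == "prob") res$prob else res$score
  }
  out
}

#' Area under the ROC curve
#'
#' The rank (Mann-Whitney) form: the probability that a random positive
#' outranks a random negative, with half credit for ties.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores Numeric score vector (higher = more promoter-like).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' compute_auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
compute_auroc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("length mismatch")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fivefold cross-validation with a hold-out test set
#'
#' Splits off a stratified 10% hold-out test set (training size rounded
#' half up, so 6,862 sequences give 6,176/686 and 65,765 give
#' 59,189/6,576), then runs stratified k-fold cross-validation on the
#' training portion. Each fold-model is evaluated on its validation fold
#' and on the hold-out set; the summary metric is the mean of the
#' validation and hold-out AUCs.
#'
#' @param data A [tss_dataset()].
#' @param arch An [architecture_spec()].
#' @param tr A [training_spec()]; its seed drives the splits and training.
#' @param k Number of folds (default 5).
#' @param holdout_fraction Hold-out fraction (default 0.1).
#' @param verbose Passed to [train_model()].
#' @return An object of class `tss_cv`: per-fold table, mean and sd of
#'   validation and hold-out AUCs, and the combined metric.
#' @export
cross_validate <- function(data, arch, tr = training_spec(), k = 5,
                           holdout_fraction = 0.1, verbose = FALSE) {
  if (k < 2) stop("k must be at least 2")
  set.seed(tr$seed)
  ho <- stratified_holdout(data$labels, 1 - holdout_fraction)
  folds <- cv_folds(data$labels[ho$train], k)
  train_data <- data[ho$train]
  test_data <- data[ho$test]
  rows <- lapply(seq_len(k), function(f) {
    fit <- train_model(train_data[folds != f], arch, tr, verbose = verbose)
    val <- train_data[folds == f]
    data.frame(fold = f, n_train = sum(folds != f), n_val = sum(folds == f),
               auc_val = compute_auroc(val$labels, predict(fit, val)),
               auc_holdout = compute_auroc(test_data$labels,
                                           predict(fit, test_data)))
  })
  tab <- do.call(rbind, rows)
  res <- list(model = model_name(arch), arch = arch, folds = tab,
              n_holdout = test_data$n,
              auc_val_mean = mean(tab$auc_val), auc_val_sd = sd(tab$auc_val),
              auc_holdout_mean = mean(tab$auc_holdout),
              auc_holdout_sd = sd(tab$auc_holdout))
  res$auc_combined <- mean(c(res$auc_val_mean, res$auc_holdout_mean))
  class(res) <- "tss_cv"
  res
}

#' @export
print.tss_cv <- function(x, ...) {
  cat(sprintf("%s fivefold CV: validation AUC %.3f +/- %.3f | hold-out AUC %.3f +/- %.3f | combined %.3f\n",
              x$model, x$auc_val_mean, x$auc_val_sd, x$auc_holdout_mean,
              x$auc_holdout_sd, x$auc_combined))
  invisible(x)
}

#' Run a hyperparameter sweep over an architecture list
#'
#' Cross-validates each architecture on the same data with the same
#' training regime and seed, and tabulates the results in the
#' mean-plus-minus-sd reporting convention.
#'
#' @param data A [tss_dataset()].
#' @param specs List of [architecture_spec()]s, e.g. [pool_sweep_specs()].
#' @param tr A [training_spec()].
#' @param k Folds per architecture.
#' @param holdout_fraction Hold-out fraction.
#' @return A data.frame with one row per architecture: name, layer
#'   hyperparameters, validation/hold-out AUC mean and sd, and the combined
#'   metric.
#' @export
run_architecture_sweep <- function(data, specs, tr = training_spec(), k = 5,
                                   holdout_fraction = 0.1) {
  rows <- lapply(specs, function(sp) {
    cv <- cross_validate(data, sp, tr, k = k,
                         holdout_fraction = holdout_fraction)
    data.frame(model = cv$model, n_filters_1 = sp$n_filters_1,
               filter_size_1 = sp$filter_size_1, pool_1 = sp$pool_1,
               n_filters_2 = sp$n_filters_2, filter_size_2 = sp$filter_size_2,
               pool_2 = sp$pool_2, auc_val_mean = cv$auc_val_mean,
               auc_val_sd = cv$auc_val_sd,
               auc_holdout_mean = cv$auc_holdout_mean,
               auc_holdout_sd = cv$auc_holdout_sd,
               auc_combined = cv$auc_combined, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
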